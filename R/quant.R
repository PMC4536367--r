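# Quantification arithmetic: small-RNA counting, abundance filters, RPM,
# log2 fold changes, 3'-end peak calling with internal-priming filtering,
# transcript counts, and translation efficiency.

longest_common_substring <- function(a, b) {
  x <- strsplit(a, "")[[1L]]
  y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) return(0L)
  best <- 0L
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    hit <- x[i] == y
    cur[hit] <- c(0L, prev)[which(hit)] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  as.integer(best)
}

#' Count miRNAs from trimmed small-RNA read sequences
#'
#' Each read is assigned to the miRNA with which it shares the longest
#' exact contiguous match of at least `min_match` nucleotides; shorter
#' best matches leave the read unassigned. Ties on match length are
#' broken by lexicographic miRNA name (first wins), which keeps counting
#' deterministic for identical paralog seeds.
#'
#' @param reads character vector of adaptor-trimmed read sequences
#'   (RNA or DNA; U is mapped to T).
#' @param mirna_db named character vector of mature miRNA sequences.
#' @param min_match minimum exact match length in nt (default 18).
#' @return named integer vector of counts over `names(mirna_db)` plus an
#'   `"*unassigned*"` element.
#' @export
count_mirnas <- function(reads, mirna_db, min_match = 18L) {
  if (length(mirna_db) == 0L) stop("empty miRNA database", call. = FALSE)
  if (is.null(names(mirna_db)) || anyNA(names(mirna_db))) {
    stop("mirna_db must be named", call. = FALSE)
  }
  db <- as_dna(mirna_db)[order(names(mirna_db))]
  counts <- stats::setNames(integer(length(db) + 1L),
                            c(names(db), "*unassigned*"))
  for (r in as_dna(reads)) {
    lens <- vapply(db, function(m) {
      if (grepl(r, m, fixed = TRUE)) return(nchar(r))   # read within miRNA
      if (grepl(m, r, fixed = TRUE)) return(nchar(m))   # miRNA within read
      longest_common_substring(r, m)
    }, 0L)
    best <- max(lens)
    if (best >= min_match) {
      counts[which.max(lens)] <- counts[which.max(lens)] + 1L
    } else {
      counts["*unassigned*"] <- counts["*unassigned*"] + 1L
    }
  }
  counts
}

#' Filter features by a minimum count in a minimum number of libraries
#'
#' Keeps rows with `count >= min_count` in at least `min_libs` libraries:
#' the abundance filters applied to small-RNA (>= 50 reads in 2
#' libraries), ribosome-profiling CDS counts (>= 50 in 2) and 3Seq
#' transcript counts (excluding < 10 in 2) tables.
#'
#' @param table numeric matrix or data.frame of counts, rows = features
#'   (rownames = ids), columns = libraries.
#' @param min_count minimum read count.
#' @param min_libs minimum number of libraries reaching `min_count`.
#' @return the filtered table (same type, possibly zero rows).
#' @export
filter_min_reads <- function(table, min_count, min_libs) {
  m <- as.matrix(table)
  if (min_libs > ncol(m)) stop("min_libs exceeds library count", call. = FALSE)
  if (nrow(m) == 0L) return(table)
  keep <- rowSums(m >= min_count) >= min_libs
  table[keep, , drop = FALSE]
}

#' Reads-per-million normalisation
#'
#' @param table counts matrix/data.frame (rows = features, cols = libraries).
#' @return matrix of RPM values; each column sums to 1e6.
#' @export
rpm <- function(table) {
  m <- as.matrix(table)
  totals <- colSums(m)
  if (any(totals <= 0)) stop("library with zero total reads", call. = FALSE)
  sweep(m, 2L, totals, "/") * 1e6
}

#' Pseudocounted log2 fold change of mean RPM
#'
#' Replicate libraries are averaged within condition first, then
#' `log2((mean_cond + pc) / (mean_ref + pc))`. Downstream meta-analysis
#' consumes only the sign and rank of these values, so no dispersion
#' model is fitted.
#'
#' @param cond RPM matrix (or vector) for the test condition.
#' @param ref RPM matrix (or vector) for the reference condition.
#' @param pseudocount RPM pseudocount (default 1).
#' @return named numeric vector of per-feature log2 fold changes.
#' @export
log2fc <- function(cond, ref, pseudocount = 1.0) {
  if (pseudocount < 0) stop("negative pseudocount", call. = FALSE)
  mc <- if (is.null(dim(cond))) cond else rowMeans(as.matrix(cond))
  mr <- if (is.null(dim(ref))) ref else rowMeans(as.matrix(ref))
  stopifnot(length(mc) == length(mr))
  log2((mc + pseudocount) / (mr + pseudocount))
}

#' Call 3'-end peaks from per-position read-end counts
#'
#' Groups 3'-end positions on the same chromosome and strand that lie
#' closer than `merge_distance` (gap between consecutive positions
#' < `merge_distance`) into one peak. The peak position is the modal end
#' site (leftmost on ties) and the read count is the sum over member
#' positions.
#'
#' @param end_sites data.frame `chrom`, `strand`, `pos` (0-based),
#'   `count`.
#' @param merge_distance nt (default 10).
#' @return data.frame of peaks: `chrom`, `strand`, `start`, `end`
#'   (0-based half-open span of member sites), `pos` (modal site),
#'   `read_count`.
#' @export
call_3p_peaks <- function(end_sites, merge_distance = 10L) {
  cols <- c("chrom", "strand", "pos", "count")
  stopifnot(all(cols %in% names(end_sites)))
  es <- end_sites[end_sites$count > 0, cols]
  if (nrow(es) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(), pos = integer(),
                      read_count = integer(), stringsAsFactors = FALSE))
  }
  # collapse duplicate positions, then sweep within chrom/strand
  es <- stats::aggregate(count ~ chrom + strand + pos, data = es, FUN = sum)
  es <- es[order(es$chrom, es$strand, es$pos), ]
  grp <- interaction(es$chrom, es$strand, drop = TRUE)
  new_group <- c(TRUE, diff(es$pos) >= merge_distance |
                   grp[-1L] != grp[-length(grp)])
  peak_id <- cumsum(new_group)
  out <- lapply(split(seq_len(nrow(es)), peak_id), function(i) {
    sub <- es[i, ]
    modal <- sub$pos[which.max(sub$count)]  # which.max: leftmost tie
    data.frame(chrom = sub$chrom[1L], strand = sub$strand[1L],
               start = min(sub$pos), end = max(sub$pos) + 1L,
               pos = modal, read_count = sum(sub$count),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flag peaks caused by internal poly(A) priming
#'
#' A peak is flagged when the 10 genomic nucleotides immediately 3' of
#' its modal end site (strand-aware) contain >= `max_a` adenosines, or
#' when the 6 immediately adjacent nucleotides are all A. At a contig
#' edge the available window is evaluated.
#'
#' @param peaks peak data.frame from [call_3p_peaks()].
#' @param genome named character vector of chromosome sequences.
#' @param window nt downstream to inspect (default 10).
#' @param max_a A count in `window` that triggers the flag (default 7).
#' @param run_a length of an all-A run immediately adjacent that triggers
#'   the flag (default 6).
#' @return logical vector, `TRUE` = internal-priming artefact (remove).
#' @export
filter_internal_priming <- function(peaks, genome, window = 10L,
                                    max_a = 7L, run_a = 6L) {
  vapply(seq_len(nrow(peaks)), function(i) {
    chrom <- peaks$chrom[i]
    if (!chrom %in% names(genome)) stop("peak on unknown contig: ", chrom)
    gseq <- genome[[chrom]]
    glen <- nchar(gseq)
    if (peaks$strand[i] == "+") {
      from <- peaks$pos[i] + 1L          # 0-based pos -> next base, 1-based
      down <- substr(gseq, from + 1L, min(glen, from + window))
    } else {
      to <- peaks$pos[i]                 # bases strictly 5' in genome coords
      down <- revcomp(substr(gseq, max(1L, to - window + 1L), to))
    }
    a_in_window <- sum(strsplit(down, "")[[1L]] == "A")
    adjacent_run <- nchar(down) >= run_a &&
      substr(down, 1L, run_a) == strrep("A", run_a)
    a_in_window >= max_a || adjacent_run
  }, logical(1))
}

#' Sum 3'UTR peak counts into per-transcript counts
#'
#' Only peaks annotated to a 3'UTR and not flagged as internal priming
#' contribute. A peak is assigned to a transcript when its modal end site
#' falls in the transcript's 3'UTR (optionally extended downstream).
#'
#' @param peaks peak data.frame with columns of [call_3p_peaks()] plus
#'   logical `internal_priming`; per-library count columns may be given
#'   via `lib_counts`.
#' @param models gene-model data.frame (see [gene_models()]).
#' @param lib_counts optional matrix (rows aligned to `peaks`) of
#'   per-library counts; defaults to the pooled `read_count` column.
#' @param utr3_extension nt of downstream extension (default 0).
#' @return matrix of per-transcript counts (rows = all `models$gene_id`).
#' @export
transcript_counts <- function(peaks, models, lib_counts = NULL,
                              utr3_extension = 0L) {
  if (is.null(lib_counts)) {
    lib_counts <- matrix(peaks$read_count, ncol = 1L,
                         dimnames = list(NULL, "pooled"))
  }
  lib_counts <- as.matrix(lib_counts)
  out <- matrix(0, nrow = nrow(models), ncol = ncol(lib_counts),
                dimnames = list(models$gene_id, colnames(lib_counts)))
  ok <- !peaks$internal_priming
  if (!any(ok)) return(out)
  utr <- utr3_ranges(models, utr3_extension)
  pk <- GenomicRanges::GRanges(peaks$chrom[ok],
                               IRanges::IRanges(peaks$pos[ok] + 1L, width = 1L),
                               strand = peaks$strand[ok])
  hits <- GenomicRanges::findOverlaps(pk, utr)
  if (length(hits) == 0L) return(out)
  # a site can only fall in one (non-overlapping) 3'UTR; keep first match
  first <- !duplicated(S4Vectors::queryHits(hits))
  qi <- S4Vectors::queryHits(hits)[first]
  gi <- S4Vectors::subjectHits(hits)[first]
  sub <- lib_counts[ok, , drop = FALSE][qi, , drop = FALSE]
  for (j in seq_len(ncol(out))) {
    agg <- rowsum(sub[, j], group = models$gene_id[gi])
    out[rownames(agg), j] <- agg[, 1L]
  }
  out
}

#' Translation efficiency and its knockout/wild-type ratio
#'
#' TE compares ribosome-footprint density on the CDS with mRNA abundance
#' from 3'-end counting. The default `ribo_over_mrna` mode is the
#' conventional ratio (footprint RPM / mRNA RPM); `mrna_over_ribo` is
#' provided as the literal inverse. Features with a zero denominator are
#' dropped with a warning.
#'
#' @param mrna_rpm named numeric vector of 3Seq mRNA RPM.
#' @param ribo_cds_rpm named numeric vector of Ribo-Seq CDS RPM.
#' @param mode `"ribo_over_mrna"` (default) or `"mrna_over_ribo"`.
#' @return data.frame `gene_id`, `mrna_rpm`, `ribo_rpm`, `te`.
#' @export
translation_efficiency <- function(mrna_rpm, ribo_cds_rpm,
                                   mode = c("ribo_over_mrna", "mrna_over_ribo")) {
  mode <- match.arg(mode)
  common <- intersect(names(mrna_rpm), names(ribo_cds_rpm))
  m <- mrna_rpm[common]
  r <- ribo_cds_rpm[common]
  denom <- if (mode == "ribo_over_mrna") m else r
  bad <- denom == 0
  if (any(bad)) {
    warning(sum(bad), " feature(s) with zero denominator skipped")
    m <- m[!bad]; r <- r[!bad]; common <- common[!bad]
  }
  te <- if (mode == "ribo_over_mrna") r / m else m / r
  data.frame(gene_id = common, mrna_rpm = unname(m), ribo_rpm = unname(r),
             te = unname(te), stringsAsFactors = FALSE, row.names = NULL)
}

#' Change in translation efficiency between genotypes
#'
#' @param te_ko TE data.frame for the knockout (from
#'   [translation_efficiency()]).
#' @param te_wt TE data.frame for the wild type.
#' @return data.frame `gene_id`, `te_ko`, `te_wt`, `delta_te`
#'   (= te_ko / te_wt) over the shared genes.
#' @export
delta_te <- function(te_ko, te_wt) {
  common <- intersect(te_ko$gene_id, te_wt$gene_id)
  k <- te_ko$te[match(common, te_ko$gene_id)]
  w <- te_wt$te[match(common, te_wt$gene_id)]
  data.frame(gene_id = common, te_ko = k, te_wt = w, delta_te = k / w,
             stringsAsFactors = FALSE, row.names = NULL)
}
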