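# Ago2 HITS-CLIP analysis: duplicate collapsing, cluster calling,
# summit detection, hierarchical genomic annotation, per-miRNA target-site
# prediction, and positional seed enrichment against shuffled backgrounds.

#' Collapse PCR-duplicate read alignments
#'
#' Reads identical in (chrom, strand, start, end) are reduced to a single
#' read; used after pooling the unique alignments of all libraries.
#'
#' @param reads data.frame `chrom`, `strand`, `start`, `end` (0-based
#'   half-open), any further columns carried from the first occurrence.
#' @return deduplicated data.frame, sorted by chrom/strand/start/end.
#' @export
collapse_duplicates <- function(reads) {
  key <- paste(reads$chrom, reads$strand, reads$start, reads$end)
  out <- reads[!duplicated(key), , drop = FALSE]
  out <- out[order(out$chrom, out$strand, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call CLIP clusters from collapsed read alignments
#'
#' A cluster is a maximal strand-specific chain of reads in which
#' consecutive reads overlap by at least `min_overlap` nucleotides
#' (half-open coordinates, so abutting reads do not overlap); chains with
#' at least `min_reads` reads are reported. The summit is the position of
#' maximal read coverage within the cluster (leftmost on ties).
#'
#' @param reads collapsed read data.frame (`chrom`, `strand`, `start`,
#'   `end`).
#' @param min_reads minimum reads per cluster (default 2).
#' @param min_overlap minimum pairwise overlap in nt (default 1).
#' @return data.frame `cluster_id`, `chrom`, `strand`, `start`, `end`,
#'   `n_reads`, `summit`.
#' @export
call_clusters <- function(reads, min_reads = 2L, min_overlap = 1L) {
  empty <- data.frame(cluster_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_reads = integer(),
                      summit = integer(), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  rd <- reads[order(reads$chrom, reads$strand, reads$start, reads$end), ]
  grp <- paste(rd$chrom, rd$strand)
  out <- list()
  for (g in unique(grp)) {
    sub <- rd[grp == g, ]
    # sweep: a new chain starts when the running max end overlaps the
    # next read by < min_overlap
    run_end <- cummax(sub$end)
    new_chain <- c(TRUE, run_end[-nrow(sub)] - sub$start[-1L] < min_overlap)
    chain <- cumsum(new_chain)
    for (ci in unique(chain)) {
      mem <- sub[chain == ci, ]
      if (nrow(mem) < min_reads) next
      cl <- data.frame(cluster_id = NA_character_, chrom = mem$chrom[1L],
                       strand = mem$strand[1L], start = min(mem$start),
                       end = max(mem$end), n_reads = nrow(mem),
                       summit = NA_integer_, stringsAsFactors = FALSE)
      cl$summit <- cluster_summit(cl, mem)
      out[[length(out) + 1L]] <- cl
    }
  }
  if (length(out) == 0L) return(empty)
  out <- do.call(rbind, out)
  out$cluster_id <- sprintf("cluster_%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Position of maximal read coverage within a cluster
#'
#' @param cluster single-row cluster data.frame (`start`, `end`).
#' @param reads data.frame of the cluster's member reads.
#' @return 0-based genomic position of the leftmost coverage maximum.
#' @export
cluster_summit <- function(cluster, reads) {
  width <- cluster$end - cluster$start
  cov <- integer(width)
  s <- pmax(reads$start, cluster$start) - cluster$start
  e <- pmin(reads$end, cluster$end) - cluster$start
  for (i in seq_along(s)) {
    if (e[i] > s[i]) cov[(s[i] + 1L):e[i]] <- cov[(s[i] + 1L):e[i]] + 1L
  }
  cluster$start + which.max(cov) - 1L
}

#' Annotate clusters to gene features hierarchically
#'
#' Each cluster gets the first category in the fixed order 3'UTR (with
#' downstream extension), CDS, 5'UTR, ncRNA, intron, intergenic whose
#' features it overlaps by at least one nucleotide on the same strand.
#' The gene id of the first matching feature is recorded.
#'
#' @param clusters cluster data.frame from [call_clusters()].
#' @param models gene-model table.
#' @param utr3_extension nt of 3'UTR downstream extension (default 5000).
#' @return `clusters` with added `annotation` and `gene_id` columns.
#' @export
annotate_clusters <- function(clusters, models, utr3_extension = 5000L) {
  clusters$annotation <- rep("intergenic", nrow(clusters))
  clusters$gene_id <- rep(NA_character_, nrow(clusters))
  if (nrow(clusters) == 0L) return(clusters)
  gr <- bed_to_granges(clusters$chrom, clusters$start, clusters$end,
                       clusters$strand)
  feature_sets <- list(
    "3UTR" = utr3_ranges(models, utr3_extension),
    "CDS" = cds_ranges(models),
    "5UTR" = utr5_ranges(models),
    "ncRNA" = ncrna_ranges(models),
    "intron" = intron_ranges(models)
  )
  todo <- rep(TRUE, nrow(clusters))
  for (cat in names(feature_sets)) {
    feats <- feature_sets[[cat]]
    if (length(feats) == 0L || !any(todo)) next
    hits <- GenomicRanges::findOverlaps(gr[todo], feats, minoverlap = 1L)
    if (length(hits) == 0L) next
    first <- !duplicated(S4Vectors::queryHits(hits))
    qi <- which(todo)[S4Vectors::queryHits(hits)[first]]
    clusters$annotation[qi] <- cat
    clusters$gene_id[qi] <- feats$gene_id[S4Vectors::subjectHits(hits)[first]]
    todo[qi] <- FALSE
  }
  clusters
}

#' Intron intervals of multi-block gene models
#'
#' Models carrying BED12-style `block_sizes` / `block_starts` columns
#' (comma-separated, relative to `tx_start`) yield the gaps between
#' consecutive blocks; single-block models yield none.
#'
#' @param models gene-model table.
#' @return GRanges with metadata column `gene_id` (possibly empty).
#' @export
intron_ranges <- function(models) {
  empty <- GenomicRanges::GRanges()
  S4Vectors::mcols(empty)$gene_id <- character(0)
  if (is.null(models$block_sizes)) return(empty)
  out <- list()
  for (i in seq_len(nrow(models))) {
    sizes <- as.integer(strsplit(models$block_sizes[i], ",")[[1L]])
    starts <- as.integer(strsplit(models$block_starts[i], ",")[[1L]])
    if (length(sizes) < 2L) next
    bs <- models$tx_start[i] + starts
    be <- bs + sizes
    out[[length(out) + 1L]] <-
      bed_to_granges(rep(models$chrom[i], length(sizes) - 1L),
                     be[-length(be)], bs[-1L],
                     rep(models$strand[i], length(sizes) - 1L),
                     gene_id = rep(models$gene_id[i], length(sizes) - 1L))
  }
  if (length(out) == 0L) return(empty)
  do.call(c, out)
}

#' Most-expressed miRNAs covering a cumulative abundance fraction
#'
#' Returns the smallest prefix of the descending-abundance list whose
#' cumulative share reaches `cumulative_fraction` (boundary inclusive);
#' equal abundances are ordered by name so the prefix is deterministic.
#'
#' @param mirna_rpm named numeric vector of miRNA abundances (RPM).
#' @param cumulative_fraction share to cover (default 0.90).
#' @return character vector of miRNA names.
#' @export
top_expressed_mirnas <- function(mirna_rpm, cumulative_fraction = 0.90) {
  stopifnot(all(mirna_rpm >= 0))
  if (sum(mirna_rpm) <= 0) stop("all-zero miRNA abundances", call. = FALSE)
  ord <- order(-mirna_rpm, names(mirna_rpm))
  shares <- cumsum(mirna_rpm[ord]) / sum(mirna_rpm)
  n <- which(shares >= cumulative_fraction - 1e-12)[1L]
  names(mirna_rpm)[ord][seq_len(n)]
}

#' Strand-corrected genomic sequence of each cluster
#'
#' @param clusters cluster data.frame.
#' @param genome named character vector of chromosome sequences.
#' @return character vector of cluster sense-strand sequences.
#' @export
cluster_sequences <- function(clusters, genome) {
  vapply(seq_len(nrow(clusters)), function(i) {
    gseq <- genome[[clusters$chrom[i]]]
    s <- substr(gseq, clusters$start[i] + 1L, clusters$end[i])
    if (clusters$strand[i] == "-") s <- revcomp(s)
    s
  }, "")
}

# summit offset within the sense-strand cluster sequence
summit_offsets <- function(clusters) {
  ifelse(clusters$strand == "+",
         clusters$summit - clusters$start,
         clusters$end - 1L - clusters$summit)
}

#' Predict miRNA target sites in 3'UTR CLIP clusters
#'
#' Scans the sense-strand genomic sequence of every 3'UTR-annotated
#' cluster for the 6mer seed motif of each supplied miRNA. Every
#' occurrence yields one site record; the site class is upgraded to 7mer
#' or 8mer when the longer motif is present at the same locus. Site
#' existence is 6mer-based, the class is annotation only.
#'
#' @param clusters annotated cluster data.frame (needs `annotation`,
#'   `gene_id`).
#' @param mirna_db named character vector of mature miRNA sequences
#'   (e.g. the [top_expressed_mirnas()] subset).
#' @param genome named character vector of chromosome sequences.
#' @return data.frame `mirna`, `cluster_id`, `gene_id`, `k_best`,
#'   `offset` (0-based in the cluster sense sequence).
#' @export
predict_target_sites <- function(clusters, mirna_db, genome) {
  empty <- data.frame(mirna = character(), cluster_id = character(),
                      gene_id = character(), k_best = integer(),
                      offset = integer(), stringsAsFactors = FALSE)
  cl <- clusters[clusters$annotation == "3UTR", , drop = FALSE]
  if (nrow(cl) == 0L || length(mirna_db) == 0L) return(empty)
  seqs <- cluster_sequences(cl, genome)
  out <- list()
  for (mir in names(mirna_db)) {
    m6 <- seed_site_motif(mirna_db[[mir]], 6L)
    m7 <- seed_site_motif(mirna_db[[mir]], 7L)
    m8 <- seed_site_motif(mirna_db[[mir]], 8L)
    for (i in seq_along(seqs)) {
      offs <- scan_sites(seqs[i], m6)
      if (length(offs) == 0L) next
      k_best <- vapply(offs, function(p) {
        if (p >= 2L && substr(seqs[i], p - 1L, p + 6L) == m8) return(8L)
        if (p >= 1L && substr(seqs[i], p, p + 6L) == m7) return(7L)
        6L
      }, 0L)
      out[[length(out) + 1L]] <-
        data.frame(mirna = mir, cluster_id = cl$cluster_id[i],
                   gene_id = cl$gene_id[i], k_best = k_best, offset = offs,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Positional seed enrichment around cluster summits
#'
#' Histograms motif start offsets relative to each cluster summit and
#' compares them with two backgrounds: dinucleotide shuffles of the
#' cluster sequences and length-matched random windows drawn from a pool
#' of 3'UTR sequences. Enrichment per bin is the pseudocounted ratio of
#' the observed count to the mean shuffled-background count.
#'
#' @param clusters annotated cluster data.frame (3'UTR clusters used).
#' @param motif DNA motif to profile.
#' @param genome named character vector of chromosome sequences.
#' @param utr_pool named character vector of 3'UTR sequences for the
#'   random-window background.
#' @param n_shuffles background replicates per cluster (default 10).
#' @param bin_width bin width in nt (default 5).
#' @param flank half-window around the summit in nt (default 50).
#' @return list with `bins` (left edges), `observed`, `bg_shuffle`,
#'   `bg_random` (mean per-replicate counts) and `enrichment`
#'   (observed vs shuffled).
#' @export
positional_seed_profile <- function(clusters, motif, genome, utr_pool,
                                    n_shuffles = 10L, bin_width = 5L,
                                    flank = 50L) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1", call. = FALSE)
  cl <- clusters[clusters$annotation == "3UTR", , drop = FALSE]
  # bins centred on their labels, so bin 0 covers [-bw/2, bw/2)
  edges <- seq(-flank - bin_width / 2, flank + bin_width / 2,
               by = bin_width)
  bins <- edges[-length(edges)] + bin_width / 2
  hist_counts <- function(offsets) {
    # findInterval maps out-of-range offsets to 0 / length(edges); both
    # are dropped by tabulate
    idx <- findInterval(offsets, edges)
    idx[idx > length(bins)] <- 0L
    tabulate(idx, nbins = length(bins))
  }
  if (nrow(cl) == 0L) {
    z <- stats::setNames(numeric(length(bins)), bins)
    return(list(bins = bins, observed = z, bg_shuffle = z, bg_random = z,
                enrichment = z))
  }
  seqs <- cluster_sequences(cl, genome)
  summit <- summit_offsets(cl)
  rel_offsets <- function(ss) {
    unlist(lapply(seq_along(ss), function(i) {
      scan_sites(ss[i], motif) - summit[i]
    }))
  }
  observed <- hist_counts(rel_offsets(seqs))
  bg_sh <- numeric(length(bins))
  bg_rd <- numeric(length(bins))
  pool_ok <- utr_pool[nchar(utr_pool) >= max(nchar(seqs))]
  if (length(pool_ok) == 0L) pool_ok <- utr_pool
  for (r in seq_len(n_shuffles)) {
    shuf <- vapply(seqs, dinucleotide_shuffle, "", USE.NAMES = FALSE)
    bg_sh <- bg_sh + hist_counts(rel_offsets(shuf))
    rnd <- vapply(seq_along(seqs), function(i) {
      len <- nchar(seqs[i])
      src <- pool_ok[nchar(pool_ok) >= len]
      if (length(src) == 0L) return(strrep("N", len))
      u <- src[[sample.int(length(src), 1L)]]
      at <- sample.int(nchar(u) - len + 1L, 1L)
      substr(u, at, at + len - 1L)
    }, "")
    bg_rd <- bg_rd + hist_counts(rel_offsets(rnd))
  }
  bg_sh <- bg_sh / n_shuffles
  bg_rd <- bg_rd / n_shuffles
  nm <- as.character(bins)
  list(bins = bins,
       observed = stats::setNames(observed, nm),
       bg_shuffle = stats::setNames(bg_sh, nm),
       bg_random = stats::setNames(bg_rd, nm),
       enrichment = stats::setNames((observed + 0.5) / (bg_sh + 0.5), nm))
}
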