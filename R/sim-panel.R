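# Synthetic expression panel and sequencing-count emitters.

#' Emit the five-dataset expression panel and raw count tables
#'
#' Log2 fold-change tables: every true target has expected log2FC
#' `+planted_lof_effect` in each LOF dataset and `-planted_gof_effect`
#' in each GOF dataset, non-targets 0, all with independent
#' `N(0, noise_sd)` noise. Count tables (3Seq mRNA, Ribo-Seq CDS,
#' small-RNA) are drawn per library as multinomials of `library_depth`
#' reads (2 replicate libraries per condition) whose expected RPM ratios
#' reproduce the planted log2FC; ribosome-footprint abundances track
#' mRNA abundances exactly, so the planted translation-efficiency change
#' is 1 for every gene.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the matching [sim_config()].
#' @param mirna_db named character vector of mature miRNA sequences for
#'   the small-RNA library (default [default_mirna_db()]).
#' @return list: `datasets` (list of [expression_dataset()]; LOF first),
#'   `counts` (list `seq3`, `ribo`, `smallrna` of integer matrices, 2 WT
#'   + 2 KO libraries each), `base_abundance` (named numeric).
#' @export
emit_expression_panel <- function(truth, config,
                                  mirna_db = default_mirna_db()) {
  set.seed(config$rng_seed + 3L)
  n <- nrow(truth)
  ids <- truth$gene_id
  noisy <- function(mu) {
    stats::setNames(mu + stats::rnorm(n, 0, config$noise_sd), ids)
  }
  lof_names <- c("lof_array_epidermis", "lof_riboseq", "lof_3seq",
                 sprintf("lof_extra%d", seq_len(max(0, config$n_lof_datasets - 3L))))
  gof_names <- c("gof_array_epi", "gof_array_hf",
                 sprintf("gof_extra%d", seq_len(max(0, config$n_gof_datasets - 2L))))
  datasets <- c(
    lapply(lof_names[seq_len(config$n_lof_datasets)], function(nm) {
      expression_dataset(nm, "LOF", noisy(truth$planted_lof_effect))
    }),
    lapply(gof_names[seq_len(config$n_gof_datasets)], function(nm) {
      expression_dataset(nm, "GOF", noisy(-truth$planted_gof_effect))
    })
  )
  names(datasets) <- vapply(datasets, function(d) d$name, "")

  # count tables: shared baseline abundances; KO shifts targets up
  base <- stats::setNames(stats::rlnorm(n, meanlog = 0, sdlog = 1), ids)
  w_wt <- base / sum(base)
  ko <- base * 2^truth$planted_lof_effect
  w_ko <- ko / sum(ko)
  draw <- function(w, depth) as.integer(stats::rmultinom(1L, depth, w))
  lib_matrix <- function(w_list, depth) {
    m <- vapply(w_list, draw, integer(n), depth = depth)
    rownames(m) <- ids
    m
  }
  depth <- config$library_depth
  seq3 <- lib_matrix(list(wt1 = w_wt, wt2 = w_wt, ko1 = w_ko, ko2 = w_ko),
                     depth)
  ribo <- lib_matrix(list(wt1 = w_wt, wt2 = w_wt, ko1 = w_ko, ko2 = w_ko),
                     depth)

  # small-RNA library dominated by a few miRNAs; the focal (knocked-out)
  # miRNA carries ~a third of WT reads and is absent in the KO
  mirs <- sort(names(mirna_db))
  others <- setdiff(mirs, config$mirna_name)
  sh <- 0.5^seq_along(others)
  w_mir_wt <- stats::setNames(numeric(length(mirs)), mirs)
  w_mir_wt[others] <- 0.65 * sh / sum(sh)
  w_mir_wt[config$mirna_name] <- 0.35
  w_mir_ko <- w_mir_wt
  w_mir_ko[config$mirna_name] <- 0
  w_mir_ko <- w_mir_ko / sum(w_mir_ko)
  smallrna <- vapply(list(wt1 = w_mir_wt, wt2 = w_mir_wt,
                          ko1 = w_mir_ko, ko2 = w_mir_ko),
                     draw, integer(length(mirs)), depth = depth)
  rownames(smallrna) <- mirs

  list(datasets = datasets,
       counts = list(seq3 = seq3, ribo = ribo, smallrna = smallrna),
       base_abundance = base)
}

#' Emit per-position 3'-end read counts from gene-level 3Seq counts
#'
#' Distributes each gene's library counts over five positions centred on
#' the transcript's annotated 3' end (the cleavage site), scattering
#' within the peak-merge distance so downstream peak calling recovers one
#' peak per gene.
#'
#' @param seq3_counts gene x library integer matrix (from
#'   [emit_expression_panel()]).
#' @param models gene-model table.
#' @param config the matching [sim_config()].
#' @return data.frame `chrom`, `strand`, `pos` (0-based), `lib`, `count`.
#' @export
emit_3p_end_sites <- function(seq3_counts, models, config) {
  set.seed(config$rng_seed + 4L)
  stopifnot(all(rownames(seq3_counts) %in% models$gene_id))
  mi <- match(rownames(seq3_counts), models$gene_id)
  plus <- models$strand[mi] == "+"
  end_pos <- ifelse(plus, models$tx_end[mi] - 1L, models$tx_start[mi])
  offsets <- -2L:2L
  wts <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  out <- vector("list", ncol(seq3_counts))
  for (j in seq_len(ncol(seq3_counts))) {
    cnt <- seq3_counts[, j]
    nz <- which(cnt > 0L)
    spread <- vapply(nz, function(i) {
      as.integer(stats::rmultinom(1L, cnt[i], wts))
    }, integer(length(offsets)))
    pos <- rep(end_pos[nz], each = length(offsets)) +
      rep(ifelse(plus[nz], 1L, -1L), each = length(offsets)) * offsets
    out[[j]] <- data.frame(chrom = rep(models$chrom[mi][nz],
                                       each = length(offsets)),
                           strand = rep(models$strand[mi][nz],
                                        each = length(offsets)),
                           pos = pos,
                           lib = colnames(seq3_counts)[j],
                           count = as.vector(spread),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[out$count > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emit CLIP read alignments over planted sites plus uniform background
#'
#' Every planted site receives `clip_reads_per_site` reads (length
#' 25-40 nt) whose centres sit on the site centre up to
#' `clip_summit_jitter` nt of jitter, on the gene's strand; background
#' reads are placed uniformly over the genome at `clip_background_rate`
#' reads per kb with random strand.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the matching [sim_config()].
#' @param seqs the [emit_sequences()] result (models + genome).
#' @return data.frame `chrom`, `start`, `end`, `name` (library), `score`,
#'   `strand`, `origin` (`site`/`background`).
#' @export
emit_clip_reads <- function(truth, config, seqs) {
  set.seed(config$rng_seed + 5L)
  models <- seqs$models
  out <- list()
  tgt <- which(truth$is_true_target)
  nps <- config$clip_reads_per_site
  if (nps > 0L && length(tgt) > 0L) {
    for (i in tgt) {
      mrow <- models[models$gene_id == truth$gene_id[i], ]
      k <- as.integer(substr(truth$seed_class[i], 1L, 1L))
      gs <- site_genomic_start(mrow, truth$site_pos[i], k)
      centre <- gs + k %/% 2L
      len <- sample(25:40, nps, replace = TRUE)
      jit <- sample(seq(-config$clip_summit_jitter,
                        config$clip_summit_jitter), nps, replace = TRUE)
      start <- pmax(0L, centre + jit - len %/% 2L)
      out[[length(out) + 1L]] <-
        data.frame(chrom = mrow$chrom, start = start, end = start + len,
                   name = "clip1", score = 1L, strand = mrow$strand,
                   origin = "site", stringsAsFactors = FALSE)
    }
  }
  glen <- nchar(seqs$genome)
  n_bg <- stats::rpois(1L, config$clip_background_rate * sum(glen) / 1000)
  if (n_bg > 0L) {
    ch <- sample(names(glen), n_bg, replace = TRUE, prob = glen)
    len <- sample(28:34, n_bg, replace = TRUE)
    start <- vapply(seq_len(n_bg), function(i) {
      sample.int(glen[[ch[i]]] - len[i], 1L) - 1L
    }, 0L)
    out[[length(out) + 1L]] <-
      data.frame(chrom = ch, start = start, end = start + len,
                 name = "clip1", score = 1L,
                 strand = sample(c("+", "-"), n_bg, replace = TRUE),
                 origin = "background", stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), origin = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
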