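# Independent brute-force oracles used to validate the fast
# implementations; deliberately naive.

# all 0-based offsets where motif matches, by explicit window comparison
naive_scan <- function(seq, motif) {
  n <- nchar(seq)
  k <- nchar(motif)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - k + 1L)) {
    if (substr(seq, i, i + k - 1L) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

# connected components of the pairwise-overlap graph of reads; returns
# clusters (>= min_reads members) as a sorted data.frame of spans
cc_clusters_oracle <- function(reads, min_reads = 2L, min_overlap = 1L) {
  n <- nrow(reads)
  if (n == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_reads = integer()))
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      same <- reads$chrom[i] == reads$chrom[j] &&
        reads$strand[i] == reads$strand[j]
      ov <- min(reads$end[i], reads$end[j]) -
        max(reads$start[i], reads$start[j])
      adj[i, j] <- same && ov >= min_overlap
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    mem <- reads[comp == cc, ]
    if (nrow(mem) < min_reads) return(NULL)
    data.frame(chrom = mem$chrom[1L], strand = mem$strand[1L],
               start = min(mem$start), end = max(mem$end),
               n_reads = nrow(mem), stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_reads = integer()))
  }
  out <- out[order(out$chrom, out$strand, out$start, out$end), ]
  rownames(out) <- NULL
  out
}

random_read_set <- function(n, chroms = c("c1", "c2"), span = 300L,
                            len_range = 25L:40L) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(len_range, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# one-sided two-sample K-S statistic by explicit evaluation at every
# pooled point
ks_D_oracle <- function(x, y, alternative) {
  t <- sort(unique(c(x, y)))
  Fx <- vapply(t, function(v) mean(x <= v), 0)
  Fy <- vapply(t, function(v) mean(y <= v), 0)
  d <- if (alternative == "greater") Fy - Fx else Fx - Fy
  max(c(0, d))
}

# hypergeometric upper tail by exhaustive enumeration of all draws
hyper_tail_oracle <- function(observed, n_draw, K, N) {
  if (n_draw == 0L) return(1)
  seeded <- c(rep(TRUE, K), rep(FALSE, N - K))
  draws <- utils::combn(N, n_draw)
  mean(vapply(seq_len(ncol(draws)), function(j) {
    sum(seeded[draws[, j]]) >= observed
  }, logical(1)))
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

MIR203 <- "GUGAAAUGUUUAGGACCACUAG"

tiny_config <- function(...) {
  defaults <- list(n_genes = 60L, n_true_targets = 12L,
                   utr_len_range = c(150L, 400L), library_depth = 5e4,
                   clip_background_rate = 0.02, intergenic_gap = 800L,
                   rng_seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
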