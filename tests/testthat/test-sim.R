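test_that("sim_config validates its invariants", {
  expect_s3_class(tiny_config(), "sim_config")
  expect_error(sim_config(n_genes = 10, n_true_targets = 11), "n_true")
  expect_error(sim_config(seed_class_mix = c("8mer" = 0.5, "7mer" = 0.2,
                                             "6mer" = 0.2)), "summing to 1")
  expect_error(sim_config(gc_content = 1.2), "gc_content")
  expect_error(sim_config(lof_effect_mean = 2, gof_effect_mean = 1),
               "gof_effect_mean")
  expect_error(sim_config(utr_len_range = c(10, 20)), "too short")
})

test_that("simulate_truth honours counts, mix and determinism", {
  cfg0 <- tiny_config(n_true_targets = 0L)
  t0 <- simulate_truth(cfg0)
  expect_false(any(t0$is_true_target))
  expect_true(all(t0$planted_lof_effect == 0))

  cfg1 <- sim_config(n_genes = 100L, n_true_targets = 30L,
                     seed_class_mix = c("8mer" = 1, "7mer" = 0, "6mer" = 0),
                     rng_seed = 5L)
  t1 <- simulate_truth(cfg1)
  expect_identical(sum(t1$seed_class == "8mer"), 30L)
  expect_identical(sum(t1$is_true_target), 30L)

  cfg2 <- tiny_config()
  expect_identical(simulate_truth(cfg2), simulate_truth(cfg2))
  # class effect ordering follows the scalars
  t2 <- simulate_truth(cfg2)
  eff <- tapply(t2$planted_gof_effect[t2$is_true_target],
                t2$seed_class[t2$is_true_target], mean)
  expect_true(eff[["8mer"]] > eff[["7mer"]] &&
                eff[["7mer"]] > eff[["6mer"]])
})

test_that("emit_sequences plants exact motifs and respects rejection rules", {
  cfg <- tiny_config()
  truth <- simulate_truth(cfg)
  seqs <- emit_sequences(truth, cfg)
  motifs <- c("8mer" = seed_site_motif(cfg$mirna_seq, 8),
              "7mer" = seed_site_motif(cfg$mirna_seq, 7),
              "6mer" = seed_site_motif(cfg$mirna_seq, 6))
  for (i in which(truth$is_true_target)) {
    m <- motifs[[truth$seed_class[i]]]
    got <- substr(seqs$utrs[[truth$gene_id[i]]], truth$site_pos[i] + 1,
                  truth$site_pos[i] + nchar(m))
    expect_identical(got, m)
    # the gene classifies to exactly its planted class
    expect_identical(classify_seed_class(seqs$utrs[[truth$gene_id[i]]],
                                         cfg$mirna_seq),
                     truth$seed_class[i])
  }
  # decoy-free non-targets carry no focal site at all
  cfg_df <- tiny_config(decoy_free = TRUE)
  truth_df <- simulate_truth(cfg_df)
  seqs_df <- emit_sequences(truth_df, cfg_df)
  for (i in which(!truth_df$is_true_target)) {
    expect_identical(
      scan_sites(seqs_df$utrs[[truth_df$gene_id[i]]], motifs[["6mer"]]),
      integer(0))
  }
  # GC content of the emitted UTRs tracks the configured fraction
  gc <- mean(strsplit(paste(seqs$utrs, collapse = ""), "")[[1]] %in%
               c("G", "C"))
  expect_lt(abs(gc - cfg$gc_content), 0.02)
  # byte determinism
  expect_identical(seqs$genome, emit_sequences(truth, cfg)$genome)
})

test_that("emitted gene models are consistent with the genome and the UTRs", {
  cfg <- tiny_config()
  truth <- simulate_truth(cfg)
  seqs <- emit_sequences(truth, cfg)
  m <- seqs$models
  expect_true(all(m$tx_start < m$tx_end))
  expect_true(all(m$cds_start >= m$tx_start & m$cds_end <= m$tx_end))
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch, ]
    expect_true(all(sub$tx_end <= nchar(seqs$genome[[ch]])))
    # loci are non-overlapping and sorted
    expect_true(all(sub$tx_start[-1] >= sub$tx_end[-nrow(sub)]))
  }
  # genomic 3'UTR equals the emitted sense UTR sequence
  for (i in sample(nrow(m), 10)) {
    g <- seqs$genome[[m$chrom[i]]]
    if (m$strand[i] == "+") {
      got <- substr(g, m$cds_end[i] + 1, m$tx_end[i])
    } else {
      got <- revcomp(substr(g, m$tx_start[i] + 1, m$cds_start[i]))
    }
    expect_identical(got, unname(seqs$utrs[[m$gene_id[i]]]))
  }
  # BED12 round trip preserves the models
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed12(m, path)
  m2 <- read_bed12(path)
  expect_equal(m2$tx_start, m$tx_start)
  expect_equal(m2$cds_end, m$cds_end)
  expect_identical(m2$gene_id, m$gene_id)
  # independent reader: rtracklayer's BED importer sees the same loci
  gr <- rtracklayer::import(path, format = "BED")
  expect_equal(GenomicRanges::start(gr), m$tx_start + 1L)
  expect_equal(GenomicRanges::end(gr), m$tx_end)
  expect_identical(as.character(GenomicRanges::strand(gr)), m$strand)
})

test_that("zero-noise panels reproduce planted effects exactly", {
  cfg <- tiny_config(noise_sd = 0)
  truth <- simulate_truth(cfg)
  panel <- emit_expression_panel(truth, cfg)
  tgt <- which(truth$is_true_target)[1]
  non <- which(!truth$is_true_target)[1]
  for (d in panel$datasets) {
    if (d$direction_class == "LOF") {
      expect_equal(unname(d$log2fc[truth$gene_id[tgt]]),
                   truth$planted_lof_effect[tgt])
    } else {
      expect_equal(unname(d$log2fc[truth$gene_id[tgt]]),
                   -truth$planted_gof_effect[tgt])
    }
    expect_equal(unname(d$log2fc[truth$gene_id[non]]), 0)
  }
})

test_that("panel noise means obey the CLT bound and counts reproduce planted ratios", {
  cfg <- sim_config(n_genes = 2000L, n_true_targets = 0L, noise_sd = 0.2,
                    utr_len_range = c(100L, 200L), rng_seed = 33L)
  truth <- simulate_truth(cfg)
  panel <- emit_expression_panel(truth, cfg)
  for (d in panel$datasets) {
    expect_lt(abs(mean(d$log2fc)), 3 * 0.2 / sqrt(2000))
  }
  # count-based log2fc estimates concentrate around the planted effect
  cfg2 <- sim_config(n_genes = 500L, n_true_targets = 100L,
                     utr_len_range = c(100L, 200L), library_depth = 1e7,
                     rng_seed = 34L)
  truth2 <- simulate_truth(cfg2)
  panel2 <- emit_expression_panel(truth2, cfg2)
  r <- rpm(panel2$counts$seq3)
  est <- log2fc(r[, c("ko1", "ko2")], r[, c("wt1", "wt2")])
  hi <- rowMeans(r) >= 50
  # RPM is compositional: upregulating targets shifts every gene's
  # relative abundance down by the total-mass ratio S
  S <- sum(panel2$base_abundance * 2^truth2$planted_lof_effect) /
    sum(panel2$base_abundance)
  err <- est[hi] + log2(S) - truth2$planted_lof_effect[hi]
  expect_gte(mean(abs(err) <= 0.1), 0.95)
})

test_that("ribosome counts track mRNA so the planted TE change is 1", {
  cfg <- tiny_config(library_depth = 2e5)
  truth <- simulate_truth(cfg)
  panel <- emit_expression_panel(truth, cfg)
  r3 <- rpm(panel$counts$seq3)
  rr <- rpm(panel$counts$ribo)
  te_wt <- translation_efficiency(rowMeans(r3[, 1:2]), rowMeans(rr[, 1:2]))
  te_ko <- translation_efficiency(rowMeans(r3[, 3:4]), rowMeans(rr[, 3:4]))
  d <- delta_te(te_ko, te_wt)
  expect_lt(abs(stats::median(d$delta_te) - 1), 0.1)
})

test_that("emit_clip_reads covers planted sites and respects empty configs", {
  cfg <- tiny_config()
  truth <- simulate_truth(cfg)
  seqs <- emit_sequences(truth, cfg)
  reads <- emit_clip_reads(truth, cfg, seqs)
  expect_true(all(reads$end - reads$start >= 25))
  site_reads <- reads[reads$origin == "site", ]
  expect_identical(nrow(site_reads),
                   sum(truth$is_true_target) * cfg$clip_reads_per_site)
  cfg0 <- tiny_config(clip_reads_per_site = 0L, clip_background_rate = 0)
  truth0 <- simulate_truth(cfg0)
  seqs0 <- emit_sequences(truth0, cfg0)
  expect_identical(nrow(emit_clip_reads(truth0, cfg0, seqs0)), 0L)
})

test_that("3'-end site emission conserves gene counts near annotated ends", {
  cfg <- tiny_config()
  truth <- simulate_truth(cfg)
  seqs <- emit_sequences(truth, cfg)
  panel <- emit_expression_panel(truth, cfg)
  es <- emit_3p_end_sites(panel$counts$seq3, seqs$models, cfg)
  per_lib <- tapply(es$count, es$lib, sum)
  expect_equal(as.vector(per_lib[colnames(panel$counts$seq3)]),
               unname(colSums(panel$counts$seq3)))
  # every emitted position lies within 2 nt of an annotated 3' end
  m <- seqs$models
  ends <- ifelse(m$strand == "+", m$tx_end - 1L, m$tx_start)
  near <- vapply(seq_len(nrow(es)), function(i) {
    any(m$chrom == es$chrom[i] & abs(ends - es$pos[i]) <= 2L)
  }, logical(1))
  expect_true(all(near))
})
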