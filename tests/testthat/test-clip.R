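test_that("collapse_duplicates keeps one read per identical alignment", {
  r <- data.frame(chrom = "c1", strand = "+", start = rep(100L, 5),
                  end = rep(130L, 5), name = paste0("lib", 1:5))
  expect_identical(nrow(collapse_duplicates(r)), 1L)
  r2 <- data.frame(chrom = "c1", strand = "+", start = c(100L, 101L),
                   end = c(130L, 130L))
  expect_identical(nrow(collapse_duplicates(r2)), 2L)
  # pooled multi-library identical alignments collapse to one
  pooled <- rbind(r, r)
  expect_identical(nrow(collapse_duplicates(pooled)), 1L)
})

test_that("call_clusters requires >= 1 nt overlap and >= 2 reads", {
  r <- data.frame(chrom = "c1", strand = "+", start = c(100L, 129L),
                  end = c(130L, 160L))
  cl <- call_clusters(r)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$start, 100L)
  expect_identical(cl$end, 160L)
  expect_identical(cl$n_reads, 2L)
  # abutting half-open intervals share zero nucleotides
  r2 <- data.frame(chrom = "c1", strand = "+", start = c(100L, 130L),
                   end = c(130L, 160L))
  expect_identical(nrow(call_clusters(r2)), 0L)
  # a single read is never a cluster
  r3 <- data.frame(chrom = "c1", strand = "+", start = 100L, end = 130L)
  expect_identical(nrow(call_clusters(r3)), 0L)
  # opposite strands never chain
  r4 <- data.frame(chrom = "c1", strand = c("+", "-"), start = c(100L, 120L),
                   end = c(130L, 150L))
  expect_identical(nrow(call_clusters(r4)), 0L)
})

test_that("call_clusters matches the connected-components oracle on random read sets", {
  set.seed(71)
  for (i in 1:150) {
    reads <- collapse_duplicates(random_read_set(sample(2:40, 1)))
    got <- call_clusters(reads)
    want <- cc_clusters_oracle(reads)
    got <- got[order(got$chrom, got$strand, got$start, got$end),
               c("chrom", "strand", "start", "end", "n_reads")]
    rownames(got) <- NULL
    expect_identical(got, want)
  }
})

test_that("cluster_summit is the leftmost coverage maximum", {
  cl <- data.frame(start = 100L, end = 130L)
  r <- data.frame(start = c(100L, 100L), end = c(130L, 130L))
  expect_identical(cluster_summit(cl, r), 100L)
  cl2 <- data.frame(start = 100L, end = 140L)
  r2 <- data.frame(start = c(100L, 110L), end = c(130L, 140L))
  expect_identical(cluster_summit(cl2, r2), 110L)
  # coverage-array oracle on random stacks
  set.seed(13)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    start <- sample(50:80, n, replace = TRUE)
    r3 <- data.frame(start = start, end = start + sample(10:30, n, TRUE))
    cl3 <- data.frame(start = min(r3$start), end = max(r3$end))
    cov <- integer(cl3$end - cl3$start)
    for (j in seq_len(n)) {
      idx <- (r3$start[j] - cl3$start + 1):(r3$end[j] - cl3$start)
      cov[idx] <- cov[idx] + 1
    }
    expect_identical(cluster_summit(cl3, r3),
                     cl3$start + which.max(cov) - 1L)
  }
})

make_models <- function() {
  gene_models(data.frame(
    gene_id = c("gA", "gB", "ncX"),
    chrom = c("c1", "c1", "c2"),
    strand = c("+", "-", "+"),
    tx_start = c(1000L, 20000L, 500L),
    tx_end = c(2000L, 21000L, 800L),
    cds_start = c(1100L, 20500L, 500L),
    cds_end = c(1500L, 20900L, 500L)))
}

test_that("annotate_clusters applies the fixed hierarchy with 3'UTR extension", {
  models <- make_models()
  cl <- data.frame(
    cluster_id = paste0("k", 1:6),
    chrom = c("c1", "c1", "c1", "c2", "c3", "c1"),
    strand = c("+", "+", "+", "+", "+", "-"),
    start = c(1490L, 1200L, 4500L, 600L, 100L, 20950L),
    end = c(1520L, 1230L, 4530L, 630L, 130L, 20980L),
    n_reads = 2L, summit = c(1500L, 1210L, 4510L, 610L, 110L, 20960L))
  ann <- annotate_clusters(cl, models)
  # straddles CDS and 3'UTR: hierarchy gives 3'UTR
  expect_identical(ann$annotation[1], "3UTR")
  expect_identical(ann$gene_id[1], "gA")
  expect_identical(ann$annotation[2], "CDS")
  # ~2.5 kb downstream of gA's 3'UTR end: caught by the 5 kb extension
  expect_identical(ann$annotation[3], "3UTR")
  expect_identical(ann$annotation[4], "ncRNA")
  expect_identical(ann$annotation[5], "intergenic")
  # minus-strand gene: 5'UTR is at high coordinates
  expect_identical(ann$annotation[6], "5UTR")
  # without the extension the downstream cluster is intergenic
  ann0 <- annotate_clusters(cl, models, utr3_extension = 0L)
  expect_identical(ann0$annotation[3], "intergenic")
})

test_that("intron_ranges emits gaps between blocks of multi-exon models", {
  m <- gene_models(data.frame(
    gene_id = "gm", chrom = "c1", strand = "+", tx_start = 100L,
    tx_end = 500L, cds_start = 120L, cds_end = 480L))
  m$block_sizes <- "100,100"
  m$block_starts <- "0,300"
  ir <- intron_ranges(m)
  expect_identical(length(ir), 1L)
  expect_identical(GenomicRanges::start(ir), 201L)  # 1-based
  expect_identical(GenomicRanges::end(ir), 400L)
  expect_identical(length(intron_ranges(make_models())), 0L)
})

test_that("top_expressed_mirnas selects the smallest covering prefix", {
  expect_setequal(top_expressed_mirnas(c(A = .5, B = .3, C = .15, D = .05)),
                  c("A", "B", "C"))
  expect_identical(top_expressed_mirnas(c(only = 12)), "only")
  ten <- stats::setNames(rep(10, 10), paste0("m", 1:10))
  expect_identical(length(top_expressed_mirnas(ten)), 9L)
  expect_error(top_expressed_mirnas(c(a = 0, b = 0)), "all-zero")
})

test_that("predict_target_sites scans only 3'UTR clusters and upgrades site class", {
  db <- c("mmu-miR-203-3p" = MIR203)
  # genome with a 6mer at 10, a full 8mer at 40 (both 0-based)
  gseq <- paste0(strrep("G", 10), "ATTTCA", strrep("G", 22), "ACATTTCA",
                 strrep("G", 30))
  genome <- c(c1 = gseq)
  cl <- data.frame(cluster_id = c("k1", "k2"), chrom = "c1",
                   strand = "+", start = c(0L, 0L), end = c(76L, 76L),
                   n_reads = 2L, summit = 10L,
                   annotation = c("3UTR", "CDS"),
                   gene_id = c("gA", "gB"))
  sites <- predict_target_sites(cl, db, genome)
  expect_identical(unique(sites$cluster_id), "k1")   # CDS cluster skipped
  expect_identical(nrow(sites), 2L)                  # two occurrences, one gene
  expect_identical(length(unique(sites$gene_id)), 1L)
  expect_identical(sites$k_best[sites$offset == 10L], 6L)
  expect_identical(sites$k_best[sites$offset == 40L], 8L)  # 6mer core of the 8mer
  # minus-strand cluster: motif on the sense strand
  genome2 <- c(c2 = revcomp(gseq))
  cl2 <- data.frame(cluster_id = "k3", chrom = "c2", strand = "-",
                    start = 0L, end = 76L, n_reads = 2L, summit = 10L,
                    annotation = "3UTR", gene_id = "gC")
  sites2 <- predict_target_sites(cl2, db, genome2)
  expect_identical(nrow(sites2), 2L)
})

test_that("positional_seed_profile concentrates planted summit motifs in bin 0", {
  set.seed(77)
  motif <- "ATTTCA"
  n <- 30
  seqs <- vapply(1:n, function(i) {
    s <- random_dna_str(80)
    s <- gsub(motif, "GGGGGG", s, fixed = TRUE)
    substr(s, 41, 46) <- motif   # motif start at 0-based offset 40
    s
  }, "")
  genome <- stats::setNames(seqs, paste0("chr", 1:n))
  cl <- data.frame(cluster_id = paste0("k", 1:n),
                   chrom = paste0("chr", 1:n), strand = "+",
                   start = 0L, end = 80L, n_reads = 2L,
                   summit = 40L, annotation = "3UTR", gene_id = "g")
  utr_pool <- vapply(1:50, function(i) random_dna_str(200), "")
  prof <- positional_seed_profile(cl, motif, genome, utr_pool,
                                  n_shuffles = 5)
  expect_equal(unname(prof$observed[as.character(0)]), n)
  expect_true(all(prof$observed[names(prof$observed) != "0"] == 0))
  expect_gte(prof$enrichment[["0"]], 3)
  # absent motif: flat zero observed histogram
  prof0 <- positional_seed_profile(cl, "ACATGGGA", genome, utr_pool,
                                   n_shuffles = 2)
  expect_true(all(prof0$observed == 0))
  expect_error(positional_seed_profile(cl, motif, genome, utr_pool,
                                       n_shuffles = 0), "n_shuffles")
})
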