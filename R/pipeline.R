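# Orchestration: simulate -> quantify -> CLIP -> meta-analysis in one
# reproducible run with a machine-readable report.

#' Quantify 3Seq libraries from per-position 3'-end counts
#'
#' Pools all libraries for peak calling, flags internal-priming peaks
#' against the genome, and sums per-library counts of clean 3'UTR peaks
#' into transcript counts.
#'
#' @param end_sites long data.frame `chrom`, `strand`, `pos`, `lib`,
#'   `count` (one row per library and position).
#' @param models gene-model table.
#' @param genome named character vector of chromosome sequences.
#' @param merge_distance peak-calling merge distance in nt (default 10).
#' @return list `peaks` (with `internal_priming` flag), `counts`
#'   (gene x library matrix).
#' @export
quantify_3seq <- function(end_sites, models, genome, merge_distance = 10L) {
  pooled <- stats::aggregate(count ~ chrom + strand + pos, data = end_sites,
                             FUN = sum)
  peaks <- call_3p_peaks(pooled, merge_distance)
  peaks$internal_priming <- filter_internal_priming(peaks, genome)
  libs <- sort(unique(end_sites$lib))
  # per-library counts per peak: assign each position to its peak span
  pk <- bed_to_granges(peaks$chrom, peaks$start, peaks$end, peaks$strand)
  pos <- GenomicRanges::GRanges(end_sites$chrom,
                                IRanges::IRanges(end_sites$pos + 1L,
                                                 width = 1L),
                                strand = end_sites$strand)
  hits <- GenomicRanges::findOverlaps(pos, pk, select = "first")
  lib_counts <- matrix(0, nrow = nrow(peaks), ncol = length(libs),
                       dimnames = list(NULL, libs))
  ok <- !is.na(hits)
  if (any(ok)) {
    agg <- stats::aggregate(end_sites$count[ok],
                            by = list(peak = hits[ok],
                                      lib = end_sites$lib[ok]),
                            FUN = sum)
    lib_counts[cbind(agg$peak, match(agg$lib, libs))] <- agg$x
  }
  counts <- transcript_counts(peaks, models, lib_counts = lib_counts)
  list(peaks = peaks, counts = counts)
}

count_dataset_log2fc <- function(counts, min_count, min_libs,
                                 wt_libs, ko_libs) {
  kept <- filter_min_reads(counts, min_count, min_libs)
  r <- rpm(kept)
  log2fc(r[, ko_libs, drop = FALSE], r[, wt_libs, drop = FALSE])
}

#' Run the full synthetic study end to end
#'
#' Simulates a study from `config`, quantifies the count-based libraries
#' through the 3'-end and CDS-count paths, runs the CLIP stage (cluster
#' calling, annotation, per-miRNA site prediction over the top-expressed
#' miRNAs, positional seed profile), runs the expression meta-analysis
#' (sign-consistent candidates, seed enrichment with controls, rank
#' metric, CDF-shift tests, high-confidence set), and evaluates the
#' result against the planted truth.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all intermediates are
#'   persisted (FASTA/BED/TSV) together with a JSON report.
#' @param utr3_extension CLIP annotation 3'UTR extension in nt
#'   (default 5000).
#' @param top_mirna_fraction cumulative abundance fraction defining the
#'   scanned miRNA set (default 0.90).
#' @param n_shuffles background replicates for the positional profile
#'   (default 10).
#' @param run_motif_discovery run exhaustive 8mer enrichment on the
#'   candidate UTRs (default TRUE).
#' @param verbose log per-stage record counts via [message()].
#' @return a `run_report` list; see Details in the package vignette.
#' @export
run_all <- function(config, out_dir = NULL, utr3_extension = 5000L,
                    top_mirna_fraction = 0.90, n_shuffles = 10L,
                    run_motif_discovery = TRUE, verbose = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  say <- function(...) if (verbose) message("[mirmeta] ", ...)
  mirna_db <- default_mirna_db()
  mirna_db[config$mirna_name] <- config$mirna_seq

  say("simulate: drawing truth and sequences")
  truth <- simulate_truth(config)
  seqs <- emit_sequences(truth, config)
  panel <- emit_expression_panel(truth, config, mirna_db)
  end_sites <- emit_3p_end_sites(panel$counts$seq3, seqs$models, config)
  clip_reads <- emit_clip_reads(truth, config, seqs)
  say("simulate: ", config$n_genes, " genes, ",
      sum(truth$is_true_target), " true targets, ",
      nrow(clip_reads), " CLIP reads")

  say("quant: 3'-end peak calling and library quantification")
  q3 <- quantify_3seq(end_sites, seqs$models, seqs$genome)
  say("quant: ", nrow(q3$peaks), " peaks (",
      sum(q3$peaks$internal_priming), " internal-priming flagged)")
  wt <- c("wt1", "wt2"); ko <- c("ko1", "ko2")
  lfc_3seq <- count_dataset_log2fc(q3$counts, 10L, 2L, wt, ko)
  lfc_ribo <- count_dataset_log2fc(panel$counts$ribo, 50L, 2L, wt, ko)

  # translation efficiency per genotype from the same filtered tables
  kept3 <- filter_min_reads(q3$counts, 10L, 2L)
  keptr <- filter_min_reads(panel$counts$ribo, 50L, 2L)
  r3 <- rpm(kept3); rr <- rpm(keptr)
  te_wt <- translation_efficiency(rowMeans(r3[, wt]), rowMeans(rr[, wt]))
  te_ko <- translation_efficiency(rowMeans(r3[, ko]), rowMeans(rr[, ko]))
  dte <- delta_te(te_ko, te_wt)
  target_dte <- dte$delta_te[dte$gene_id %in%
                               truth$gene_id[truth$is_true_target]]

  say("quant: small-RNA counting and top-expressed miRNAs")
  mir_kept <- filter_min_reads(panel$counts$smallrna, 50L, 2L)
  mir_rpm <- rowMeans(rpm(mir_kept)[, wt, drop = FALSE])
  top_mirs <- top_expressed_mirnas(mir_rpm, top_mirna_fraction)
  say("quant: ", length(top_mirs), " miRNAs cover ",
      round(100 * top_mirna_fraction), "% of WT miRNA reads")

  say("clip: collapsing, clustering, annotating")
  collapsed <- collapse_duplicates(clip_reads)
  clusters <- call_clusters(collapsed)
  clusters <- annotate_clusters(clusters, seqs$models, utr3_extension)
  scan_set <- mirna_db[intersect(names(mirna_db), top_mirs)]
  if (!config$mirna_name %in% names(scan_set)) {
    scan_set[config$mirna_name] <- config$mirna_seq
  }
  sites <- predict_target_sites(clusters, scan_set, seqs$genome)
  focal_sites <- sites[sites$mirna == config$mirna_name, , drop = FALSE]
  clip_targets <- unique(focal_sites$gene_id)
  say("clip: ", nrow(clusters), " clusters (",
      sum(clusters$annotation == "3UTR"), " 3'UTR), ",
      nrow(focal_sites), " focal-miRNA sites in ",
      length(clip_targets), " genes")
  set.seed(config$rng_seed + 6L)
  profile <- positional_seed_profile(
    clusters, seed_site_motif(config$mirna_seq, 6L), seqs$genome,
    seqs$utrs, n_shuffles = n_shuffles)

  say("meta: sign-consistent candidates and seed enrichment")
  lof_keep <- vapply(panel$datasets, function(d) {
    d$direction_class == "LOF" && !d$name %in% c("lof_riboseq", "lof_3seq")
  }, logical(1))
  lof_list <- c(panel$datasets[lof_keep],
                list(expression_dataset("lof_riboseq_counts", "LOF",
                                        lfc_ribo),
                     expression_dataset("lof_3seq_counts", "LOF",
                                        lfc_3seq)))
  gof_list <- panel$datasets[vapply(panel$datasets, function(d) {
    d$direction_class == "GOF"
  }, logical(1))]
  mp <- meta_panel(lof_list, gof_list)
  mr <- sign_consistent_candidates(mp)
  seed_classes <- classify_seed_classes(seqs$utrs[mp$universe],
                                        config$mirna_seq)
  candidates <- mr$gene_id[mr$candidate]
  set.seed(config$rng_seed + 7L)
  enrichment <- seed_enrichment(candidates, seed_classes, mp$universe,
                                anti_set = mr$gene_id[mr$anti_candidate])
  metric <- rank_correlation_metric(mp)
  cdf_tests <- lapply(c(mp$lof, mp$gof), function(d) {
    cdf_shift_tests(d, seed_classes)
  })
  names(cdf_tests) <- vapply(c(mp$lof, mp$gof), function(d) d$name, "")
  hc <- high_confidence_targets(mr, seed_classes, clip_targets)
  say("meta: ", length(mp$universe), " universe genes, ",
      length(candidates), " candidates, ", length(hc),
      " high-confidence targets")

  motif_table <- NULL
  planted_motif_rank <- NA_integer_
  if (run_motif_discovery && length(candidates) > 0L) {
    say("meta: de novo 8mer motif enrichment over candidate UTRs")
    fg <- seqs$utrs[candidates]
    set.seed(config$rng_seed + 8L)
    bg <- vapply(fg, dinucleotide_shuffle, "", USE.NAMES = FALSE)
    motif_table <- motif_enrichment(fg, bg, 8L)
    planted_motif_rank <-
      match(seed_site_motif(config$mirna_seq, 8L), motif_table$motif)
  }

  evaluation <- evaluate_against_truth(hc, truth)
  recovery <- clip_site_recovery(truth, focal_sites)
  seeded_cand <- candidates[seed_classes$seed_class[
    match(candidates, seed_classes$gene_id)] %in% c("7mer", "8mer")]

  report <- list(
    package_version = as.character(utils::packageVersion("mirmeta")),
    rng_seed = config$rng_seed,
    config = unclass(config),
    counts = list(
      n_genes = config$n_genes,
      n_true_targets = sum(truth$is_true_target),
      clip_reads = nrow(clip_reads),
      clip_reads_collapsed = nrow(collapsed),
      peaks = nrow(q3$peaks),
      peaks_internal_priming = sum(q3$peaks$internal_priming),
      clusters = nrow(clusters),
      clusters_3utr = sum(clusters$annotation == "3UTR"),
      top_mirnas = length(top_mirs),
      focal_sites = nrow(focal_sites),
      focal_site_genes = length(clip_targets),
      universe = length(mp$universe),
      up_in_all_lof = sum(mr$up_in_all_lof),
      down_in_all_gof = sum(mr$down_in_all_gof),
      candidates = length(candidates),
      candidates_with_seed = length(seeded_cand),
      high_confidence = length(hc)
    ),
    enrichment = enrichment,
    cdf_tests = cdf_tests,
    rank_metric = metric,
    median_delta_te_targets = stats::median(target_dte),
    clip_site_recovery = recovery,
    profile = profile,
    profile_bin0_enrichment =
      unname(profile$enrichment[as.character(0)]),
    planted_motif_rank = planted_motif_rank,
    motif_top = if (!is.null(motif_table)) utils::head(motif_table, 5L),
    high_confidence_targets = hc,
    evaluation = evaluation
  )
  # count-chain sanity
  stopifnot(report$counts$high_confidence <=
              report$counts$candidates_with_seed,
            report$counts$candidates_with_seed <=
              report$counts$candidates,
            report$counts$candidates <= report$counts$universe)

  if (!is.null(out_dir)) {
    persist_run(out_dir, truth, seqs, panel, end_sites, clip_reads,
                clusters, sites, mp, mr, seed_classes, metric, enrichment,
                report)
  }
  class(report) <- "run_report"
  report
}

#' Precision and recall of a predicted target set against planted truth
#'
#' @param targets character vector of predicted (high-confidence) gene
#'   ids.
#' @param truth a [simulate_truth()] result.
#' @return list `precision` (`NA` when no predictions), `recall` (`NA`
#'   when no true targets), `n_predicted`, `n_true`,
#'   `recall_by_class` (named over 8/7/6mer).
#' @export
evaluate_against_truth <- function(targets, truth) {
  true_genes <- truth$gene_id[truth$is_true_target]
  tp <- intersect(targets, true_genes)
  by_class <- vapply(c("8mer", "7mer", "6mer"), function(cc) {
    g <- truth$gene_id[truth$is_true_target & truth$seed_class == cc]
    if (length(g) == 0L) return(NA_real_)
    length(intersect(targets, g)) / length(g)
  }, 0)
  list(precision = if (length(targets)) length(tp) / length(targets)
       else NA_real_,
       recall = if (length(true_genes)) length(tp) / length(true_genes)
       else NA_real_,
       n_predicted = length(targets),
       n_true = length(true_genes),
       recall_by_class = by_class)
}

#' Fraction of planted sites recovered with correct miRNA assignment
#'
#' A planted site counts as recovered when its gene appears in the
#' focal-miRNA site table, i.e. a 3'UTR-annotated cluster on that gene
#' contained the focal seed.
#'
#' @param truth a [simulate_truth()] result.
#' @param focal_sites site table restricted to the focal miRNA.
#' @return fraction in `[0, 1]` (`NA` when no sites were planted).
#' @export
clip_site_recovery <- function(truth, focal_sites) {
  tg <- truth$gene_id[truth$is_true_target]
  if (length(tg) == 0L) return(NA_real_)
  mean(tg %in% focal_sites$gene_id)
}

#' Null calibration of the sign-consistency candidate logic
#'
#' Repeatedly generates a panel with no planted effects (pure
#' `N(0, noise_sd)` log2 fold changes) over a fixed gene universe and
#' records the candidate count and the candidate-set seed-enrichment
#' p-value. Under the null the candidate count is Binomial(n_genes,
#' 2^-(n_lof + n_gof)) and the enrichment p is (conservatively)
#' uniform.
#'
#' @param seed_classes data.frame or named vector of per-gene seed
#'   classes defining the universe.
#' @param n_runs number of runs (default 200).
#' @param n_lof,n_gof panel sizes (defaults 3, 2).
#' @param noise_sd log2 noise SD (default 0.25).
#' @param rng_seed seed for the whole calibration.
#' @return data.frame `run`, `n_candidates`, `enrichment_p`.
#' @export
null_candidate_calibration <- function(seed_classes, n_runs = 200L,
                                       n_lof = 3L, n_gof = 2L,
                                       noise_sd = 0.25, rng_seed = 1L) {
  if (is.data.frame(seed_classes)) {
    seed_classes <- stats::setNames(seed_classes$seed_class,
                                    seed_classes$gene_id)
  }
  genes <- names(seed_classes)
  n <- length(genes)
  set.seed(rng_seed)
  out <- lapply(seq_len(n_runs), function(run) {
    mk <- function(nm, dir) {
      expression_dataset(nm, dir,
                         stats::setNames(stats::rnorm(n, 0, noise_sd),
                                         genes))
    }
    mp <- meta_panel(lapply(seq_len(n_lof),
                            function(i) mk(paste0("lof", i), "LOF")),
                     lapply(seq_len(n_gof),
                            function(i) mk(paste0("gof", i), "GOF")))
    mr <- sign_consistent_candidates(mp)
    cand <- mr$gene_id[mr$candidate]
    enr <- seed_enrichment(cand, seed_classes, genes)
    data.frame(run = run, n_candidates = length(cand),
               enrichment_p = enr$p[enr$set == "candidates"])
  })
  do.call(rbind, out)
}

persist_run <- function(out_dir, truth, seqs, panel, end_sites, clip_reads,
                        clusters, sites, mp, mr, seed_classes, metric,
                        enrichment, report) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_fasta(seqs$utrs, fp("utr3.fa"))
  write_fasta(seqs$genome, fp("genome.fa"))
  write_bed12(seqs$models, fp("gene_models.bed"))
  write_bed6(clip_reads, fp("clip_reads.bed"))
  write_bed6(data.frame(chrom = clusters$chrom, start = clusters$start,
                        end = clusters$end, name = clusters$annotation,
                        score = clusters$n_reads,
                        strand = clusters$strand),
             fp("clip_clusters.bed"))
  for (nm in names(panel$counts)) {
    write_tsv_matrix(panel$counts[[nm]], fp(paste0("counts_", nm, ".tsv")),
                     id_col = if (nm == "smallrna") "mirna" else "gene_id")
  }
  for (d in c(mp$lof, mp$gof)) {
    write_tsv_matrix(matrix(d$log2fc, ncol = 1L,
                            dimnames = list(names(d$log2fc), "log2fc")),
                     fp(paste0("log2fc_", d$name, ".tsv")))
  }
  utils::write.table(sites, fp("clip_sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(merge(mr, seed_classes, by = "gene_id"),
                     fp("meta_result.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(metric, fp("rank_metric.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(enrichment, fp("enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth, fp("sim_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  slim <- report
  slim$rank_metric <- NULL
  slim$profile <- list(bins = report$profile$bins,
                       observed = report$profile$observed,
                       enrichment = report$profile$enrichment)
  jsonlite::write_json(slim, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}
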