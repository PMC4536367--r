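# Seeded synthetic-study generator: a complete miRNA loss/gain-of-function
# study (sequences, gene models, expression panel, count tables, CLIP
# reads) with known planted ground truth.

# mature sequence of the focal miRNA used by the default configuration
# (mmu-miR-203-3p, miRBase); bundled with the package in
# inst/extdata/mature_mirnas.fa together with other abundant skin miRNAs
MIR203_SEQ <- "GUGAAAUGUUUAGGACCACUAG"

#' Default mature-miRNA database bundled with the package
#'
#' A small set of abundant mouse skin miRNAs (miRBase mature sequences),
#' read from `inst/extdata/mature_mirnas.fa`.
#'
#' @return named character vector of DNA-space sequences.
#' @export
default_mirna_db <- function() {
  read_fasta(system.file("extdata", "mature_mirnas.fa", package = "mirmeta",
                         mustWork = TRUE))
}

#' Configuration of the synthetic study
#'
#' Defaults approximate the shape of a mouse epidermis miRNA
#' loss/gain-of-function study: ~6,000 genes detectable across all
#' datasets, ~300 true targets, three LOF and two GOF expression
#' datasets, count-based libraries of 2e6 reads with 2 replicates per
#' condition, and CLIP coverage of ~10 reads per bound site.
#'
#' @param n_genes number of genes.
#' @param n_true_targets number of true targets (`<= n_genes`).
#' @param seed_class_mix named proportions over `8mer`, `7mer`, `6mer`
#'   (sum to 1).
#' @param utr_len_range 3'UTR length range in nt.
#' @param gc_content background GC fraction in (0, 1).
#' @param lof_effect_mean,gof_effect_mean planted |log2FC| for an 8mer
#'   target in LOF / GOF datasets; `gof_effect_mean >= lof_effect_mean
#'   >= 0` (knockout perturbs transcripts less than induction).
#' @param class_effect_scalars effect multipliers, 8mer > 7mer > 6mer.
#' @param noise_sd per-dataset log2 measurement noise SD.
#' @param n_lof_datasets,n_gof_datasets panel sizes (defaults 3 and 2).
#' @param clip_reads_per_site CLIP reads emitted per planted site.
#' @param clip_background_rate background CLIP reads per kb of genome.
#' @param clip_summit_jitter max nt a site read's centre deviates from
#'   the site centre.
#' @param library_depth reads per count-based library.
#' @param decoy_free if `TRUE`, non-target UTRs are rejection-sampled to
#'   carry no 6mer-or-longer site for the focal miRNA; the default
#'   `FALSE` leaves chance ("decoy") seeds in, giving enrichment tests a
#'   realistic null.
#' @param utr5_len,cds_len fixed 5'UTR and CDS lengths in nt.
#' @param intergenic_gap nt between consecutive gene loci (kept larger
#'   than the 5-kb 3'UTR annotation extension so extensions do not spill
#'   onto neighbouring loci).
#' @param mirna_name,mirna_seq focal miRNA (default mmu-miR-203-3p).
#' @param rng_seed integer seed; all emitters derive their streams from
#'   it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 6000L,
                       n_true_targets = 300L,
                       seed_class_mix = c("8mer" = 0.4, "7mer" = 0.4,
                                          "6mer" = 0.2),
                       utr_len_range = c(200L, 1200L),
                       gc_content = 0.5,
                       lof_effect_mean = 0.5,
                       gof_effect_mean = 1.0,
                       class_effect_scalars = c("8mer" = 1.0,
                                                "7mer" = 0.75,
                                                "6mer" = 0.5),
                       noise_sd = 0.25,
                       n_lof_datasets = 3L,
                       n_gof_datasets = 2L,
                       clip_reads_per_site = 10L,
                       clip_background_rate = 0.05,
                       clip_summit_jitter = 15L,
                       library_depth = 2e6,
                       decoy_free = FALSE,
                       utr5_len = 150L,
                       cds_len = 300L,
                       intergenic_gap = 6000L,
                       mirna_name = "mmu-miR-203-3p",
                       mirna_seq = MIR203_SEQ,
                       rng_seed = 101L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_true_targets = as.integer(n_true_targets),
              seed_class_mix = seed_class_mix,
              utr_len_range = as.integer(utr_len_range),
              gc_content = gc_content,
              lof_effect_mean = lof_effect_mean,
              gof_effect_mean = gof_effect_mean,
              class_effect_scalars = class_effect_scalars,
              noise_sd = noise_sd,
              n_lof_datasets = as.integer(n_lof_datasets),
              n_gof_datasets = as.integer(n_gof_datasets),
              clip_reads_per_site = as.integer(clip_reads_per_site),
              clip_background_rate = clip_background_rate,
              clip_summit_jitter = as.integer(clip_summit_jitter),
              library_depth = library_depth,
              decoy_free = isTRUE(decoy_free),
              utr5_len = as.integer(utr5_len),
              cds_len = as.integer(cds_len),
              intergenic_gap = as.integer(intergenic_gap),
              mirna_name = mirna_name,
              mirna_seq = as_dna(mirna_seq),
              rng_seed = as.integer(rng_seed))
  err <- function(...) stop("invalid sim_config: ", ..., call. = FALSE)
  if (cfg$n_genes < 1L || cfg$n_true_targets < 0L) err("negative counts")
  if (cfg$n_true_targets > cfg$n_genes) err("n_true_targets > n_genes")
  if (any(cfg$seed_class_mix < 0) ||
      abs(sum(cfg$seed_class_mix) - 1) > 1e-8) {
    err("seed_class_mix must be proportions summing to 1")
  }
  if (!all(c("8mer", "7mer", "6mer") %in% names(cfg$seed_class_mix))) {
    err("seed_class_mix needs names 8mer/7mer/6mer")
  }
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1) err("gc_content not in (0,1)")
  if (!(cfg$gof_effect_mean >= cfg$lof_effect_mean &&
        cfg$lof_effect_mean >= 0)) {
    err("need gof_effect_mean >= lof_effect_mean >= 0")
  }
  if (cfg$noise_sd < 0) err("negative noise_sd")
  if (cfg$utr_len_range[1L] < 30L || diff(cfg$utr_len_range) < 0L) {
    err("utr_len_range too short to host a site")
  }
  if (cfg$n_lof_datasets < 1L || cfg$n_gof_datasets < 1L) {
    err("need at least one LOF and one GOF dataset")
  }
  structure(cfg, class = "sim_config")
}

largest_remainder_counts <- function(props, total) {
  raw <- props * total
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0L) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1L
  }
  as.integer(base)
}

#' Draw the synthetic ground truth
#'
#' Selects which genes are true targets, their seed class (honouring
#' `seed_class_mix` up to rounding), one planted 3'UTR site position per
#' target, and the planted LOF/GOF effect sizes
#' (`effect_mean * class_effect_scalars[class]`, log2 units).
#'
#' @param config a [sim_config()].
#' @return data.frame of class `sim_truth`: `gene_id`, `is_true_target`,
#'   `seed_class`, `utr_len`, `site_pos` (0-based offset in the 3'UTR,
#'   `NA` for non-targets), `planted_lof_effect`, `planted_gof_effect`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed + 1L)
  n <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))
  utr_len <- if (diff(config$utr_len_range) == 0L) {
    rep(config$utr_len_range[1L], n)
  } else {
    sample(config$utr_len_range[1L]:config$utr_len_range[2L], n,
           replace = TRUE)
  }
  truth <- data.frame(gene_id = gene_id,
                      is_true_target = FALSE,
                      seed_class = "none",
                      utr_len = utr_len,
                      site_pos = NA_integer_,
                      planted_lof_effect = 0,
                      planted_gof_effect = 0,
                      stringsAsFactors = FALSE)
  if (config$n_true_targets > 0L) {
    tgt <- sort(sample.int(n, config$n_true_targets))
    mix <- config$seed_class_mix[c("8mer", "7mer", "6mer")]
    cnt <- largest_remainder_counts(mix, config$n_true_targets)
    cls <- sample(rep(c("8mer", "7mer", "6mer"), cnt))
    k <- as.integer(substr(cls, 1L, 1L))
    truth$is_true_target[tgt] <- TRUE
    truth$seed_class[tgt] <- cls
    # keep sites away from the UTR edges so flanking rejection rules and
    # CLIP read placement have room
    truth$site_pos[tgt] <- vapply(seq_along(tgt), function(i) {
      lo <- 10L
      hi <- truth$utr_len[tgt[i]] - k[i] - 10L
      if (hi < lo) stop("3'UTR too short to host a planted site",
                        call. = FALSE)
      sample(lo:hi, 1L)
    }, 0L)
    sc <- config$class_effect_scalars[cls]
    truth$planted_lof_effect[tgt] <- config$lof_effect_mean * sc
    truth$planted_gof_effect[tgt] <- config$gof_effect_mean * sc
  }
  class(truth) <- c("sim_truth", "data.frame")
  truth
}

random_dna <- function(n_nt, gc) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n_nt, replace = TRUE, prob = prob),
        collapse = "")
}

#' Emit 3'UTR sequences, gene models and a synthetic genome
#'
#' Every planted site position carries the exact motif of its class, and
#' rejection sampling guarantees that a target gene's 3'UTR classifies to
#' exactly its planted class (no accidental longer site). With
#' `decoy_free = TRUE` non-target UTRs carry no 6mer-or-longer site at
#' all; by default chance seeds are left in place. Gene loci (5'UTR,
#' CDS, 3'UTR; single exon) are laid out on four synthetic chromosomes
#' with mixed strands and `intergenic_gap` spacers.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the matching [sim_config()].
#' @return list: `utrs` (named character, sense 3'UTR sequences),
#'   `genome` (named character, chromosome sequences), `models`
#'   (gene-model table).
#' @export
emit_sequences <- function(truth, config) {
  set.seed(config$rng_seed + 2L)
  n <- nrow(truth)
  gc <- config$gc_content
  mir <- config$mirna_seq
  motifs <- c("8mer" = seed_site_motif(mir, 8L),
              "7mer" = seed_site_motif(mir, 7L),
              "6mer" = seed_site_motif(mir, 6L))
  utrs <- character(n)
  for (i in seq_len(n)) {
    len <- truth$utr_len[i]
    cls <- truth$seed_class[i]
    for (attempt in seq_len(100L)) {
      s <- random_dna(len, gc)
      if (truth$is_true_target[i]) {
        motif <- motifs[[cls]]
        p <- truth$site_pos[i]
        substr(s, p + 1L, p + nchar(motif)) <- motif
        if (classify_seed_class(s, mir) == cls) break
      } else if (config$decoy_free) {
        if (classify_seed_class(s, mir) == "none") break
      } else {
        break
      }
      if (attempt == 100L) stop("rejection sampling failed", call. = FALSE)
    }
    utrs[i] <- s
  }
  names(utrs) <- truth$gene_id

  # lay out loci: 4 chromosomes, round-robin-free contiguous blocks
  chrom_of <- paste0("chrS", cut(seq_len(n), 4L, labels = FALSE))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gap <- config$intergenic_gap
  u5 <- config$utr5_len
  cds <- config$cds_len
  genome <- list()
  models <- vector("list", n)
  for (ch in unique(chrom_of)) {
    idx <- which(chrom_of == ch)
    segs <- character(2L * length(idx) + 1L)
    offset <- 0L
    si <- 1L
    for (i in idx) {
      segs[si] <- random_dna(gap, gc)
      offset <- offset + gap
      si <- si + 1L
      tx <- paste0(random_dna(u5, gc), random_dna(cds, gc), utrs[i])
      tx_len <- nchar(tx)
      segs[si] <- if (strand[i] == "+") tx else revcomp(tx)
      if (strand[i] == "+") {
        cds_start <- offset + u5
      } else {
        cds_start <- offset + truth$utr_len[i]
      }
      models[[i]] <- data.frame(gene_id = truth$gene_id[i], chrom = ch,
                                strand = strand[i],
                                tx_start = offset, tx_end = offset + tx_len,
                                cds_start = cds_start,
                                cds_end = cds_start + cds,
                                stringsAsFactors = FALSE)
      offset <- offset + tx_len
      si <- si + 1L
    }
    segs[si] <- random_dna(gap, gc)
    genome[[ch]] <- paste(segs[seq_len(si)], collapse = "")
  }
  models <- gene_models(do.call(rbind, models))
  list(utrs = utrs, genome = unlist(genome), models = models)
}

# genomic start of a planted site (0-based), strand-aware
site_genomic_start <- function(model, site_pos, k) {
  if (model$strand == "+") {
    model$cds_end + site_pos
  } else {
    model$cds_start - site_pos - k
  }
}
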