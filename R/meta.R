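# Expression meta-analysis: sign-consistent candidate intersection across
# loss- and gain-of-function datasets, hypergeometric seed enrichment with
# negative controls, rank-sum correlation metric, one-sided K-S CDF-shift
# tests, and the final meta + CLIP high-confidence target set.

#' Construct an expression dataset (one comparison's log2 fold changes)
#'
#' @param name dataset label.
#' @param direction_class `"LOF"` (knockout vs wild type; targets
#'   expected up), `"GOF"` (induced vs uninduced; targets expected down)
#'   or `"OTHER"`.
#' @param log2fc named numeric vector of finite per-gene log2 fold
#'   changes (names = gene ids, unique).
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(name, direction_class, log2fc) {
  stopifnot(direction_class %in% c("LOF", "GOF", "OTHER"),
            !is.null(names(log2fc)), !anyDuplicated(names(log2fc)),
            all(is.finite(log2fc)))
  structure(list(name = name, direction_class = direction_class,
                 log2fc = log2fc),
            class = "expression_dataset")
}

#' Assemble a meta-analysis panel
#'
#' The universe is the intersection of gene ids detected in every
#' dataset; genes missing anywhere are dropped, never imputed as zero.
#'
#' @param lof_datasets list of LOF [expression_dataset()] objects.
#' @param gof_datasets list of GOF [expression_dataset()] objects.
#' @return object of class `meta_panel` with elements `lof`, `gof`,
#'   `universe`.
#' @export
meta_panel <- function(lof_datasets, gof_datasets) {
  stopifnot(length(lof_datasets) >= 1L, length(gof_datasets) >= 1L)
  all_ds <- c(lof_datasets, gof_datasets)
  if (!all(vapply(lof_datasets, function(d) d$direction_class, "") == "LOF")) {
    stop("lof_datasets must all have direction_class LOF", call. = FALSE)
  }
  if (!all(vapply(gof_datasets, function(d) d$direction_class, "") == "GOF")) {
    stop("gof_datasets must all have direction_class GOF", call. = FALSE)
  }
  universe <- Reduce(intersect, lapply(all_ds, function(d) names(d$log2fc)))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  structure(list(lof = lof_datasets, gof = gof_datasets,
                 universe = universe),
            class = "meta_panel")
}

panel_matrix <- function(panel, which = c("lof", "gof")) {
  which <- match.arg(which)
  ds <- panel[[which]]
  m <- vapply(ds, function(d) d$log2fc[panel$universe],
              numeric(length(panel$universe)))
  m <- matrix(m, nrow = length(panel$universe),
              dimnames = list(panel$universe,
                              vapply(ds, function(d) d$name, "")))
  m
}

#' Sign-consistent candidate targets across a panel
#'
#' A gene is a candidate iff its log2 fold change is strictly positive in
#' every loss-of-function dataset and strictly negative in every
#' gain-of-function dataset (exact zeros never qualify).
#'
#' @param panel a [meta_panel()].
#' @return data.frame `gene_id`, `up_in_all_lof`, `down_in_all_gof`,
#'   `candidate`, `anti_candidate` (the positively correlated control
#'   set: down in all LOF and up in all GOF).
#' @export
sign_consistent_candidates <- function(panel) {
  lof <- panel_matrix(panel, "lof")
  gof <- panel_matrix(panel, "gof")
  up_lof <- rowSums(lof > 0) == ncol(lof)
  down_gof <- rowSums(gof < 0) == ncol(gof)
  data.frame(gene_id = panel$universe,
             up_in_all_lof = unname(up_lof),
             down_in_all_gof = unname(down_gof),
             candidate = unname(up_lof & down_gof),
             anti_candidate = unname(rowSums(lof < 0) == ncol(lof) &
                                       rowSums(gof > 0) == ncol(gof)),
             stringsAsFactors = FALSE, row.names = NULL)
}

hypergeom_upper_tail <- function(observed, n_draw, K, N) {
  if (n_draw == 0L) return(1)
  stats::phyper(observed - 1L, K, N - K, n_draw, lower.tail = FALSE)
}

#' Seed-match enrichment of a candidate gene set
#'
#' Tests whether candidates carry 7/8mer 3'UTR seed matches more often
#' than expected from the universe's seed distribution (hypergeometric
#' upper tail). Two negative controls are reported: a size-matched
#' uniformly random gene set from the universe (drawn from the current
#' RNG stream) and, if supplied, the anti-correlated gene set.
#'
#' @param candidates character vector of candidate gene ids.
#' @param seed_classes named character vector (gene -> seed class) or the
#'   data.frame from [classify_seed_classes()], covering the universe.
#' @param universe character vector of all detected gene ids.
#' @param anti_set optional character vector: the positively correlated
#'   control gene set.
#' @param seed_set which classes count as "seeded" (default 7/8mer).
#' @return data.frame with one row per set (`candidates`, `random`,
#'   `anti_correlated`): `n`, `with_seed`, `background_rate`, `fold`, `p`.
#' @export
seed_enrichment <- function(candidates, seed_classes, universe,
                            anti_set = NULL,
                            seed_set = c("7mer", "8mer")) {
  if (is.data.frame(seed_classes)) {
    seed_classes <- stats::setNames(seed_classes$seed_class,
                                    seed_classes$gene_id)
  }
  if (!all(universe %in% names(seed_classes))) {
    stop("seed class missing for some universe genes", call. = FALSE)
  }
  seeded <- universe[seed_classes[universe] %in% seed_set]
  N <- length(universe)
  K <- length(seeded)
  one_row <- function(set, label) {
    n <- length(set)
    obs <- sum(set %in% seeded)
    bg <- K / N
    data.frame(set = label, n = n, with_seed = obs,
               background_rate = bg,
               fold = if (n > 0L && bg > 0) (obs / n) / bg else NA_real_,
               p = hypergeom_upper_tail(obs, n, K, N),
               stringsAsFactors = FALSE)
  }
  rows <- list(one_row(intersect(candidates, universe), "candidates"))
  rnd <- universe[sample.int(N, min(length(candidates), N))]
  rows <- c(rows, list(one_row(rnd, "random")))
  if (!is.null(anti_set)) {
    rows <- c(rows, list(one_row(intersect(anti_set, universe),
                                 "anti_correlated")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ranked correlation-to-miRNA metric
#'
#' In every loss-of-function dataset genes are ranked with the most
#' upregulated gene first; in every gain-of-function dataset with the
#' most downregulated gene first. The per-dataset ranks are summed and
#' the sums ranked again, so rank 1 is the gene whose expression is most
#' consistently anti-correlated with the miRNA. Ties receive average
#' ranks at both stages.
#'
#' @param panel a [meta_panel()].
#' @return data.frame `gene_id`, `rank_sum`, `metric`.
#' @export
rank_correlation_metric <- function(panel) {
  lof <- panel_matrix(panel, "lof")
  gof <- panel_matrix(panel, "gof")
  r <- cbind(apply(-lof, 2L, rank, ties.method = "average"),
             apply(gof, 2L, rank, ties.method = "average"))
  rank_sum <- rowSums(r)
  data.frame(gene_id = panel$universe, rank_sum = unname(rank_sum),
             metric = unname(rank(rank_sum, ties.method = "average")),
             stringsAsFactors = FALSE, row.names = NULL)
}

# one-sided two-sample K-S statistic; alternative "greater" means x is
# stochastically greater than y (the CDF of x lies below that of y).
# Single sorted sweep over the pooled sample; ties handled by evaluating
# the CDF difference only at the last index of each distinct value.
ks_one_sided_D <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(x); m <- length(y)
  z <- c(x, y)
  step <- c(rep(1 / n, n), rep(-1 / m, m))
  o <- order(z)
  zs <- z[o]
  cs <- cumsum(step[o])              # = Fx(t) - Fy(t) within the sweep
  at_value <- c(zs[-1L] != zs[-length(zs)], TRUE)
  d <- cs[at_value]
  if (alternative == "greater") max(c(0, -d)) else max(c(0, d))
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' `alternative = "greater"` tests whether `x` is stochastically greater
#' than `y`. The p-value uses the asymptotic one-sided bound
#' `exp(-2 D^2 nm/(n+m))`; when the number of distinct label assignments
#' `choose(n+m, n)` is at most `exact_limit`, the exact permutation null
#' is enumerated instead.
#'
#' @param x,y numeric samples.
#' @param alternative `"greater"` or `"less"` (shift direction of `x`).
#' @param exact_limit maximum enumeration size (default 1e5).
#' @return list `D`, `p`, `method`.
#' @export
ks_test_one_sided <- function(x, y, alternative = c("greater", "less"),
                              exact_limit = 1e5) {
  alternative <- match.arg(alternative)
  n <- length(x); m <- length(y)
  D <- ks_one_sided_D(x, y, alternative)
  if (choose(n + m, n) <= exact_limit) {
    pool <- c(x, y)
    combos <- utils::combn(n + m, n)
    stat <- vapply(seq_len(ncol(combos)), function(j) {
      i <- combos[, j]
      ks_one_sided_D(pool[i], pool[-i], alternative)
    }, 0)
    p <- mean(stat >= D - 1e-12)
    method <- "exact"
  } else {
    p <- exp(-2 * D^2 * n * m / (n + m))
    method <- "asymptotic"
  }
  list(D = D, p = min(1, p), method = method)
}

#' CDF-shift tests of seed classes against the no-match class
#'
#' For each seed class, compares that class's log2 fold-change
#' distribution with the no-match class by a one-sided two-sample K-S
#' test in the direction implied by the dataset: in a GOF dataset seeded
#' genes are expected to shift down, in a LOF dataset up. Classes with
#' fewer than `min_n` genes are reported with `p = NA`.
#'
#' @param dataset an [expression_dataset()].
#' @param seed_classes named character vector or data.frame of per-gene
#'   seed classes.
#' @param min_n minimum class size (default 5).
#' @return data.frame `class`, `n`, `mean_log2fc`, `D`, `p`.
#' @export
cdf_shift_tests <- function(dataset, seed_classes, min_n = 5L) {
  if (is.data.frame(seed_classes)) {
    seed_classes <- stats::setNames(seed_classes$seed_class,
                                    seed_classes$gene_id)
  }
  genes <- intersect(names(dataset$log2fc), names(seed_classes))
  lfc <- dataset$log2fc[genes]
  cls <- seed_classes[genes]
  none <- lfc[cls == "none"]
  if (length(none) == 0L) stop("no-match class is empty", call. = FALSE)
  alt <- if (dataset$direction_class == "GOF") "less" else "greater"
  rows <- lapply(c("8mer", "7mer", "6mer"), function(cc) {
    x <- lfc[cls == cc]
    if (length(x) < min_n) {
      return(data.frame(class = cc, n = length(x),
                        mean_log2fc = if (length(x)) mean(x) else NA_real_,
                        D = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    kt <- ks_test_one_sided(x, none, alternative = alt)
    data.frame(class = cc, n = length(x), mean_log2fc = mean(x),
               D = kt$D, p = kt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(class = "none", n = length(none),
               mean_log2fc = mean(none), D = 0, p = NA_real_,
               stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' High-confidence targets: meta-analysis candidates bound by Ago2
#'
#' Candidates carrying a 7mer or 8mer 3'UTR seed match, intersected with
#' the genes that have a seed-containing 3'UTR CLIP cluster.
#'
#' @param meta_result data.frame from [sign_consistent_candidates()].
#' @param seed_classes named vector or data.frame of per-gene seed
#'   classes.
#' @param clip_targets character vector of CLIP-supported gene ids.
#' @return sorted character vector of gene ids.
#' @export
high_confidence_targets <- function(meta_result, seed_classes, clip_targets) {
  if (is.data.frame(seed_classes)) {
    seed_classes <- stats::setNames(seed_classes$seed_class,
                                    seed_classes$gene_id)
  }
  cand <- meta_result$gene_id[meta_result$candidate]
  seeded <- cand[seed_classes[cand] %in% c("7mer", "8mer")]
  sort(intersect(seeded, unique(clip_targets)))
}

#' Response of a target set in an independent perturbation dataset
#'
#' One-sided K-S comparison of the targets' log2 fold changes against
#' all other universe genes, plus the top-k targets ranked by log2 fold
#' change (descending for `alternative = "greater"`).
#'
#' @param dataset an [expression_dataset()].
#' @param targets character vector of target gene ids (nonempty,
#'   contained in the dataset).
#' @param alternative expected shift of the targets (default
#'   `"greater"`, i.e. upregulated).
#' @param top_k rows of the ranked table (default 20).
#' @return list `n_targets`, `n_background`, `D`, `p`, `top` (data.frame
#'   `gene_id`, `log2fc`).
#' @export
target_response <- function(dataset, targets,
                            alternative = c("greater", "less"),
                            top_k = 20L) {
  alternative <- match.arg(alternative)
  targets <- intersect(targets, names(dataset$log2fc))
  if (length(targets) == 0L) stop("empty target set", call. = FALSE)
  x <- dataset$log2fc[targets]
  y <- dataset$log2fc[setdiff(names(dataset$log2fc), targets)]
  kt <- ks_test_one_sided(x, y, alternative = alternative)
  ord <- order(if (alternative == "greater") -x else x)
  top <- data.frame(gene_id = names(x)[ord], log2fc = unname(x[ord]),
                    stringsAsFactors = FALSE)[seq_len(min(top_k, length(x))), ]
  list(n_targets = length(x), n_background = length(y),
       D = kt$D, p = kt$p, top = top)
}
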