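#' Two-sided permutation test on a difference of group means
#'
#' The observed statistic is `mean(x) - mean(y)`. The null distribution
#' relabels the pooled values: either exhaustively over all
#' `choose(nA+nB, nA)` assignments (automatic when that count is at
#' most `max_exhaustive`, default 10000, in which case the p value is
#' exact), or by `n_perm` random relabelings with the small-sample
#' correction `p = (1 + #{|null| >= |obs|}) / (n_perm + 1)`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param n_perm Number of random permutations (default 5000).
#' @param seed Optional seed for the sampled mode.
#' @param exhaustive `"auto"` (default), `TRUE` or `FALSE`.
#' @param max_exhaustive Enumeration cutoff for `"auto"`.
#' @return List with `observed_diff`, `p_perm`, `method`
#'   (`"exhaustive"` or `"sampled"`) and `n_used` (number of null
#'   relabelings).
#' @examples
#' permutation_test(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
permutation_test <- function(x, y, n_perm = 5000, seed = NULL,
                             exhaustive = "auto",
                             max_exhaustive = 10000) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2)
    stop("both groups need at least 2 observations")
  if (!is.null(seed)) set.seed(seed)
  z <- c(x, y)
  nA <- length(x); nB <- length(y); n <- nA + nB
  total <- sum(z)
  obs <- mean(x) - mean(y)
  tol <- 1e-12 * max(1, abs(obs))
  use_exh <- isTRUE(exhaustive) ||
    (identical(exhaustive, "auto") && choose(n, nA) <= max_exhaustive)
  if (use_exh) {
    combs <- combn(n, nA)
    sumsA <- colSums(matrix(z[combs], nrow = nA))
    diffs <- sumsA / nA - (total - sumsA) / nB
    p <- mean(abs(diffs) >= abs(obs) - tol)
    return(list(observed_diff = obs, p_perm = p,
                method = "exhaustive", n_used = ncol(combs)))
  }
  idx <- vapply(seq_len(n_perm), function(i) sample.int(n, nA),
                integer(nA))
  sumsA <- colSums(matrix(z[idx], nrow = nA))
  diffs <- sumsA / nA - (total - sumsA) / nB
  p <- (1 + sum(abs(diffs) >= abs(obs) - tol)) / (n_perm + 1)
  list(observed_diff = obs, p_perm = p, method = "sampled",
       n_used = n_perm)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (monotone, capped at 1), via
#' `stats::p.adjust(method = "BH")` after validating the input.
#'
#' @param pvals Numeric vector of raw p values in (0, 1].
#' @return Adjusted p values in the input order.
#' @export
fdr_adjust <- function(pvals) {
  if (!length(pvals)) stop("empty p-value list")
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stop("p values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Permutation comparison of every measure x band between two groups
#'
#' For each (measure, band) cell of the long metrics table, runs the
#' two-sided permutation test of group A minus group B means, then
#' adjusts the whole family (all measures x bands) by
#' Benjamini-Hochberg. Cells whose pooled values are constant carry no
#' randomness — the test cannot reject there — and are flagged
#' `degenerate` with `p_perm = 1` (on dense coherence graphs this
#' happens structurally for average degree and small-worldness; see the
#' vignette).
#'
#' @param metrics Long data.frame (`subject_id`, `band`, `measure`,
#'   `value`) from [cohort_metrics()].
#' @param covariates Data.frame with `subject_id` and `group` (exactly
#'   two levels).
#' @param config Pipeline configuration (permutation count, FDR level,
#'   seed).
#' @return Data.frame, one row per measure x band: `measure`, `band`,
#'   `mean_A`, `mean_B`, `observed_diff`, `p_perm`, `p_fdr`,
#'   `significant`, `degenerate`.
#' @export
compare_groups <- function(metrics, covariates,
                           config = default_config()) {
  lev <- unique(covariates$group)
  if (length(lev) != 2) stop("need exactly two group levels, got ",
                             length(lev))
  grp <- covariates$group[match(metrics$subject_id,
                                covariates$subject_id)]
  if (anyNA(grp)) stop("metrics contain subjects absent from covariates")
  set.seed(config$seed %||% 1)
  cells <- unique(metrics[, c("measure", "band")])
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- metrics$measure == cells$measure[i] &
      metrics$band == cells$band[i]
    vA <- metrics$value[sel & grp == lev[1]]
    vB <- metrics$value[sel & grp == lev[2]]
    if (!length(vA) || !length(vB))
      stop("missing metric rows for ", cells$measure[i], " x ",
           cells$band[i])
    if (var(c(vA, vB)) <= 0) {
      out[[i]] <- data.frame(measure = cells$measure[i],
                             band = cells$band[i],
                             mean_A = mean(vA), mean_B = mean(vB),
                             observed_diff = mean(vA) - mean(vB),
                             p_perm = 1, degenerate = TRUE,
                             stringsAsFactors = FALSE)
      next
    }
    pt <- permutation_test(vA, vB, n_perm = config$n_perm %||% 5000)
    out[[i]] <- data.frame(measure = cells$measure[i],
                           band = cells$band[i],
                           mean_A = mean(vA), mean_B = mean(vB),
                           observed_diff = pt$observed_diff,
                           p_perm = pt$p_perm, degenerate = FALSE,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$p_fdr <- fdr_adjust(res$p_perm)
  res$significant <- res$p_fdr < (config$fdr_level %||% 0.05) &
    !res$degenerate
  res[, c("measure", "band", "mean_A", "mean_B", "observed_diff",
          "p_perm", "p_fdr", "significant", "degenerate")]
}

#' Pearson correlation of graph measures with cognitive scores
#'
#' For each requested (measure, band) and each score column, computes
#' Pearson's r and its two-sided p value across subjects. P values are
#' reported unadjusted.
#'
#' @param metrics Long metrics table from [cohort_metrics()].
#' @param covariates Covariate table containing the score columns.
#' @param pairs Data.frame with columns `measure`, `band` selecting
#'   which graph measures to correlate.
#' @param scores Character vector of score column names in
#'   `covariates`.
#' @return Data.frame: `measure`, `band`, `score`, `r`, `p`.
#' @export
correlate_scores <- function(metrics, covariates, pairs, scores) {
  miss <- setdiff(scores, names(covariates))
  if (length(miss)) stop("score column(s) not found: ",
                         paste(miss, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    sel <- metrics$measure == pairs$measure[i] &
      metrics$band == pairs$band[i]
    v <- metrics$value[sel]
    ids <- metrics$subject_id[sel]
    ord <- match(covariates$subject_id, ids)
    v <- v[ord]
    if (anyNA(v)) stop("metric values missing for some subjects")
    if (var(v) <= 0) stop("constant metric vector: correlation undefined")
    for (s in scores) {
      y <- covariates[[s]]
      if (var(y) <= 0) stop("constant score vector: correlation undefined")
      ct <- cor.test(v, y, method = "pearson")
      out[[length(out) + 1]] <-
        data.frame(measure = pairs$measure[i], band = pairs$band[i],
                   score = s, r = unname(ct$estimate), p = ct$p.value,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
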