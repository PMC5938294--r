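#' ROC area under the curve for passage prediction
#'
#' AUC in the Mann-Whitney (pair-counting) form with ties credited 0.5,
#' oriented so that smaller size predicting passage counts as concordant,
#' with a DeLong asymptotic 95% confidence interval. Computed via
#' \pkg{pROC}.
#'
#' @param scores Numeric size estimates (larger = less likely to pass).
#' @param outcomes Character/factor vector with levels `"passed"` and
#'   `"not_passed"`.
#' @return List with `auc`, `ci95` (length-2), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, outcomes) {
  outcomes <- as.character(outcomes)
  if (!all(outcomes %in% c("passed", "not_passed")))
    stop("outcomes must be 'passed' or 'not_passed'", call. = FALSE)
  n_pos <- sum(outcomes == "passed")
  n_neg <- sum(outcomes == "not_passed")
  if (n_pos == 0L || n_neg == 0L)
    stop("undefined AUC: both outcome classes must be present", call. = FALSE)
  r <- pROC::roc(response = outcomes, predictor = as.numeric(scores),
                 levels = c("not_passed", "passed"), direction = ">",
                 quiet = TRUE)
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]),
    error = function(e) c(NA_real_, NA_real_))
  list(auc = as.numeric(pROC::auc(r)), ci95 = ci,
       n_pos = n_pos, n_neg = n_neg)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' @param a,b Paired measurement vectors (mm), equal length >= 2.
#' @return List with `bias` (mean of `a - b`) and `loa`
#'   (`bias +/- 1.96 * SD(a - b)`, sample SD).
#' @examples
#' bland_altman(c(4.0, 5.4), c(4.0, 5.0))
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    stop("invalid input: `a` and `b` must have equal length", call. = FALSE)
  if (length(a) < 2L)
    stop("invalid input: need at least 2 pairs", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s))
}

#' Bin percentage-point differences
#'
#' Bins per-stone probability spreads into `<20`, `20-40`, `40-60`,
#' `60-80` and `>80` ppt. Bins are half-open on the right (a spread of
#' exactly 20 ppt falls in `20-40`); the last bin includes 100.
#'
#' @param differences Numeric vector of ppt values in \[0, 100\].
#' @return Named numeric vector of bin fractions summing to 1.
#' @export
ppt_bins <- function(differences) {
  if (any(differences < 0 | differences > 100))
    stop("invalid input: ppt values must lie in [0, 100]", call. = FALSE)
  labs <- c("<20", "20-40", "40-60", "60-80", ">80")
  b <- cut(differences, breaks = c(0, 20, 40, 60, 80, Inf), right = FALSE,
           labels = labs, include.lowest = TRUE)
  tab <- table(b) / length(differences)
  stats::setNames(as.numeric(tab), labs)
}

#' Friedman's rank test
#'
#' Within-subject mid-ranks, chi-square statistic with tie correction and
#' `k - 1` degrees of freedom. For fewer than `perm_below` subjects the
#' chi-square approximation is replaced by a within-row Monte-Carlo
#' permutation p-value.
#'
#' @param values Numeric matrix, `n` subjects x `k` treatments.
#' @param perm_below Use the permutation p-value when `n < perm_below`
#'   (default 8).
#' @param n_perm Number of Monte-Carlo permutations, default 2000.
#' @param seed Seed for the permutation draw, default 0.
#' @return List with `statistic`, `p_value`, `df`, and `method`.
#' @export
friedman_rank_test <- function(values, perm_below = 8, n_perm = 2000,
                               seed = 0) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L)
    stop("invalid input: need >= 2 subjects and >= 2 treatments",
         call. = FALSE)
  stat_fun <- function(m) {
    r <- t(apply(m, 1, rank))   # mid-ranks for ties
    cs <- colSums(r)
    num <- (k - 1) * sum((cs - n * (k + 1) / 2)^2)
    den <- sum(r^2) - n * k * (k + 1)^2 / 4
    if (den <= 0) return(0)     # all rows fully tied
    num / den
  }
  stat <- stat_fun(values)
  df <- k - 1
  if (n < perm_below) {
    stats_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      perm <- t(apply(values, 1, sample))
      stat_fun(perm)
    }, 0))
    p <- (1 + sum(stats_perm >= stat - 1e-12)) / (n_perm + 1)
    method <- "permutation"
  } else {
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    method <- "chi-square"
  }
  list(statistic = stat, p_value = p, df = df, method = method)
}
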