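#' Tumor proportion score from detections or counts
#'
#' TPS is the percentage of PD-L1 positive (viable) tumor cells among all
#' tumor cells; "other" cells are ignored by construction. A record with no
#' tumor cells at all has no defined TPS and raises an explicit error (a
#' slide-level QC concern), never a silent 0.
#'
#' @param detections Annotation-set tibble; alternatively supply counts
#'   directly via `n_pos` / `n_neg`.
#' @param n_pos,n_neg Positive/negative tumor cell counts (used when
#'   `detections` is `NULL`).
#' @param case_id,source Identifiers recorded on the output.
#' @return One-row tibble: `case_id`, `source`, `tps_pct`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' compute_tps(n_pos = 30, n_neg = 70)
compute_tps <- function(detections = NULL, n_pos = NULL, n_neg = NULL,
                        case_id = "case", source = "unknown") {
  if (!is.null(detections)) {
    det <- as_annotation_set(detections)
    n_pos <- sum(det$class == "pos_tumor")
    n_neg <- sum(det$class == "neg_tumor")
    if (nrow(det) > 0) source <- det$source[1]
  }
  stopifnot(!is.null(n_pos), !is.null(n_neg), n_pos >= 0, n_neg >= 0)
  if (n_pos + n_neg == 0) {
    stop("TPS undefined: no tumor cells (n_pos + n_neg = 0)", call. = FALSE)
  }
  tibble::tibble(case_id = case_id, source = source,
                 tps_pct = 100 * n_pos / (n_pos + n_neg),
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg))
}

#' Discretize TPS at the clinical cutoffs
#'
#' Maps TPS percentages onto the three clinically relevant bands:
#' `<1%` (code 0), `1-49%` (code 1, the band includes its lower bound and
#' runs up to but excluding 50), and `>=50%` (code 2).
#'
#' @param tps_pct Numeric TPS values in `[0, 100]`.
#' @return Ordered factor with levels `<1%`, `1-49%`, `>=50%` and integer
#'   codes 0/1/2 accessible via `as.integer(.) - 1`.
#' @export
#' @examples
#' discretize_tps(c(0.5, 1, 49.9, 50))
discretize_tps <- function(tps_pct) {
  stopifnot(all(tps_pct >= 0 & tps_pct <= 100))
  code <- ifelse(tps_pct < 1, 0L, ifelse(tps_pct < 50, 1L, 2L))
  factor(tps_levels()[code + 1L], levels = tps_levels(), ordered = TRUE)
}

#' @rdname discretize_tps
#' @export
tps_levels <- function() c("<1%", "1-49%", ">=50%")

ratings_to_codes <- function(x, n_levels) {
  if (is.factor(x)) return(as.integer(x) - 1L)
  x <- as.integer(x)
  stopifnot(all(x >= 0 & x <= n_levels - 1))
  x
}

#' Linear weighted Cohen's kappa
#'
#' Chance-corrected agreement between two raters on an ordered categorical
#' scale, with linear weights `w_ij = 1 - |i - j| / (k - 1)` so that
#' near-miss disagreements are partially credited. Chance agreement comes
#' from the product of the two raters' marginals. With `k = 2` the weights
#' reduce to 0/1 and the statistic equals unweighted Cohen's kappa.
#'
#' When both raters are constant: perfect agreement gives kappa 1; a
#' degenerate table with imperfect agreement but chance agreement 1 is
#' undefined and returned as flagged `NA`.
#'
#' @param a,b Ratings of the two raters: ordered factors (e.g. from
#'   [discretize_tps()]) or integer codes `0 .. n_levels-1`. Equal length
#'   `>= 2`.
#' @param n_levels Number of scale categories (default 3, the TPS bands).
#'   Ignored when `a` is a factor.
#' @return Kappa in `[-1, 1]`, or flagged `NA` when undefined.
#' @export
#' @examples
#' linear_kappa(c(0, 1, 2, 2), c(0, 1, 2, 1))
linear_kappa <- function(a, b, n_levels = 3) {
  if (is.factor(a)) n_levels <- nlevels(a)
  ca <- ratings_to_codes(a, n_levels); cb <- ratings_to_codes(b, n_levels)
  stopifnot(length(ca) == length(cb), length(ca) >= 2)
  k <- n_levels
  tab <- table(factor(ca, 0:(k - 1)), factor(cb, 0:(k - 1))) / length(ca)
  w <- 1 - abs(outer(0:(k - 1), 0:(k - 1), `-`)) / (k - 1)
  po <- sum(w * tab)
  pe <- sum(w * outer(rowSums(tab), colSums(tab)))
  if (abs(1 - pe) < 1e-12) {
    if (abs(1 - po) < 1e-12) return(1)
    return(structure(NA_real_, reason = "degenerate marginals"))
  }
  as.numeric((po - pe) / (1 - pe))
}

#' Binary kappa at a single TPS cutoff
#'
#' Binarizes two TPS series at a clinical cutoff (`tps >= cutoff` is
#' positive) and computes unweighted Cohen's kappa on the resulting 2x2
#' table.
#'
#' @param tps_a,tps_b Numeric TPS percentages, equal length `>= 2`.
#' @param cutoff Cutoff percentage, typically 1 or 50.
#' @return Kappa, or flagged `NA` when all cases fall on one side of the
#'   cutoff for both raters with imperfect agreement structure.
#' @export
#' @examples
#' kappa_at_cutoff(c(0, 10, 60, 80), c(0, 5, 55, 40), cutoff = 50)
kappa_at_cutoff <- function(tps_a, tps_b, cutoff) {
  stopifnot(length(tps_a) == length(tps_b), cutoff > 0)
  a <- as.integer(tps_a >= cutoff); b <- as.integer(tps_b >= cutoff)
  if (length(unique(a)) == 1 && length(unique(b)) == 1) {
    # every case on the same side of the cutoff for both raters: agreement
    # is vacuous, not perfect
    return(structure(NA_real_, reason = "degenerate marginals"))
  }
  linear_kappa(a, b, n_levels = 2)
}

#' ICC(2,1): two-way random effects, absolute agreement, single rater
#'
#' Intraclass correlation from the two-way random-effects ANOVA
#' decomposition of an n cases x k raters matrix:
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' where MSR, MSC and MSE are the mean squares for rows (cases), columns
#' (raters) and error. The confidence interval is the standard F-based
#' interval for this estimator (McGraw & Wong), not a 1.96-SD interval.
#' Cases with missing cells are dropped (and counted in `n_dropped`).
#'
#' @param ratings Numeric matrix or data frame, rows = cases, columns =
#'   raters; `n >= 2`, `k >= 2`.
#' @param conf_level Confidence level for the interval.
#' @return List with `value`, `ci_low`, `ci_high`, `n`, `k`, `n_dropped`,
#'   and the mean squares `msr`, `msc`, `mse`. `value` is flagged `NA` when
#'   there is no between-case variance.
#' @export
#' @examples
#' m <- cbind(a = c(10, 20, 30, 40), b = c(12, 19, 33, 38))
#' icc_2_1(m)
icc_2_1 <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 2, k >= 2)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (msr < 1e-12 && denom < 1e-12) {
    return(list(value = structure(NA_real_, reason = "no between-case variance"),
                ci_low = NA_real_, ci_high = NA_real_, n = n, k = k,
                n_dropped = n_dropped, msr = msr, msc = msc, mse = mse))
  }
  icc <- (msr - mse) / denom
  # F-based interval (McGraw & Wong 1996, case 2A)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(value = as.numeric(icc), ci_low = ci_low, ci_high = ci_high,
       n = n, k = k, n_dropped = n_dropped, msr = msr, msc = msc, mse = mse)
}

#' Bland-Altman agreement between two measurement series
#'
#' Mean difference `a - b` with limits of agreement at 1.96 standard
#' deviations of the differences, the standard assessment of systematic
#' bias between two ways of measuring the same quantity (e.g. median
#' reader TPS vs detector TPS).
#'
#' @param a,b Numeric series of equal length `>= 2`.
#' @return Object of class `"bland_altman"`: list with `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`, and the per-case `means` and
#'   `diffs` for plotting.
#' @export
#' @examples
#' bland_altman(c(10, 20, 30), c(12, 18, 33))
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  sd_d <- stats::sd(d)
  structure(
    list(mean_diff = mean(d), sd_diff = sd_d,
         loa_low = mean(d) - 1.96 * sd_d, loa_high = mean(d) + 1.96 * sd_d,
         n = length(d), means = (a + b) / 2, diffs = d),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, mean difference %.3f (95%% LoA %.3f to %.3f)\n",
              x$n, x$mean_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Majority-vote agreement at a cutoff
#'
#' Agreement of one source with the majority vote of the human readers,
#' computed per cutoff: each case's reference category is the majority of
#' the voters' binarized ratings, always excluding the target source's own
#' rating when it is among the voters; kappa is then the unweighted Cohen's
#' kappa between the target's binarized ratings and the majority series.
#' Tied majorities (possible with even voter counts) are excluded from the
#' computation by default and counted, or broken toward the higher
#' (positive) category with `tie = "higher"`.
#'
#' @param tps Long tibble with columns `case_id`, `source`, `tps_pct`.
#' @param target Source id being evaluated.
#' @param voters Character vector of human reader ids forming the majority
#'   (the target is removed from this set automatically if present).
#' @param cutoff Cutoff percentage (1 or 50).
#' @param tie `"exclude"` (default) or `"higher"`.
#' @return List with `kappa`, `n_cases`, `n_ties`, `cutoff`, `target`.
#' @export
majority_vote_agreement <- function(tps, target, voters, cutoff,
                                    tie = c("exclude", "higher")) {
  tie <- match.arg(tie)
  stopifnot(all(c("case_id", "source", "tps_pct") %in% names(tps)))
  voters <- setdiff(voters, target)
  if (length(voters) < 2) {
    stop("need >= 3 readers (>= 2 voters after excluding the target)", call. = FALSE)
  }
  wide <- tps |>
    dplyr::filter(.data$source %in% c(voters, target)) |>
    dplyr::mutate(pos = as.integer(.data$tps_pct >= cutoff)) |>
    dplyr::select("case_id", "source", "pos") |>
    tidyr::pivot_wider(names_from = "source", values_from = "pos")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  vm <- as.matrix(wide[, voters, drop = FALSE])
  n_pos <- rowSums(vm); n_vote <- ncol(vm)
  maj <- ifelse(n_pos * 2 > n_vote, 1L, ifelse(n_pos * 2 < n_vote, 0L, NA_integer_))
  n_ties <- sum(is.na(maj))
  if (tie == "higher") {
    maj[is.na(maj)] <- 1L
    n_used <- length(maj); keep <- rep(TRUE, length(maj))
  } else {
    keep <- !is.na(maj); n_used <- sum(keep)
  }
  if (n_used < 2) {
    return(list(kappa = structure(NA_real_, reason = "too few untied cases"),
                n_cases = n_used, n_ties = n_ties, cutoff = cutoff,
                target = target))
  }
  kap <- linear_kappa(wide[[target]][keep], maj[keep], n_levels = 2)
  list(kappa = kap, n_cases = n_used, n_ties = n_ties, cutoff = cutoff,
       target = target)
}
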