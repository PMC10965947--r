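#' Per-class and macro F1 from confusion matrices
#'
#' Pools TP/FP/FN by summation across ROIs before computing ratios
#' (micro-pooling per class), then evaluates the F1 score
#' `2 TP / (2 TP + FP + FN)` — the harmonic mean of precision and recall —
#' for each class and the macro mean over classes. For class `c`: TP is the
#' diagonal cell `(c, c)`; FP is column `c` minus the diagonal (the
#' prediction said `c` but the reference disagreed or saw no cell); FN is
#' row `c` minus the diagonal. A class absent from both sides everywhere
#' has undefined F1 and is excluded from the macro mean (flagged by
#' `defined = FALSE`), never counted as zero.
#'
#' @param confusions A single confusion matrix from
#'   [confusion_from_match()] or a list of them (one per ROI).
#' @return Object of class `"f1_report"`: tibble with one row per cell
#'   class (`class`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `defined`) and attributes `macro_f1`, `n_total`.
#' @export
#' @examples
#' m <- matrix(0L, 4, 4, dimnames = list(confusion_classes(), confusion_classes()))
#' m["pos_tumor", "pos_tumor"] <- 2L
#' m["pos_tumor", "background"] <- 1L
#' m["background", "pos_tumor"] <- 1L
#' f1_from_confusions(m)
f1_from_confusions <- function(confusions) {
  if (is.matrix(confusions)) confusions <- list(confusions)
  stopifnot(length(confusions) >= 1)
  pooled <- Reduce(`+`, confusions)
  stopifnot(all(dim(pooled) == c(4, 4)))
  classes <- cell_classes()
  rows <- purrr::map(classes, function(cl) {
    tp <- pooled[cl, cl]
    fp <- sum(pooled[, cl]) - tp
    fn <- sum(pooled[cl, ]) - tp
    denom <- 2 * tp + fp + fn
    tibble::tibble(
      class = cl, tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn),
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      f1 = if (denom > 0) 2 * tp / denom else NA_real_,
      defined = denom > 0)
  })
  out <- dplyr::bind_rows(rows)
  macro <- if (any(out$defined)) mean(out$f1[out$defined]) else NA_real_
  structure(out, macro_f1 = macro, n_total = sum(pooled),
            class = c("f1_report", class(out)))
}

#' Macro F1 of a match or confusion
#'
#' Convenience accessor for the macro-averaged F1 of an [f1_from_confusions()]
#' report (or anything coercible to one).
#'
#' @param x An `"f1_report"`, a confusion matrix, or a list of confusion
#'   matrices.
#' @return The macro F1 (mean of defined per-class F1 scores).
#' @export
macro_f1 <- function(x) {
  if (!inherits(x, "f1_report")) x <- f1_from_confusions(x)
  attr(x, "macro_f1")
}

#' Pairwise macro F1 matrix across sources
#'
#' For every unordered pair of sources (readers and/or detectors) sharing at
#' least one ROI, matches their point sets ROI by ROI under the hit
#' criterion, pools the confusion matrices, and computes macro F1 — the
#' pairwise interobserver (and reader-AI) agreement matrix. With
#' `mode = "per_case"` confusions are pooled within a case and the
#' case-level macro F1 values are averaged; cases default to ROIs unless a
#' `case_of` mapping is given. Pairs with no shared ROI are `NA` (flagged
#' missing, not 0).
#'
#' @param annotations One tibble holding all sources' annotation sets
#'   (columns `roi_id`, `source`, `x_um`, `y_um`, `class`).
#' @param radius_um Hit radius in um.
#' @param mode `"pooled"` (default) or `"per_case"`.
#' @param case_of Optional named character vector mapping `roi_id` to a
#'   case id (used by `mode = "per_case"`).
#' @param match_mode Passed to [match_points()].
#' @return Object of class `"pairwise_f1"`: symmetric numeric matrix of
#'   macro F1 with unit diagonal, sources as dimnames.
#' @export
pairwise_f1 <- function(annotations, radius_um = 8,
                        mode = c("pooled", "per_case"), case_of = NULL,
                        match_mode = "one_to_one") {
  mode <- match.arg(mode)
  ann <- as_annotation_set(annotations)
  sources <- sort(unique(ann$source))
  stopifnot(length(sources) >= 2)
  k <- length(sources)
  m <- matrix(NA_real_, k, k, dimnames = list(sources, sources))
  diag(m) <- 1
  by_src <- split(ann, ann$source)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      sa <- by_src[[sources[a]]]; sb <- by_src[[sources[b]]]
      shared <- intersect(unique(sa$roi_id), unique(sb$roi_id))
      if (length(shared) == 0) next
      confs <- purrr::map(shared, function(r) {
        match_points(sa[sa$roi_id == r, ], sb[sb$roi_id == r, ],
                     radius_um = radius_um, mode = match_mode) |>
          confusion_from_match()
      })
      names(confs) <- shared
      if (mode == "pooled") {
        val <- macro_f1(confs)
      } else {
        case_key <- if (is.null(case_of)) shared else unname(case_of[shared])
        per_case <- purrr::map_dbl(split(confs, case_key), macro_f1)
        val <- mean(per_case, na.rm = TRUE)
      }
      m[a, b] <- m[b, a] <- val
    }
  }
  structure(m, class = c("pairwise_f1", "matrix"))
}

#' Summarize agreement values by group with 1.96-SD confidence intervals
#'
#' Groupwise means of agreement values (pairwise F1 or kappa) with the
#' 95% confidence interval formed by taking 1.96 standard deviations away
#' from the mean — gated on a Shapiro-Wilk normality test at the 0.05
#' level. Non-normal groups are reported with median and range instead and
#' flagged (`normal = FALSE`); groups too small or too uniform for the test
#' use the normal path with `normality_tested = FALSE`.
#'
#' @param df Data frame with a value column and optional grouping columns.
#' @param value Name of the numeric value column (tidy-eval).
#' @param ... Grouping columns (tidy-eval); empty for one overall group.
#' @param alpha Significance level of the normality gate.
#' @return Tibble with `n`, `mean`, `sd`, `ci_low`, `ci_high`, `median`,
#'   `min`, `max`, `normal`, `normality_tested` per group.
#' @export
#' @examples
#' summarize_groups(data.frame(f1 = c(0.5, 0.7)), f1)
summarize_groups <- function(df, value, ..., alpha = 0.05) {
  val <- rlang::enquo(value)
  df <- dplyr::group_by(df, ...)
  out <- dplyr::summarise(df, .groups = "drop",
    n = dplyr::n(),
    mean = mean(!!val), sd = stats::sd(!!val),
    median = stats::median(!!val),
    min = min(!!val), max = max(!!val),
    .pvals = list(shapiro_or_na(!!val)))
  if (any(out$n < 2)) stop("each group needs >= 2 values for a CI", call. = FALSE)
  out$normality_tested <- !vapply(out$.pvals, is.na, logical(1))
  out$normal <- vapply(out$.pvals, function(p) is.na(p) || p >= alpha, logical(1))
  out$.pvals <- NULL
  out$ci_low <- ifelse(out$normal, out$mean - 1.96 * out$sd, NA_real_)
  out$ci_high <- ifelse(out$normal, out$mean + 1.96 * out$sd, NA_real_)
  stat_cols <- c("n", "mean", "sd", "ci_low", "ci_high", "median", "min",
                 "max", "normal", "normality_tested")
  out[, c(setdiff(names(out), stat_cols), stat_cols)]
}

shapiro_or_na <- function(x) {
  if (length(x) < 3 || length(x) > 5000 || stats::sd(x) == 0) return(NA_real_)
  stats::shapiro.test(x)$p.value
}
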