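#' Slide-level TPS agreement battery
#'
#' Runs the full slide-level agreement analysis over a TPS panel: for every
#' unordered pair of sources the pairwise ICC(2,1), the 3-category linear
#' weighted kappa over the clinical bands ("all cutoffs together"), and the
#' binary kappas at the 1% and 50% cutoffs; group summaries
#' (reader-reader vs reader-AI means with 1.96-SD confidence intervals);
#' majority-vote kappas of every source against the human majority
#' (excluding the source's own rating) per cutoff; and the Bland-Altman
#' comparison of the median reader TPS against the AI TPS. The panel ICC
#' across all readers jointly is also reported with its F-based interval.
#'
#' Cases missing a reading are dropped pairwise, not panel-wide.
#'
#' @param tps Long tibble with columns `case_id`, `source`, `tps_pct`.
#' @param readers Character vector of human reader ids.
#' @param ai Optional id of the detector source (`NULL` for a reader-only
#'   study).
#' @param cutoffs Binary cutoffs in percent (default `c(1, 50)`).
#' @param tie Majority tie rule, see [majority_vote_agreement()].
#' @return Object of class `"tps_agreement"`: list with `pairs` (per-pair
#'   tibble), `groups` (summaries via [summarize_groups()]), `majority`
#'   (per source x cutoff), `icc_panel`, `bland_altman` (or `NULL`),
#'   `cutoffs`.
#' @export
tps_agreement_report <- function(tps, readers, ai = NULL, cutoffs = c(1, 50),
                                 tie = "exclude") {
  stopifnot(all(c("case_id", "source", "tps_pct") %in% names(tps)),
            length(readers) >= 2)
  sources <- c(readers, ai)
  stopifnot(all(sources %in% tps$source))
  wide <- tps |>
    dplyr::select("case_id", "source", "tps_pct") |>
    tidyr::pivot_wider(names_from = "source", values_from = "tps_pct")
  pair_rows <- list()
  combs <- utils::combn(sources, 2, simplify = FALSE)
  for (pr in combs) {
    sub <- wide[stats::complete.cases(wide[, pr]), pr]
    a <- sub[[1]]; b <- sub[[2]]
    icc <- icc_2_1(cbind(a, b))
    row <- tibble::tibble(
      source_a = pr[1], source_b = pr[2],
      pair_type = if (!is.null(ai) && ai %in% pr) "reader-ai" else "reader-reader",
      n_cases = length(a),
      icc = as.numeric(icc$value),
      kappa_overall = as.numeric(linear_kappa(discretize_tps(a),
                                              discretize_tps(b))))
    for (ct in cutoffs) {
      row[[sprintf("kappa_%gpct", ct)]] <-
        as.numeric(kappa_at_cutoff(a, b, ct))
    }
    pair_rows[[length(pair_rows) + 1]] <- row
  }
  pairs <- dplyr::bind_rows(pair_rows)
  groups <- dplyr::bind_rows(
    summarize_groups(pairs, .data$icc, .data$pair_type) |>
      dplyr::mutate(metric = "icc", .before = 1),
    summarize_groups(pairs, .data$kappa_overall, .data$pair_type) |>
      dplyr::mutate(metric = "kappa_overall", .before = 1))
  majority <- purrr::map(sources, function(src) {
    purrr::map(cutoffs, function(ct) {
      mv <- majority_vote_agreement(tps, target = src, voters = readers,
                                    cutoff = ct, tie = tie)
      tibble::tibble(source = src, cutoff = ct,
                     kappa = as.numeric(mv$kappa),
                     n_cases = mv$n_cases, n_ties = mv$n_ties)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  reader_mat <- as.matrix(wide[, readers])
  icc_panel <- icc_2_1(reader_mat)
  ba <- NULL
  if (!is.null(ai)) {
    sub <- wide[stats::complete.cases(wide[, c(readers, ai)]), ]
    med_reader <- apply(as.matrix(sub[, readers]), 1, stats::median)
    ba <- bland_altman(sub[[ai]], med_reader)
  }
  structure(
    list(pairs = pairs, groups = groups, majority = majority,
         icc_panel = icc_panel, bland_altman = ba, cutoffs = cutoffs,
         readers = readers, ai = ai),
    class = "tps_agreement")
}

#' @export
print.tps_agreement <- function(x, ...) {
  cat(sprintf("<tps_agreement> %d sources, %d pairs\n",
              length(c(x$readers, x$ai)), nrow(x$pairs)))
  print(x$groups)
  if (!is.null(x$bland_altman)) print(x$bland_altman)
  invisible(x)
}

#' Tidy methods for pdl1bench result objects
#'
#' Broom-style accessors: `tidy()` returns the per-unit tibble of a result
#' (per class for F1 reports, per pair of sources for pairwise matrices and
#' agreement reports, per pair of points for matches); `glance()` returns a
#' one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.f1_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidiers
#' @export
glance.f1_report <- function(x, ...) {
  tibble::tibble(macro_f1 = attr(x, "macro_f1"),
                 n_total = attr(x, "n_total"),
                 n_classes_defined = sum(x$defined))
}

#' @rdname tidiers
#' @export
tidy.pairwise_f1 <- function(x, ...) {
  m <- unclass(x)
  out <- tibble::as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE))
  names(out) <- c("source_a", "source_b", "macro_f1")
  dplyr::filter(out, .data$source_a < .data$source_b)
}

#' @rdname tidiers
#' @export
tidy.cell_match <- function(x, ...) x$pairs

#' @rdname tidiers
#' @export
glance.cell_match <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs),
                 n_unmatched_ref = nrow(x$unmatched_ref),
                 n_unmatched_pred = nrow(x$unmatched_pred),
                 mean_distance_um = mean(x$pairs$distance_um),
                 radius_um = x$radius_um)
}

#' @rdname tidiers
#' @export
tidy.tps_agreement <- function(x, ...) x$pairs

#' @rdname tidiers
#' @export
glance.tps_agreement <- function(x, ...) {
  g <- x$groups
  pick <- function(metric, type) {
    v <- g$mean[g$metric == metric & g$pair_type == type]
    if (length(v) == 1) v else NA_real_
  }
  tibble::tibble(
    icc_reader_reader = pick("icc", "reader-reader"),
    icc_reader_ai = pick("icc", "reader-ai"),
    kappa_reader_reader = pick("kappa_overall", "reader-reader"),
    kappa_reader_ai = pick("kappa_overall", "reader-ai"),
    icc_panel = as.numeric(x$icc_panel$value),
    bland_altman_mean_diff = if (!is.null(x$bland_altman))
      x$bland_altman$mean_diff else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(mean = x$means, diff = x$diffs)
}
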