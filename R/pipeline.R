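# Deterministic stream of sub-seeds derived from one master seed, so every
# stage of a run has its own independent, reproducible RNG stream.
seed_stream <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Default configuration for a synthetic benchmarking run
#'
#' The configuration bundles the synthetic study conditions (ROI geometry
#' and densities, reader panel, detector model, slide-level panel) with the
#' analysis constants (8 um hit radius, 1%/50% cutoffs, 5% increments,
#' pooling and tie rules). Every field can be overridden; a run is fully
#' reproducible from `(config, seed)`. Configurations serialize to a single
#' YAML file via [write_run_config()] / [read_run_config()].
#'
#' @param seed Master seed for the run.
#' @return A nested list of class `"run_config"`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    roi = list(width_um = 150, height_um = 150, spacing_um_per_px = 0.5,
               tumor_per_mm2 = 2500, other_per_mm2 = 1500,
               positivity = 0.3, d_min = 6),
    cell_study = list(n_cases = 10, rois_per_case = 2),
    readers = list(
      reader_1 = list(miss_rate = 0.05, confusion_diag = 0.90,
                      jitter_sigma_um = 1.5, extra_rate_per_mm2 = 50),
      reader_2 = list(miss_rate = 0.05, confusion_diag = 0.90,
                      jitter_sigma_um = 1.5, extra_rate_per_mm2 = 50),
      reader_3 = list(miss_rate = 0.05, confusion_diag = 0.90,
                      jitter_sigma_um = 1.5, extra_rate_per_mm2 = 50)),
    detector = list(miss_rate = 0.10, confusion_diag = 0.85,
                    jitter_sigma_um = 0.8, extra_rate_per_mm2 = 100),
    matching = list(radius_um = 8, mode = "one_to_one"),
    metrics = list(pooling = "pooled"),
    tps_study = list(n_cases = 100, n_readers = 6, reader_sd_pct = 10,
                     increment_pct = 5,
                     band_weights = c(0.30, 0.45, 0.25),
                     ai_bias_pct = -4.7, ai_sd_pct = 8,
                     ai_increment_pct = NULL),
    cutoffs = c(1, 50),
    majority_tie = "exclude"
  ), class = "run_config")
}

config_reader_model <- function(cfg) {
  reader_model(miss_rate = cfg$miss_rate, confusion = cfg$confusion_diag,
               jitter_sigma_um = cfg$jitter_sigma_um,
               extra_rate_per_mm2 = cfg$extra_rate_per_mm2)
}

#' @rdname default_config
#' @param config A `"run_config"` (or plain list with the same fields).
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_config())
  cfg <- utils::modifyList(base, cfg)
  structure(cfg, class = "run_config")
}

# True slide-level TPS values drawn from a mixture over the three clinical
# bands (weights: <1%, 1-49%, >=50%).
sample_true_tps <- function(n, band_weights, seed) {
  withr::with_seed(seed, {
    band <- sample.int(3, n, replace = TRUE, prob = band_weights)
    lo <- c(0, 1, 50)[band]; hi <- c(1, 50, 100)[band]
    stats::runif(n, lo, hi)
  })
}

#' Run the full synthetic benchmarking pipeline
#'
#' Orchestrates the whole study end to end on synthetic data: generates
#' ground-truth ROIs, simulates the reader panel and the detector on each,
#' computes the pairwise macro F1 matrix and its reader-reader /
#' reader-AI group summaries, pools confusion matrices for the background
#' disagreement fractions, simulates the slide-level TPS panel (plus a
#' detector TPS series), and runs the TPS agreement battery. All outputs
#' are written to `out_dir` as CSV/JSON together with a provenance record;
#' a run is byte-identical under a fixed `(config, seed)`.
#'
#' @param config A `"run_config"` from [default_config()] (possibly
#'   modified) or a path to a YAML config.
#' @param out_dir Output directory; `NULL` to skip writing files.
#' @return Invisibly, a list with `annotations`, `pairwise`,
#'   `cell_groups`, `background`, `tps`, `agreement`, `config`, `log`.
#' @export
#' @examples
#' \donttest{
#' cfg <- default_config(seed = 7)
#' cfg$cell_study <- list(n_cases = 2, rois_per_case = 1)
#' cfg$tps_study$n_cases <- 20
#' res <- run_pipeline(cfg)
#' res$cell_groups
#' }
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  cfg <- config
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  say("flags: matching=%s pooling=%s majority_tie=%s radius_um=%g cutoffs=%s",
      cfg$matching$mode, cfg$metrics$pooling, cfg$majority_tie,
      cfg$matching$radius_um, paste(cfg$cutoffs, collapse = "/"))

  n_rois <- cfg$cell_study$n_cases * cfg$cell_study$rois_per_case
  sources <- c(names(cfg$readers), "ai")
  seeds <- seed_stream(cfg$seed, n_rois * (1 + length(sources)) + 8)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }

  # --- cell-level study -----------------------------------------------------
  ann <- list(); case_of <- character(0)
  models <- c(purrr::map(cfg$readers, config_reader_model),
              list(ai = config_reader_model(cfg$detector)))
  ri <- 0L
  for (case in seq_len(cfg$cell_study$n_cases)) {
    for (r in seq_len(cfg$cell_study$rois_per_case)) {
      ri <- ri + 1L
      roi_id <- sprintf("case%02d_roi%d", case, r)
      roi <- generate_tissue_roi(
        width_um = cfg$roi$width_um, height_um = cfg$roi$height_um,
        spacing_um_per_px = cfg$roi$spacing_um_per_px,
        tumor_per_mm2 = cfg$roi$tumor_per_mm2,
        other_per_mm2 = cfg$roi$other_per_mm2,
        positivity = cfg$roi$positivity, d_min = cfg$roi$d_min,
        seed = next_seed())
      for (src in sources) {
        ann[[length(ann) + 1]] <- simulate_reader(
          roi, models[[src]], source = src, roi_id = roi_id,
          seed = next_seed())
      }
      case_of[roi_id] <- sprintf("case%02d", case)
    }
  }
  annotations <- dplyr::bind_rows(ann)
  say("simulated %d ROIs x %d sources: %d points",
      n_rois, length(sources), nrow(annotations))

  pw <- pairwise_f1(annotations, radius_um = cfg$matching$radius_um,
                    mode = if (cfg$metrics$pooling == "per_case")
                      "per_case" else "pooled",
                    case_of = case_of, match_mode = cfg$matching$mode)
  pw_tidy <- tidy.pairwise_f1(pw) |>
    dplyr::mutate(pair_type = ifelse(.data$source_a == "ai" |
                                       .data$source_b == "ai",
                                     "reader-ai", "reader-reader"))
  cell_groups <- summarize_groups(pw_tidy, .data$macro_f1, .data$pair_type)

  # pooled confusion per pair type, for the background disagreement share
  bg <- purrr::map(list(`reader-reader` = FALSE, `reader-ai` = TRUE),
                   function(with_ai) {
    pairs <- dplyr::filter(pw_tidy, (.data$pair_type == "reader-ai") == with_ai)
    fracs <- purrr::map_dbl(seq_len(nrow(pairs)), function(i) {
      sa <- annotations[annotations$source == pairs$source_a[i], ]
      sb <- annotations[annotations$source == pairs$source_b[i], ]
      shared <- intersect(unique(sa$roi_id), unique(sb$roi_id))
      conf <- purrr::map(shared, ~ confusion_from_match(match_points(
        sa[sa$roi_id == .x, ], sb[sb$roi_id == .x, ],
        radius_um = cfg$matching$radius_um, mode = cfg$matching$mode)))
      as.numeric(background_disagreement_fraction(Reduce(`+`, conf)))
    })
    mean(fracs, na.rm = TRUE)
  })
  say("background disagreement: reader-reader %.3f, reader-ai %.3f",
      bg[["reader-reader"]], bg[["reader-ai"]])

  # --- slide-level study ----------------------------------------------------
  ts <- cfg$tps_study
  true_tps <- sample_true_tps(ts$n_cases, ts$band_weights, next_seed())
  tps <- simulate_tps_panel(true_tps, n_readers = ts$n_readers,
                            reader_sd_pct = ts$reader_sd_pct,
                            increment_pct = ts$increment_pct,
                            seed = next_seed())
  ai_tps <- withr::with_seed(next_seed(), {
    pmin(pmax(true_tps + ts$ai_bias_pct +
                stats::rnorm(ts$n_cases, 0, ts$ai_sd_pct), 0), 100)
  })
  # the detector computes a continuous ratio; rounding only if configured
  if (!is.null(ts$ai_increment_pct)) {
    ai_tps <- round_to_increment(ai_tps, ts$ai_increment_pct)
  }
  tps <- dplyr::bind_rows(
    tps,
    tibble::tibble(case_id = unique(tps$case_id), source = "ai",
                   tps_pct = ai_tps, true_tps = true_tps))
  readers_tps <- sprintf("reader_%d", seq_len(ts$n_readers))
  agreement <- tps_agreement_report(tps, readers = readers_tps, ai = "ai",
                                    cutoffs = cfg$cutoffs,
                                    tie = cfg$majority_tie)
  say("tps panel: %d cases x %d readers + ai", ts$n_cases, ts$n_readers)

  result <- list(annotations = annotations, pairwise = pw,
                 cell_groups = cell_groups,
                 background = list(reader_reader = bg[["reader-reader"]],
                                   reader_ai = bg[["reader-ai"]]),
                 tps = tps, agreement = agreement, config = cfg,
                 log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(unclass(pw), file.path(out_dir, "pairwise_f1.csv"))
    write_annotations(annotations, file.path(out_dir, "annotations.csv"))
    write_tps(tps, file.path(out_dir, "tps.csv"))
    jsonlite::write_json(
      list(cell_groups = cell_groups,
           background_disagreement = result$background),
      file.path(out_dir, "f1_report.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(pairs = agreement$pairs, groups = agreement$groups,
           majority = agreement$majority,
           icc_panel = agreement$icc_panel[c("value", "ci_low", "ci_high")],
           bland_altman = agreement$bland_altman[
             c("mean_diff", "sd_diff", "loa_low", "loa_high", "n")]),
      file.path(out_dir, "agreement.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(seed = cfg$seed, config = unclass(cfg),
           package_version = as.character(utils::packageVersion("pdl1bench"))),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  invisible(result)
}
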