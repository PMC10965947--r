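#' Reader noise model
#'
#' Statistical model of an imperfect annotator (or detector) acting on a
#' ground-truth point pattern: per-class miss rates, a row-stochastic class
#' confusion matrix, isotropic Gaussian localization jitter, and spurious
#' extra points added as a homogeneous Poisson process.
#'
#' @param miss_rate Per-class probability of omitting a true cell; scalar or
#'   length-3 vector named/ordered as [cell_classes()].
#' @param confusion 3x3 row-stochastic matrix mapping true class (row) to
#'   reported class (column), ordered as [cell_classes()]. A scalar `d` is
#'   shorthand for diagonal `d` with the remainder split evenly off-diagonal.
#' @param jitter_sigma_um Standard deviation (um) of isotropic Gaussian
#'   localization noise.
#' @param extra_rate_per_mm2 Intensity of spurious points per square mm.
#' @param extra_class_probs Class distribution of spurious points (length 3,
#'   sums to 1).
#' @return A `reader_model` list.
#' @export
#' @examples
#' reader_model(miss_rate = 0.05, confusion = 0.9, jitter_sigma_um = 1.5)
reader_model <- function(miss_rate = 0, confusion = diag(3),
                         jitter_sigma_um = 0, extra_rate_per_mm2 = 0,
                         extra_class_probs = c(1, 1, 1) / 3) {
  k <- length(cell_classes())
  miss_rate <- rep_len(as.numeric(miss_rate), k)
  if (length(confusion) == 1) {
    d <- as.numeric(confusion)
    confusion <- matrix((1 - d) / (k - 1), k, k)
    diag(confusion) <- d
  }
  confusion <- as.matrix(confusion)
  dimnames(confusion) <- list(cell_classes(), cell_classes())
  stopifnot(
    all(miss_rate >= 0 & miss_rate <= 1),
    all(dim(confusion) == c(k, k)), all(confusion >= 0),
    jitter_sigma_um >= 0, extra_rate_per_mm2 >= 0,
    length(extra_class_probs) == k, all(extra_class_probs >= 0)
  )
  if (any(abs(rowSums(confusion) - 1) > 1e-9)) {
    stop("confusion matrix rows must sum to 1 (within 1e-9)", call. = FALSE)
  }
  structure(
    list(miss_rate = stats::setNames(miss_rate, cell_classes()),
         confusion = confusion,
         jitter_sigma_um = as.numeric(jitter_sigma_um),
         extra_rate_per_mm2 = as.numeric(extra_rate_per_mm2),
         extra_class_probs = extra_class_probs / sum(extra_class_probs)),
    class = "reader_model")
}

# Hard-core (minimum separation) rejection sampler on [0,w) x [0,h), um.
# Grid-bucketed neighbor lookup keeps it linear-ish in n. Errors, never
# truncates, if the requested count cannot be packed.
sample_hardcore <- function(n, width_um, height_um, d_min,
                            max_attempts = 200L * n + 1000L) {
  if (n == 0) return(cbind(x = numeric(), y = numeric()))
  xs <- numeric(n); ys <- numeric(n)
  if (d_min <= 0) {
    # pure binomial process; draw per point (x then y) for stable order
    for (i in seq_len(n)) {
      xs[i] <- stats::runif(1, 0, width_um)
      ys[i] <- stats::runif(1, 0, height_um)
    }
    return(cbind(x = xs, y = ys))
  }
  cell <- d_min
  nx <- max(1L, ceiling(width_um / cell)); ny <- max(1L, ceiling(height_um / cell))
  grid <- vector("list", nx * ny)
  gidx <- function(gx, gy) (gy - 1L) * nx + gx
  placed <- 0L; attempts <- 0L; d2 <- d_min^2
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "infeasible packing: placed %d of %d points with d_min = %g um after %d attempts",
        placed, n, d_min, max_attempts), call. = FALSE)
    }
    x <- stats::runif(1, 0, width_um); y <- stats::runif(1, 0, height_um)
    gx <- min(nx, 1L + floor(x / cell)); gy <- min(ny, 1L + floor(y / cell))
    ok <- TRUE
    for (ix in max(1L, gx - 1L):min(nx, gx + 1L)) {
      for (iy in max(1L, gy - 1L):min(ny, gy + 1L)) {
        for (j in grid[[gidx(ix, iy)]]) {
          if ((x - xs[j])^2 + (y - ys[j])^2 < d2) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
      grid[[gidx(gx, gy)]] <- c(grid[[gidx(gx, gy)]], placed)
    }
  }
  cbind(x = xs, y = ys)
}

#' Generate a synthetic ground-truth ROI
#'
#' Draws a hard-core (minimum-separation) point pattern of tumor and other
#' cells over a rectangular region of interest, assigns PD-L1 positivity to
#' tumor cells, and optionally renders an immunohistochemistry-like RGB image
#' (hematoxylin-toned nuclei; a DAB-toned membrane ring around positive tumor
#' cells) so the classical detection pipeline has signal to find.
#'
#' Cell counts are Poisson with intensity `tumor_per_mm2` / `other_per_mm2`
#' over the ROI area; each tumor cell is positive independently with
#' probability `positivity`. Randomness is drawn in a fixed documented order
#' (counts, then positions point by point, then positivity labels), so a
#' given `(parameters, seed)` pair is reproducible across platforms.
#'
#' @param width_um,height_um ROI size in micrometers (defaults: the 150 um
#'   square fields used for exhaustive cell-level annotation).
#' @param spacing_um_per_px Pixel spacing used when rendering.
#' @param tumor_per_mm2,other_per_mm2 Poisson intensities (cells per mm2).
#' @param positivity Fraction of tumor cells that are PD-L1 positive.
#' @param d_min Minimum inter-cell distance in um. Requests that cannot be
#'   packed raise an error rather than silently truncating.
#' @param seed Integer seed; same seed and parameters give identical output.
#' @param render If `TRUE`, attach a rendered RGB image (array in `[0,1]`).
#' @return An object of class `"roi"`: a list with `width_um`, `height_um`,
#'   `spacing_um_per_px`, `cells` (tibble `x_um`, `y_um`, `class`), `seed`,
#'   and optionally `image`.
#' @seealso [simulate_reader()], [render_roi_image()]
#' @export
#' @examples
#' roi <- generate_tissue_roi(seed = 1)
#' roi
generate_tissue_roi <- function(width_um = 150, height_um = 150,
                                spacing_um_per_px = 0.5,
                                tumor_per_mm2 = 2500, other_per_mm2 = 1500,
                                positivity = 0.3, d_min = 6,
                                seed = 1L, render = FALSE) {
  stopifnot(width_um > 0, height_um > 0, spacing_um_per_px > 0,
            tumor_per_mm2 >= 0, other_per_mm2 >= 0,
            positivity >= 0, positivity <= 1, d_min >= 0)
  area_mm2 <- width_um * height_um / 1e6
  cells <- withr::with_seed(seed, {
    n_tumor <- stats::rpois(1, tumor_per_mm2 * area_mm2)
    n_other <- stats::rpois(1, other_per_mm2 * area_mm2)
    xy <- sample_hardcore(n_tumor + n_other, width_um, height_um, d_min)
    pos <- if (n_tumor > 0) stats::runif(n_tumor) < positivity else logical()
    cls <- c(ifelse(pos, "pos_tumor", "neg_tumor"),
             rep("other", n_other))
    tibble::tibble(x_um = xy[, "x"], y_um = xy[, "y"], class = cls)
  })
  roi <- structure(
    list(width_um = width_um, height_um = height_um,
         spacing_um_per_px = spacing_um_per_px,
         cells = cells, seed = as.integer(seed), image = NULL),
    class = "roi")
  if (render) roi$image <- render_roi_image(roi)
  roi
}

#' Simulate an imperfect reader on a ground-truth ROI
#'
#' Applies a [reader_model()] to the true cells: each cell is independently
#' dropped with its class miss rate; survivors are relabeled by sampling the
#' confusion row and displaced by isotropic Gaussian jitter (clipped to the
#' ROI bounds, so the miss rate is governed solely by the miss parameter);
#' spurious points are added as a Poisson process. Per-cell randomness is
#' drawn in truth order (miss, class, jitter x, jitter y), then extras, so
#' output is reproducible under `(model, seed)`.
#'
#' @param roi A ground-truth ROI from [generate_tissue_roi()].
#' @param model A [reader_model()].
#' @param source Source id recorded on the output points.
#' @param roi_id ROI id recorded on the output points.
#' @param seed Integer seed.
#' @return An annotation-set tibble (see [annotation_set()]).
#' @export
#' @examples
#' roi <- generate_tissue_roi(seed = 1)
#' simulate_reader(roi, reader_model(jitter_sigma_um = 1), source = "r1", seed = 2)
simulate_reader <- function(roi, model = reader_model(), source = "reader",
                            roi_id = "roi", seed = 1L) {
  stopifnot(inherits(roi, "roi"), inherits(model, "reader_model"))
  classes <- cell_classes()
  withr::with_seed(seed, {
    tr <- roi$cells
    n_tr <- nrow(tr)
    keep_x <- numeric(n_tr); keep_y <- numeric(n_tr); keep_c <- character(n_tr)
    kept <- 0L
    if (n_tr > 0) {
      for (i in seq_len(n_tr)) {
        cls <- tr$class[i]
        if (stats::runif(1) < model$miss_rate[[cls]]) next
        rep_cls <- sample(classes, 1, prob = model$confusion[cls, ])
        dx <- stats::rnorm(1, 0, model$jitter_sigma_um)
        dy <- stats::rnorm(1, 0, model$jitter_sigma_um)
        kept <- kept + 1L
        keep_x[kept] <- clamp_coord(tr$x_um[i] + dx, roi$width_um)
        keep_y[kept] <- clamp_coord(tr$y_um[i] + dy, roi$height_um)
        keep_c[kept] <- rep_cls
      }
    }
    keep_x <- keep_x[seq_len(kept)]; keep_y <- keep_y[seq_len(kept)]
    keep_c <- keep_c[seq_len(kept)]
    area_mm2 <- roi$width_um * roi$height_um / 1e6
    n_extra <- stats::rpois(1, model$extra_rate_per_mm2 * area_mm2)
    if (n_extra > 0) {
      ex <- stats::runif(n_extra, 0, roi$width_um)
      ey <- stats::runif(n_extra, 0, roi$height_um)
      ec <- sample(classes, n_extra, replace = TRUE,
                   prob = model$extra_class_probs)
      keep_x <- c(keep_x, ex); keep_y <- c(keep_y, ey); keep_c <- c(keep_c, ec)
    }
    annotation_set(keep_x, keep_y, keep_c, source = source, roi_id = roi_id)
  })
}

clamp_coord <- function(v, upper) pmin(pmax(v, 0), upper * (1 - 1e-12))

#' Expected matched fraction under Gaussian localization jitter
#'
#' Closed-form recall of an otherwise perfect reader whose points are
#' displaced by isotropic Gaussian jitter and matched back to the truth
#' within a fixed radius: the displacement magnitude is Rayleigh(sigma), so
#' the matched fraction is `1 - exp(-radius^2 / (2 sigma^2))` (1 when
#' `sigma = 0`). Used as an independent oracle for the simulator + matcher.
#'
#' @param sigma_um Jitter standard deviation (um), `>= 0`.
#' @param radius_um Matching radius (um), `> 0`.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' expected_recall_under_jitter(4, 8)  # 1 - exp(-2)
expected_recall_under_jitter <- function(sigma_um, radius_um) {
  stopifnot(all(sigma_um >= 0), all(radius_um > 0))
  ifelse(sigma_um == 0, 1, 1 - exp(-radius_um^2 / (2 * sigma_um^2)))
}

# Round half away from zero to the nearest multiple of `increment`.
# (base round() rounds half to even, which is not the convention used for
# visual TPS estimates.)
round_to_increment <- function(x, increment) {
  sign(x) * floor(abs(x) / increment + 0.5) * increment
}

#' Simulate a panel of slide-level visual TPS estimates
#'
#' Each reader's estimate of a case's tumor proportion score is the true TPS
#' plus Gaussian reader noise, clipped to `[0, 100]` and rounded (half away
#' from zero) to the nearest `increment_pct` — the "five percent increments"
#' convention of visual scoring. Noise is drawn case by case, reader by
#' reader within each case.
#'
#' @param true_tps Numeric vector of true TPS percentages in `[0, 100]`.
#' @param n_readers Number of readers.
#' @param reader_sd_pct Standard deviation of reader noise (percent TPS).
#' @param increment_pct Rounding granularity (default 5).
#' @param seed Integer seed.
#' @return A tibble in long form: `case_id`, `source`, `tps_pct`, plus the
#'   `true_tps` per case repeated for convenience.
#' @export
#' @examples
#' simulate_tps_panel(c(0, 20, 80), n_readers = 3, reader_sd_pct = 0, seed = 1)
simulate_tps_panel <- function(true_tps, n_readers, reader_sd_pct = 10,
                               increment_pct = 5, seed = 1L) {
  stopifnot(all(true_tps >= 0 & true_tps <= 100), n_readers >= 1,
            reader_sd_pct >= 0, increment_pct > 0)
  n <- length(true_tps)
  case_ids <- sprintf("case_%03d", seq_len(n))
  withr::with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      noise <- stats::rnorm(n_readers, 0, reader_sd_pct)
      est <- round_to_increment(pmin(pmax(true_tps[i] + noise, 0), 100),
                                increment_pct)
      out[[i]] <- tibble::tibble(
        case_id = case_ids[i],
        source = sprintf("reader_%d", seq_len(n_readers)),
        tps_pct = est, true_tps = true_tps[i])
    }
    dplyr::bind_rows(out)
  })
}
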