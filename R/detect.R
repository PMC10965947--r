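#' Detect nucleus centers by Laplacian-of-Gaussian blob detection
#'
#' Classical, class-agnostic nucleus detector: unmixes the hematoxylin
#' density map by color deconvolution, computes the scale-normalized
#' Laplacian-of-Gaussian response over a range of scales matched to nucleus
#' size, finds local maxima in (x, y, scale), and applies non-maximum
#' suppression at a minimum separation. Returns centers in continuous um
#' coordinates (pixel (i, j), 1-based, maps to `((j - 0.5) * spacing,
#' (i - 0.5) * spacing)`).
#'
#' This operator is a deliberately simple classical detector for rendered or
#' plain IHC rasters; it detects each lobe of a multinucleated cell
#' separately and makes no attempt at nuclei shape modeling.
#'
#' @param image RGB array (height x width x 3) in `[0, 1]`.
#' @param spacing_um_per_px Pixel spacing in um.
#' @param sigma_range_um Range of LoG scales in um (roughly nucleus
#'   radius / sqrt(2); the default covers 3-10 um nucleus diameters).
#' @param n_scales Number of logarithmically spaced scales.
#' @param min_prominence Minimum scale-normalized LoG response (optical
#'   density units) for a peak to count.
#' @param min_sep_um Non-maximum-suppression radius in um.
#' @param stain_matrix Stain matrix passed to [separate_stains()].
#' @return Tibble with columns `x_um`, `y_um`, `response` sorted by
#'   decreasing response; zero rows for a blank image.
#' @export
#' @examples
#' roi <- generate_tissue_roi(width_um = 60, height_um = 60,
#'                            tumor_per_mm2 = 1500, other_per_mm2 = 0,
#'                            d_min = 12, seed = 3, render = TRUE)
#' detect_nuclei(roi$image, roi$spacing_um_per_px)
detect_nuclei <- function(image, spacing_um_per_px,
                          sigma_range_um = c(1.1, 3.6), n_scales = 5,
                          min_prominence = 0.08, min_sep_um = 4,
                          stain_matrix = hdab_stain_matrix()) {
  stopifnot(spacing_um_per_px > 0, all(sigma_range_um > 0),
            min_prominence > 0, min_sep_um > 0, n_scales >= 1)
  h_map <- separate_stains(image, stain_matrix)$hematoxylin
  sigmas_um <- exp(seq(log(sigma_range_um[1]), log(sigma_range_um[2]),
                       length.out = n_scales))
  nr <- nrow(h_map); nc <- ncol(h_map)
  resp <- array(0, c(nr, nc, length(sigmas_um)))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  for (s in seq_along(sigmas_um)) {
    sig_px <- sigmas_um[s] / spacing_um_per_px
    sm <- EBImage::gblur(h_map, sigma = sig_px)
    # negated Laplacian: bright blobs give positive response;
    # sigma^2 factor makes the response comparable across scales
    resp[, , s] <- -sig_px^2 * EBImage::filter2(sm, lap)
  }
  peaks <- find_local_maxima_3d(resp, min_prominence)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(x_um = numeric(), y_um = numeric(),
                          response = numeric()))
  }
  # non-maximum suppression, strongest response first
  peaks <- peaks[order(-peaks$value, peaks$i, peaks$j), , drop = FALSE]
  x_um <- (peaks$j - 0.5) * spacing_um_per_px
  y_um <- (peaks$i - 0.5) * spacing_um_per_px
  keep <- logical(nrow(peaks)); min_sep2 <- min_sep_um^2
  kept_x <- numeric(0); kept_y <- numeric(0)
  for (p in seq_len(nrow(peaks))) {
    if (length(kept_x) == 0 ||
        all((x_um[p] - kept_x)^2 + (y_um[p] - kept_y)^2 >= min_sep2)) {
      keep[p] <- TRUE
      kept_x <- c(kept_x, x_um[p]); kept_y <- c(kept_y, y_um[p])
    }
  }
  tibble::tibble(x_um = x_um[keep], y_um = y_um[keep],
                 response = peaks$value[keep])
}

# Strict local maxima of a (rows x cols x scales) response array above a
# threshold; 26-connected in (i, j, s), borders excluded in-plane.
find_local_maxima_3d <- function(resp, threshold) {
  nr <- dim(resp)[1]; nc <- dim(resp)[2]; ns <- dim(resp)[3]
  if (nr < 3 || nc < 3) {
    return(data.frame(i = integer(), j = integer(), value = numeric()))
  }
  out_i <- integer(0); out_j <- integer(0); out_v <- numeric(0)
  for (s in seq_len(ns)) {
    m <- resp[, , s]
    core <- m[2:(nr - 1), 2:(nc - 1)]
    is_max <- core > threshold
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      is_max <- is_max & (core > m[2:(nr - 1) + di, 2:(nc - 1) + dj])
    }
    for (ds in c(-1, 1)) {
      s2 <- s + ds
      if (s2 < 1 || s2 > ns) next
      m2 <- resp[, , s2]
      for (di in -1:1) for (dj in -1:1) {
        is_max <- is_max & (core >= m2[2:(nr - 1) + di, 2:(nc - 1) + dj])
      }
    }
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      out_i <- c(out_i, idx[, 1] + 1L)
      out_j <- c(out_j, idx[, 2] + 1L)
      out_v <- c(out_v, core[idx])
    }
  }
  data.frame(i = out_i, j = out_j, value = out_v)
}
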