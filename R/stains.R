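#' H-DAB stain vectors
#'
#' Unit-norm optical-density vectors for hematoxylin and DAB
#' (Ruifrok-Johnston style), rows = stains, columns = R, G, B. Used both to
#' render synthetic immunohistochemistry and to unmix real or rendered RGB
#' images.
#'
#' @return A 2x3 numeric matrix with rownames `hematoxylin`, `dab`.
#' @export
hdab_stain_matrix <- function() {
  m <- rbind(hematoxylin = c(0.650, 0.704, 0.286),
             dab = c(0.269, 0.568, 0.776))
  m / sqrt(rowSums(m^2))
}

# Gaussian blob + membrane-ring optical-density painter used by the
# renderer; works on a local window around each cell for speed.
paint_cell <- function(dens, cx_px, cy_px, sigma_px, amp, ring_r_px = NULL,
                       ring_w_px = NULL) {
  nr <- nrow(dens); nc <- ncol(dens)
  ext <- ceiling(if (is.null(ring_r_px)) 4 * sigma_px else ring_r_px + 4 * ring_w_px)
  i0 <- max(1L, floor(cy_px - ext)); i1 <- min(nr, ceiling(cy_px + ext))
  j0 <- max(1L, floor(cx_px - ext)); j1 <- min(nc, ceiling(cx_px + ext))
  if (i0 > i1 || j0 > j1) return(dens)
  ii <- i0:i1; jj <- j0:j1
  dy <- (ii - 0.5) - cy_px; dx <- (jj - 0.5) - cx_px
  d2 <- outer(dy^2, dx^2, `+`)
  if (is.null(ring_r_px)) {
    dens[ii, jj] <- dens[ii, jj] + amp * exp(-d2 / (2 * sigma_px^2))
  } else {
    d <- sqrt(d2)
    dens[ii, jj] <- dens[ii, jj] + amp * exp(-(d - ring_r_px)^2 / (2 * ring_w_px^2))
  }
  dens
}

#' Render an ROI as an IHC-like RGB image
#'
#' Paints each cell nucleus as a hematoxylin-toned Gaussian blob and gives
#' PD-L1 positive tumor cells an additional DAB-toned membrane ring, then
#' composes the RGB image through the Beer-Lambert law with the same stain
#' vectors used by [separate_stains()], so stain separation is a left
#' inverse of rendering. This is a deliberately simple raster model — blobs,
#' not nuclei morphology — sufficient to exercise a classical detector.
#'
#' @param roi An object from [generate_tissue_roi()].
#' @param nucleus_sigma_um Gaussian radius parameter of the nucleus blob (um).
#' @param nucleus_od Peak hematoxylin optical density of a nucleus.
#' @param membrane_radius_um,membrane_sigma_um Radius and width (um) of the
#'   DAB membrane ring on positive tumor cells.
#' @param membrane_od Peak DAB optical density of the membrane ring.
#' @param stain_matrix Stain matrix as in [hdab_stain_matrix()].
#' @return RGB array (height x width x 3) with values in `[0, 1]`.
#' @export
render_roi_image <- function(roi, nucleus_sigma_um = 2.2, nucleus_od = 0.9,
                             membrane_radius_um = 5, membrane_sigma_um = 1.2,
                             membrane_od = 0.6,
                             stain_matrix = hdab_stain_matrix()) {
  stopifnot(inherits(roi, "roi"))
  sp <- roi$spacing_um_per_px
  nr <- ceiling(roi$height_um / sp); nc <- ceiling(roi$width_um / sp)
  h_map <- matrix(0, nr, nc); d_map <- matrix(0, nr, nc)
  cells <- roi$cells
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x_um[i] / sp; cy <- cells$y_um[i] / sp
    h_map <- paint_cell(h_map, cx, cy, nucleus_sigma_um / sp, nucleus_od)
    if (cells$class[i] == "pos_tumor") {
      d_map <- paint_cell(d_map, cx, cy, sigma_px = NA, amp = membrane_od,
                          ring_r_px = membrane_radius_um / sp,
                          ring_w_px = membrane_sigma_um / sp)
    }
  }
  img <- array(0, c(nr, nc, 3))
  for (ch in 1:3) {
    od <- h_map * stain_matrix[1, ch] + d_map * stain_matrix[2, ch]
    img[, , ch] <- 10^(-od)
  }
  img
}

#' Separate hematoxylin and DAB stains by color deconvolution
#'
#' Converts an RGB image to optical densities (`-log10` of transmitted
#' intensity) and linearly unmixes them into per-stain density maps using
#' the given stain vectors; the third, residual channel is the unit vector
#' orthogonal to both stains. Negative densities are clamped to zero.
#'
#' @param image RGB array (height x width x 3), values in `(0, 1]`.
#' @param stain_matrix 2x3 matrix of unit-norm stain OD vectors
#'   (rows: hematoxylin, DAB).
#' @return Named list of matrices `hematoxylin`, `dab`, `residual`, same
#'   raster dimensions as the input.
#' @export
#' @examples
#' roi <- generate_tissue_roi(width_um = 40, height_um = 40, seed = 1)
#' maps <- separate_stains(render_roi_image(roi))
#' str(maps$hematoxylin)
separate_stains <- function(image, stain_matrix = hdab_stain_matrix()) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3,
            all(dim(stain_matrix) == c(2, 3)))
  m <- stain_matrix / sqrt(rowSums(stain_matrix^2))
  resid <- c(m[1, 2] * m[2, 3] - m[1, 3] * m[2, 2],
             m[1, 3] * m[2, 1] - m[1, 1] * m[2, 3],
             m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  if (sqrt(sum(resid^2)) < 1e-6) {
    stop("stain matrix is singular or ill-conditioned: stain vectors are collinear",
         call. = FALSE)
  }
  m3 <- rbind(m, residual = resid / sqrt(sum(resid^2)))
  if (kappa(m3) > 1e8) {
    stop("stain matrix is singular or ill-conditioned", call. = FALSE)
  }
  nr <- dim(image)[1]; nc <- dim(image)[2]
  od <- -log10(pmax(matrix(image, nr * nc, 3), 1e-6))
  conc <- od %*% solve(m3)
  conc[conc < 0] <- 0
  list(hematoxylin = matrix(conc[, 1], nr, nc),
       dab = matrix(conc[, 2], nr, nc),
       residual = matrix(conc[, 3], nr, nc))
}
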