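test_that("a pure white image unmixes to all-zero density maps", {
  img <- array(1, c(20, 20, 3))
  maps <- separate_stains(img)
  expect_equal(max(abs(maps$hematoxylin)), 0)
  expect_equal(max(abs(maps$dab)), 0)
})

test_that("stain separation is a left inverse of rendering", {
  roi <- generate_tissue_roi(width_um = 80, height_um = 80,
                             tumor_per_mm2 = 2000, other_per_mm2 = 1000,
                             positivity = 0.5, d_min = 8, seed = 12,
                             render = TRUE)
  expect_gt(nrow(roi$cells), 5)
  # rebuild the pure hematoxylin OD map the renderer painted
  sp <- roi$spacing_um_per_px
  nr <- nrow(roi$image); nc <- ncol(roi$image)
  h_true <- matrix(0, nr, nc)
  for (i in seq_len(nrow(roi$cells))) {
    h_true <- pdl1bench:::paint_cell(h_true, roi$cells$x_um[i] / sp,
                                     roi$cells$y_um[i] / sp, 2.2 / sp, 0.9)
  }
  h_got <- separate_stains(roi$image)$hematoxylin
  expect_gt(stats::cor(as.vector(h_true), as.vector(h_got)), 0.99)
})

test_that("a pure hematoxylin disk leaks under 5% into the DAB map", {
  sm <- hdab_stain_matrix()
  nr <- 60
  od_h <- matrix(0, nr, nr)
  od_h <- pdl1bench:::paint_cell(od_h, 30, 30, 6, 1.0)
  img <- array(0, c(nr, nr, 3))
  for (ch in 1:3) img[, , ch] <- 10^(-od_h * sm[1, ch])
  maps <- separate_stains(img)
  expect_lt(max(maps$dab), 0.05 * max(maps$hematoxylin))
})

test_that("a singular stain matrix is rejected", {
  bad <- rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_error(separate_stains(array(1, c(5, 5, 3)), bad), "singular")
})

test_that("blank images yield no detections and thresholds dominate", {
  blank <- array(1, c(60, 60, 3))
  expect_equal(nrow(detect_nuclei(blank, 0.5)), 0)

  roi <- generate_tissue_roi(width_um = 60, height_um = 60,
                             tumor_per_mm2 = 2000, other_per_mm2 = 0,
                             d_min = 10, seed = 2, render = TRUE)
  det <- detect_nuclei(roi$image, roi$spacing_um_per_px)
  expect_gt(nrow(det), 0)
  none <- detect_nuclei(roi$image, roi$spacing_um_per_px,
                        min_prominence = max(det$response) * 10)
  expect_equal(nrow(none), 0)
})

test_that("the detector recovers well-separated rendered nuclei", {
  # 50 nuclei with generous separation in a 210x210 um field
  n_target <- 50
  roi <- generate_tissue_roi(width_um = 210, height_um = 210,
                             tumor_per_mm2 = n_target / 0.0441,
                             other_per_mm2 = 0, positivity = 0.4,
                             d_min = 14, seed = 77, render = TRUE)
  truth <- roi$cells
  det <- detect_nuclei(roi$image, roi$spacing_um_per_px)
  m <- match_points(
    annotation_set(truth$x_um, truth$y_um, truth$class, source = "truth"),
    annotation_set(det$x_um, det$y_um, rep("other", nrow(det)), source = "det"),
    radius_um = 3)
  expect_gte(nrow(m$pairs), ceiling(0.96 * nrow(truth)))
  expect_lte(nrow(m$unmatched_pred), 2)
})

test_that("detections are equivariant to integer-pixel translation", {
  roi <- generate_tissue_roi(width_um = 50, height_um = 50,
                             tumor_per_mm2 = 1600, other_per_mm2 = 0,
                             d_min = 12, seed = 5, render = TRUE)
  sp <- roi$spacing_um_per_px
  pad <- 40L  # pixels of white margin
  nr <- nrow(roi$image); nc <- ncol(roi$image)
  big <- array(1, c(nr + 2 * pad, nc + 2 * pad, 3))
  shift <- 7L
  a <- big; a[pad + 1:nr, pad + 1:nc, ] <- roi$image
  b <- big; b[pad + shift + 1:nr, pad + shift + 1:nc, ] <- roi$image
  da <- detect_nuclei(a, sp)
  db <- detect_nuclei(b, sp)
  expect_equal(nrow(da), nrow(db))
  oa <- order(da$y_um, da$x_um); ob <- order(db$y_um, db$x_um)
  expect_equal(db$x_um[ob], da$x_um[oa] + shift * sp, tolerance = 1e-8)
  expect_equal(db$y_um[ob], da$y_um[oa] + shift * sp, tolerance = 1e-8)
})

test_that("polygon label transfer follows the intersect-and-label rule", {
  polys <- dplyr::bind_rows(
    labeled_polygon(c(0, 20, 20, 0), c(0, 0, 20, 20), "pos_tumor", "p1"),
    labeled_polygon(c(30, 50, 50, 30), c(0, 0, 20, 20), "other", "p2"))
  pts <- data.frame(x_um = c(10, 40, 70), y_um = c(10, 10, 10))
  out <- label_points_by_polygons(pts, polys)
  expect_equal(nrow(out), 2)  # point outside all polygons is discarded
  expect_equal(out$class[out$x_um == 10], "pos_tumor")
  expect_equal(out$class[out$x_um == 40], "other")
  # output is a subset of the input points: never invents coordinates
  expect_true(all(paste(out$x_um, out$y_um) %in% paste(pts$x_um, pts$y_um)))
  # deterministic order: sorted by y then x
  expect_equal(out$x_um, sort(out$x_um))
})

test_that("point-in-polygon agrees with an independent even-odd oracle", {
  skip_if_not_installed("mgcv")
  set.seed(21)
  rects <- list(c(5, 25, 5, 25), c(40, 70, 10, 30), c(10, 30, 50, 90))
  cls <- c("neg_tumor", "pos_tumor", "other")
  polys <- dplyr::bind_rows(purrr::imap(rects, function(r, i) {
    labeled_polygon(c(r[1], r[2], r[2], r[1]), c(r[3], r[3], r[4], r[4]),
                    cls[i], paste0("p", i))
  }))
  pts <- data.frame(x_um = runif(200, 0, 100), y_um = runif(200, 0, 100))
  got <- label_points_by_polygons(pts, polys)
  for (i in seq_along(rects)) {
    p <- polys[polys$polygon_id == paste0("p", i), ]
    inside <- mgcv::in.out(as.matrix(rbind(p[, c("x_um", "y_um")],
                                           p[1, c("x_um", "y_um")])),
                           as.matrix(pts))
    want <- pts[inside, ]
    sub <- got[got$class == cls[i], ]
    expect_setequal(paste(sub$x_um, sub$y_um), paste(want$x_um, want$y_um))
  }
})

test_that("boundary points count as inside", {
  poly <- labeled_polygon(c(0, 10, 10, 0), c(0, 0, 10, 10), "other")
  out <- label_points_by_polygons(data.frame(x_um = c(0, 5, 10),
                                             y_um = c(0, 0, 5)), poly)
  expect_equal(nrow(out), 3)
})

test_that("overlapping polygons follow the tie rule", {
  big <- labeled_polygon(c(0, 40, 40, 0), c(0, 0, 40, 40), "other", "big")
  small <- labeled_polygon(c(10, 20, 20, 10), c(10, 10, 20, 20),
                           "pos_tumor", "small")
  polys <- dplyr::bind_rows(big, small)
  pt <- data.frame(x_um = 15, y_um = 15)
  expect_equal(label_points_by_polygons(pt, polys)$class, "pos_tumor")
  expect_error(label_points_by_polygons(pt, polys, tie = "strict"),
               "overlapping")
  # same-class overlap is not a conflict even in strict mode
  twin <- labeled_polygon(c(5, 30, 30, 5), c(5, 5, 30, 30), "other", "twin")
  ok <- label_points_by_polygons(pt, dplyr::bind_rows(big, twin),
                                 tie = "strict")
  expect_equal(ok$class, "other")
})

test_that("degenerate polygons are rejected", {
  expect_error(labeled_polygon(c(0, 1), c(0, 1), "other"), "3 distinct")
  expect_error(labeled_polygon(c(0, 10, 0, 10), c(0, 10, 10, 0), "other"),
               "self-intersecting")
})

test_that("point-box conversion uses the 20 um convention and round trips", {
  b <- points_to_boxes(data.frame(x_um = 30, y_um = 40))
  expect_equal(c(b$xmin_um, b$xmax_um), c(20, 40))
  expect_equal(c(b$ymin_um, b$ymax_um), c(30, 50))

  s <- points_to_boxes(data.frame(x_um = 30, y_um = 40), side_um = 0.5)
  expect_equal(c(s$xmin_um, s$xmax_um), c(29.75, 30.25))
  expect_equal(c(s$ymin_um, s$ymax_um), c(39.75, 40.25))

  set.seed(2)
  pts <- data.frame(x_um = runif(50, 0, 300), y_um = runif(50, 0, 300),
                    class = sample(cell_classes(), 50, TRUE))
  back <- boxes_to_points(points_to_boxes(pts))
  expect_equal(back$x_um, pts$x_um)
  expect_equal(back$y_um, pts$y_um)
  expect_equal(back$class, pts$class)

  # centers recovered from corner columns alone
  corners <- points_to_boxes(pts)[, c("xmin_um", "xmax_um", "ymin_um", "ymax_um")]
  expect_equal(boxes_to_points(corners)$x_um, pts$x_um)
})

test_that("semi-automatic annotation recovers labels on a rendered ROI", {
  roi <- generate_tissue_roi(width_um = 120, height_um = 120,
                             tumor_per_mm2 = 1800, other_per_mm2 = 600,
                             positivity = 0.5, d_min = 12, seed = 31,
                             render = TRUE)
  det <- detect_nuclei(roi$image, roi$spacing_um_per_px)
  # one polygon per true class region: label transfer via nearest-truth class
  # is emulated with small squares around each true cell
  polys <- dplyr::bind_rows(purrr::map(seq_len(nrow(roi$cells)), function(i) {
    x <- roi$cells$x_um[i]; y <- roi$cells$y_um[i]; h <- 5
    labeled_polygon(c(x - h, x + h, x + h, x - h), c(y - h, y - h, y + h, y + h),
                    roi$cells$class[i], sprintf("p%03d", i))
  }))
  lab <- label_points_by_polygons(det, polys)
  m <- match_points(
    as_truth <- annotation_set(roi$cells$x_um, roi$cells$y_um,
                               roi$cells$class, source = "truth"),
    lab, radius_um = 3)
  expect_gte(nrow(m$pairs), floor(0.9 * nrow(roi$cells)))
  agree <- mean(m$pairs$ref_class == m$pairs$pred_class)
  expect_gte(agree, 0.96)
})
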