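#' Build a labeled polygon table
#'
#' Free-hand region annotations are stored as a tidy vertex table: one row
#' per vertex, grouped by `polygon_id`, each polygon carrying a single cell
#' class. Rings are implicitly closed (the last vertex connects back to the
#' first), must have at least three distinct vertices, and must be simple
#' (non-self-intersecting).
#'
#' @param x_um,y_um Vertex coordinates in um, in ring order.
#' @param class Single class label for the polygon.
#' @param polygon_id Polygon identifier.
#' @param roi_id ROI identifier.
#' @return Tibble with columns `polygon_id`, `roi_id`, `class`, `x_um`,
#'   `y_um`.
#' @export
#' @examples
#' labeled_polygon(c(0, 10, 10, 0), c(0, 0, 10, 10), "pos_tumor", "p1")
labeled_polygon <- function(x_um, y_um, class, polygon_id = "poly_1",
                            roi_id = "roi") {
  stopifnot(length(x_um) == length(y_um), length(class) == 1)
  check_classes(class)
  validate_ring(cbind(x_um, y_um), polygon_id)
  tibble::tibble(polygon_id = polygon_id, roi_id = roi_id, class = class,
                 x_um = as.numeric(x_um), y_um = as.numeric(y_um))
}

validate_ring <- function(v, id = "polygon") {
  # drop a duplicated closing vertex if present
  n <- nrow(v)
  if (n >= 2 && all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (nrow(unique(v)) < 3) {
    stop(sprintf("polygon '%s' needs >= 3 distinct vertices", id), call. = FALSE)
  }
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (b == a + 1 || (a == 1 && b == n)) next  # adjacent edges share a vertex
      if (segments_cross(seg[a, 1:2], seg[a, 3:4], seg[b, 1:2], seg[b, 3:4])) {
        stop(sprintf("polygon '%s' is self-intersecting", id), call. = FALSE)
      }
    }
  }
  invisible(v)
}

segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# Even-odd (ray crossing) point-in-polygon; points on the boundary count as
# inside. vx/vy: ring vertices (not closed). Returns logical vector over px.
point_in_ring <- function(px, py, vx, vy, eps = 1e-9) {
  n <- length(vx)
  out <- logical(length(px))
  for (k in seq_along(px)) {
    x <- px[k]; y <- py[k]
    inside <- FALSE; on_edge <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
      # boundary test: collinear and within the segment's bounding box
      cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
      seg_len <- sqrt((xj - xi)^2 + (yj - yi)^2)
      if (seg_len > 0 && abs(cross) / seg_len <= eps &&
          x >= min(xi, xj) - eps && x <= max(xi, xj) + eps &&
          y >= min(yi, yj) - eps && y <= max(yi, yj) + eps) {
        on_edge <- TRUE
        break
      }
      if ((yi > y) != (yj > y)) {
        xint <- xi + (y - yi) * (xj - xi) / (yj - yi)
        if (x < xint) inside <- !inside
      }
      j <- i
    }
    out[k] <- on_edge || inside
  }
  out
}

ring_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(2:n, 1)
  abs(sum(vx * vy[j] - vx[j] * vy)) / 2
}

#' Transfer polygon labels to detected points
#'
#' The second step of the semi-automatic annotation pipeline: each detected
#' nucleus center falling inside a free-hand polygon receives that polygon's
#' class. Points inside no polygon are discarded (the detector found a cell
#' the annotator did not enclose). Points inside several polygons follow the
#' tie rule: by default the smallest-area polygon wins (annotators refine
#' inside larger regions); with `tie = "strict"` overlapping polygons of
#' different classes raise an error listing the offending points.
#'
#' @param points Data frame with `x_um`, `y_um` (e.g. [detect_nuclei()]
#'   output).
#' @param polygons Labeled polygon table as from [labeled_polygon()]
#'   (rows bound together for several polygons).
#' @param tie `"smallest"` (default) or `"strict"`.
#' @param source,roi_id Identifiers stamped on the output annotation set.
#' @return Annotation-set tibble, sorted by `y_um` then `x_um`; a subset of
#'   the input points by coordinates (never invents points).
#' @export
#' @examples
#' polys <- labeled_polygon(c(0, 20, 20, 0), c(0, 0, 20, 20), "neg_tumor")
#' pts <- data.frame(x_um = c(5, 30), y_um = c(5, 5))
#' label_points_by_polygons(pts, polys)
label_points_by_polygons <- function(points, polygons,
                                     tie = c("smallest", "strict"),
                                     source = "semiauto", roi_id = "roi") {
  tie <- match.arg(tie)
  stopifnot(all(c("x_um", "y_um") %in% names(points)),
            all(c("polygon_id", "class", "x_um", "y_um") %in% names(polygons)))
  pts <- tibble::as_tibble(points)
  polys <- split(polygons, polygons$polygon_id)
  if (nrow(pts) == 0 || length(polys) == 0) {
    return(annotation_set(source = source, roi_id = roi_id))
  }
  hits <- purrr::map(polys, function(p) {
    validate_ring(cbind(p$x_um, p$y_um), p$polygon_id[1])
    point_in_ring(pts$x_um, pts$y_um, p$x_um, p$y_um)
  })
  areas <- purrr::map_dbl(polys, ~ ring_area(.x$x_um, .x$y_um))
  classes <- purrr::map_chr(polys, ~ .x$class[1])
  hit_mat <- do.call(cbind, hits)  # points x polygons
  n_hit <- rowSums(hit_mat)
  label <- rep(NA_character_, nrow(pts))
  multi <- which(n_hit > 1)
  if (length(multi) > 0) {
    conflicted <- multi[vapply(multi, function(k) {
      length(unique(classes[hit_mat[k, ]])) > 1
    }, logical(1))]
    if (tie == "strict" && length(conflicted) > 0) {
      coords <- paste(sprintf("(%.3g, %.3g)", pts$x_um[conflicted],
                              pts$y_um[conflicted]), collapse = ", ")
      stop("points inside overlapping polygons of different classes: ",
           coords, call. = FALSE)
    }
  }
  for (k in which(n_hit > 0)) {
    in_polys <- which(hit_mat[k, ])
    label[k] <- classes[in_polys[which.min(areas[in_polys])]]
  }
  keep <- !is.na(label)
  out <- annotation_set(pts$x_um[keep], pts$y_um[keep], label[keep],
                        source = source, roi_id = roi_id)
  dplyr::arrange(out, .data$y_um, .data$x_um)
}

#' Convert between point annotations and detection boxes
#'
#' Object detectors work with bounding boxes; cell annotations are points.
#' `points_to_boxes()` centers a square box of side `side_um` (default the
#' 20 um convention for training boxes) on each point; `boxes_to_points()`
#' takes box centers as the detection locations. The two are mutually
#' inverse on centers.
#'
#' @param points Data frame with `x_um`, `y_um` and optionally `class`,
#'   `confidence`.
#' @param side_um Box side length in um (> 0).
#' @return `points_to_boxes()`: tibble with `x_um`, `y_um`, `side_um`,
#'   `xmin_um`, `xmax_um`, `ymin_um`, `ymax_um` (plus `class`/`confidence`
#'   when present); `boxes_to_points()`: tibble of centers.
#' @export
#' @examples
#' points_to_boxes(data.frame(x_um = 30, y_um = 40))
points_to_boxes <- function(points, side_um = 20) {
  stopifnot(side_um > 0, all(c("x_um", "y_um") %in% names(points)))
  out <- tibble::as_tibble(points)
  out$side_um <- side_um
  out$xmin_um <- out$x_um - side_um / 2
  out$xmax_um <- out$x_um + side_um / 2
  out$ymin_um <- out$y_um - side_um / 2
  out$ymax_um <- out$y_um + side_um / 2
  out
}

#' @rdname points_to_boxes
#' @param boxes Tibble from [points_to_boxes()] or any frame with
#'   `xmin_um`/`xmax_um`/`ymin_um`/`ymax_um`.
#' @export
boxes_to_points <- function(boxes) {
  b <- tibble::as_tibble(boxes)
  if (!all(c("x_um", "y_um") %in% names(b))) {
    b$x_um <- (b$xmin_um + b$xmax_um) / 2
    b$y_um <- (b$ymin_um + b$ymax_um) / 2
  }
  dplyr::select(b, -dplyr::any_of(c("side_um", "xmin_um", "xmax_um",
                                    "ymin_um", "ymax_um")))
}
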