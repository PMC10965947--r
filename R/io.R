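#' Read and write annotation sets
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`csv`}{Columns `roi_id`, `reader_id`, `x_um`, `y_um`, `class`,
#'     `confidence` (confidence may be empty); UTF-8 with a header row.
#'     `reader_id` maps to the in-memory `source` column.}
#'   \item{`geojson`}{FeatureCollection of Point features with properties
#'     `class`, `source`, `roi_id` (geometry coordinates in um).}
#'   \item{`asap-xml`}{The ASAP whole-slide viewer dialect:
#'     `<Annotation Type="Dot">` (points) and `<Annotation Type="Polygon">`
#'     with `<Coordinate X= Y=>` children. Coordinates are pixels and are
#'     converted to um via `spacing_um_per_px`; the class is taken from the
#'     `PartOfGroup` attribute. Read-only.}
#' }
#' Round trips through csv/geojson are lossless for coordinates (to 1e-6
#' um), labels and source ids. Unknown class labels and malformed rows are
#' rejected with the offending row/feature identified.
#'
#' @param path File path.
#' @param dialect One of `"csv"`, `"geojson"`, `"asap-xml"`; guessed from
#'   the file extension by default.
#' @param spacing_um_per_px Pixel spacing, required for `asap-xml`.
#' @return `read_annotations()` returns an annotation-set tibble (for
#'   `asap-xml`, point annotations; polygons via [read_asap_polygons()]);
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path, dialect = NULL, spacing_um_per_px = NULL) {
  dialect <- dialect %||% guess_dialect(path)
  switch(dialect,
    csv = read_annotations_csv(path),
    geojson = read_annotations_geojson(path),
    `asap-xml` = read_asap_xml(path, spacing_um_per_px)$points,
    stop("unknown dialect: ", dialect, call. = FALSE))
}

guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = "csv", geojson = "geojson", json = "geojson",
         xml = "asap-xml",
         stop("cannot guess annotation dialect from extension '", ext, "'",
              call. = FALSE))
}

read_annotations_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("roi_id", "reader_id", "x_um", "y_um", "class")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("annotation csv is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$class %in% cell_classes() | is.na(df$x_um) | is.na(df$y_um))
  if (length(bad) > 0) {
    stop("malformed annotation row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "),
         " (unknown class or missing coordinate)", call. = FALSE)
  }
  if (!"confidence" %in% names(df)) df$confidence <- NA_real_
  annotation_set(df$x_um, df$y_um, df$class, source = df$reader_id,
                 roi_id = df$roi_id, confidence = df$confidence)
}

#' @rdname read_annotations
#' @param annotations Annotation-set tibble to write.
#' @export
write_annotations <- function(annotations, path, dialect = NULL) {
  dialect <- dialect %||% guess_dialect(path)
  ann <- as_annotation_set(annotations)
  if (dialect == "csv") {
    out <- dplyr::rename(ann, reader_id = "source")
    readr::write_csv(out, path, progress = FALSE)
  } else if (dialect == "geojson") {
    features <- purrr::pmap(ann, function(roi_id, source, x_um, y_um, class,
                                          confidence) {
      props <- list(class = class, source = source, roi_id = roi_id)
      if (!is.na(confidence)) props$confidence <- confidence
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = c(x_um, y_um)),
           properties = props)
    })
    fc <- list(type = "FeatureCollection", features = features)
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("write_annotations() supports dialects 'csv' and 'geojson'",
         call. = FALSE)
  }
  invisible(path)
}

read_annotations_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  }
  rows <- purrr::imap(fc$features, function(f, i) {
    if (!identical(f$geometry$type, "Point")) {
      stop(sprintf("feature %d: expected Point geometry, got %s",
                   i, f$geometry$type %||% "none"), call. = FALSE)
    }
    cls <- f$properties$class
    if (is.null(cls)) {
      stop(sprintf("feature %d: missing 'class' property", i), call. = FALSE)
    }
    if (!cls %in% cell_classes()) {
      stop(sprintf("feature %d: unknown class '%s'", i, cls), call. = FALSE)
    }
    tibble::tibble(
      roi_id = f$properties$roi_id %||% "roi",
      source = f$properties$source %||% "unknown",
      x_um = as.numeric(f$geometry$coordinates[[1]]),
      y_um = as.numeric(f$geometry$coordinates[[2]]),
      class = cls,
      confidence = as.numeric(f$properties$confidence %||% NA_real_))
  })
  dplyr::bind_rows(rows) |>
    (\(df) if (nrow(df) == 0) annotation_set() else df)()
}

#' Read ASAP XML annotations
#'
#' Parses the ASAP annotation XML dialect. `Dot` annotations become point
#' annotations; `Polygon` annotations become labeled polygon tables (class
#' from the `PartOfGroup` attribute, optionally remapped via `class_map`).
#' Coordinates in the file are pixels and are converted to um.
#'
#' @param path XML file path.
#' @param spacing_um_per_px Pixel spacing in um per pixel (required, > 0).
#' @param class_map Optional named character vector remapping `PartOfGroup`
#'   values onto [cell_classes()].
#' @param source Source id stamped on the points.
#' @return List with `points` (annotation-set tibble) and `polygons`
#'   (labeled polygon tibble).
#' @export
read_asap_xml <- function(path, spacing_um_per_px, class_map = NULL,
                          source = "asap") {
  if (is.null(spacing_um_per_px) || spacing_um_per_px <= 0) {
    stop("asap-xml coordinates are pixels; a positive spacing_um_per_px is required",
         call. = FALSE)
  }
  doc <- xml2::read_xml(path)
  anns <- xml2::xml_find_all(doc, ".//Annotation")
  pts <- list(); polys <- list()
  for (a in anns) {
    type <- xml2::xml_attr(a, "Type")
    grp <- xml2::xml_attr(a, "PartOfGroup")
    cls <- if (!is.null(class_map) && grp %in% names(class_map))
      unname(class_map[grp]) else grp
    check_classes(cls)
    coords <- xml2::xml_find_all(a, ".//Coordinate")
    x <- as.numeric(xml2::xml_attr(coords, "X")) * spacing_um_per_px
    y <- as.numeric(xml2::xml_attr(coords, "Y")) * spacing_um_per_px
    ord <- xml2::xml_attr(coords, "Order")
    if (!all(is.na(ord))) {
      o <- order(as.numeric(ord)); x <- x[o]; y <- y[o]
    }
    if (identical(type, "Dot")) {
      pts[[length(pts) + 1]] <- annotation_set(x, y, rep(cls, length(x)),
                                               source = source)
    } else if (identical(type, "Polygon")) {
      polys[[length(polys) + 1]] <-
        labeled_polygon(x, y, cls, polygon_id = xml2::xml_attr(a, "Name"))
    }
  }
  list(points = if (length(pts)) dplyr::bind_rows(pts) else annotation_set(),
       polygons = if (length(polys)) dplyr::bind_rows(polys) else
         tibble::tibble(polygon_id = character(), roi_id = character(),
                        class = character(), x_um = numeric(),
                        y_um = numeric()))
}

#' Read and write labeled polygons as GeoJSON
#'
#' FeatureCollection of Polygon features with a `class` property; ring
#' coordinates in um. The closing vertex is added on write and dropped on
#' read.
#'
#' @param polygons Labeled polygon tibble (see [labeled_polygon()]).
#' @param path File path.
#' @return `read_polygons()` returns a labeled polygon tibble.
#' @export
write_polygons <- function(polygons, path) {
  features <- purrr::map(split(polygons, polygons$polygon_id), function(p) {
    ring <- cbind(p$x_um, p$y_um)
    ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))),
         properties = list(class = p$class[1], polygon_id = p$polygon_id[1],
                           roi_id = p$roi_id[1]))
  })
  fc <- list(type = "FeatureCollection", features = unname(features))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons
#' @export
read_polygons <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- purrr::imap(fc$features, function(f, i) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop(sprintf("feature %d: expected Polygon geometry", i), call. = FALSE)
    }
    cls <- f$properties$class
    if (is.null(cls)) {
      stop(sprintf("feature %d: missing 'class' property", i), call. = FALSE)
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    if (nrow(ring) >= 2 && all(ring[1, ] == ring[nrow(ring), ])) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    labeled_polygon(ring[, 1], ring[, 2], cls,
                    polygon_id = f$properties$polygon_id %||%
                      sprintf("poly_%d", i),
                    roi_id = f$properties$roi_id %||% "roi")
  })
  dplyr::bind_rows(rows)
}

#' Write a ground-truth ROI to disk
#'
#' Writes the rendered image as PNG (when present), the truth points as a
#' GeoJSON FeatureCollection (source `"truth"`), and a sidecar JSON with
#' the geometry metadata (`width_um`, `height_um`, `spacing_um_per_px`,
#' `seed`).
#'
#' @param roi An object from [generate_tissue_roi()].
#' @param dir Output directory (created if absent).
#' @param name Basename for the three files.
#' @return The directory path, invisibly.
#' @export
write_roi <- function(roi, dir, name = "roi") {
  stopifnot(inherits(roi, "roi"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(roi$image)) {
    png::writePNG(roi$image, file.path(dir, paste0(name, ".png")))
  }
  pts <- as_annotation_set(roi$cells, source = "truth", roi_id = name)
  write_annotations(pts, file.path(dir, paste0(name, ".geojson")))
  meta <- list(width_um = roi$width_um, height_um = roi$height_um,
               spacing_um_per_px = roi$spacing_um_per_px, seed = roi$seed)
  jsonlite::write_json(meta, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read and write slide-level TPS tables
#'
#' CSV with columns `case_id`, `source_id`, `tps_pct` and optional counts
#' `n_pos`, `n_neg`; `source_id` maps to the in-memory `source` column.
#'
#' @param tps Long TPS tibble (`case_id`, `source`, `tps_pct`, ...).
#' @param path File path.
#' @return `read_tps()` returns the long tibble.
#' @export
write_tps <- function(tps, path) {
  stopifnot(all(c("case_id", "source", "tps_pct") %in% names(tps)))
  out <- dplyr::rename(tps, source_id = "source")
  keep <- intersect(c("case_id", "source_id", "tps_pct", "n_pos", "n_neg"),
                    names(out))
  readr::write_csv(out[keep], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tps
#' @export
read_tps <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("case_id", "source_id", "tps_pct")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("tps csv is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(df$tps_pct) | df$tps_pct < 0 | df$tps_pct > 100)
  if (length(bad) > 0) {
    stop("tps out of [0, 100] or missing at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  dplyr::rename(df, source = "source_id")
}
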