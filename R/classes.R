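#' Cell class labels
#'
#' The three cell classes used throughout the package: PD-L1 negative tumor
#' cells, PD-L1 positive tumor cells and "other" (non-tumor / to-be-excluded)
#' cells. `"background"` is a reserved sentinel used only in confusion
#' matrices to book-keep presence/absence disagreements; it never appears on
#' an annotated point.
#'
#' @return `cell_classes()` returns a character vector of the three point
#'   classes; `confusion_classes()` appends the `"background"` sentinel.
#' @export
#' @examples
#' cell_classes()
cell_classes <- function() c("neg_tumor", "pos_tumor", "other")

#' @rdname cell_classes
#' @export
confusion_classes <- function() c(cell_classes(), "background")

BACKGROUND <- "background"

#' Build an annotation set
#'
#' An annotation set is a tibble of cell points from one source (a reader or
#' a detector) on one or more regions of interest. Coordinates are continuous
#' micrometers with the origin at the ROI top-left corner, x rightward and y
#' downward.
#'
#' @param x_um,y_um Numeric point coordinates in micrometers.
#' @param class Character vector of classes, each one of [cell_classes()].
#' @param source Source identifier (reader or detector id). Length 1 or
#'   `length(x_um)`.
#' @param roi_id ROI identifier. Length 1 or `length(x_um)`.
#' @param confidence Optional numeric confidence in `[0, 1]` (`NA` allowed).
#' @return A tibble with columns `roi_id`, `source`, `x_um`, `y_um`,
#'   `class`, `confidence`.
#' @export
#' @examples
#' annotation_set(c(10, 20), c(5, 5), c("pos_tumor", "other"), source = "r1")
annotation_set <- function(x_um = numeric(), y_um = numeric(),
                           class = character(), source = "unknown",
                           roi_id = "roi", confidence = NA_real_) {
  stopifnot(length(x_um) == length(y_um), length(class) == length(x_um))
  if (length(x_um) == 0) {
    return(tibble::tibble(roi_id = character(), source = character(),
                          x_um = numeric(), y_um = numeric(),
                          class = character(), confidence = numeric()))
  }
  check_classes(class)
  tibble::tibble(
    roi_id = as.character(rep_len(roi_id, length(x_um))),
    source = as.character(rep_len(source, length(x_um))),
    x_um = as.numeric(x_um), y_um = as.numeric(y_um),
    class = as.character(class),
    confidence = as.numeric(rep_len(confidence, length(x_um)))
  )
}

check_classes <- function(class, allow_background = FALSE) {
  allowed <- if (allow_background) confusion_classes() else cell_classes()
  bad <- setdiff(unique(class), allowed)
  if (length(bad) > 0) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  invisible(class)
}

# Coerce a loose points data frame (x_um/y_um/class [...]) to annotation-set
# columns, filling defaults.
as_annotation_set <- function(df, source = NULL, roi_id = NULL) {
  stopifnot(all(c("x_um", "y_um", "class") %in% names(df)))
  df <- tibble::as_tibble(df)
  if (!"source" %in% names(df)) df$source <- source %||% "unknown"
  if (!"roi_id" %in% names(df)) df$roi_id <- roi_id %||% "roi"
  if (!"confidence" %in% names(df)) df$confidence <- NA_real_
  check_classes(df$class)
  dplyr::select(df, "roi_id", "source", "x_um", "y_um", "class", "confidence")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %.0f x %.0f um, %.3g um/px, %d cells (seed %s)\n",
              x$width_um, x$height_um, x$spacing_um_per_px,
              nrow(x$cells), format(x$seed)))
  if (nrow(x$cells) > 0) {
    print(table(factor(x$cells$class, levels = cell_classes())))
  }
  invisible(x)
}
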