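#' Match two point sets under the hit criterion
#'
#' Distance-gated matching between a reference and a prediction annotation
#' set on the same ROI: a prediction can hit a reference point only within
#' `radius_um` (8 um, the average tumor/immune nucleus diameter; the
#' boundary distance counts as a hit), and when several predictions fall in
#' the radius only the closest one takes the hit.
#'
#' The default `mode = "one_to_one"` is a symmetric global-greedy matching:
#' all reference-prediction pairs within the radius are sorted by ascending
#' distance and accepted when neither member is already matched. Ties are
#' broken by (reference rank, prediction rank) after sorting each set
#' lexicographically by (y, x), so the result is deterministic and
#' independent of input row order. `mode = "reference"` is the
#' reference-sided variant for sensitivity analysis: every reference takes
#' its closest in-radius prediction and predictions may be reused.
#'
#' @param reference,prediction Annotation-set tibbles (see
#'   [annotation_set()]) on the same ROI; coordinates in um.
#' @param radius_um Hit radius in um (> 0), default 8.
#' @param mode `"one_to_one"` (default) or `"reference"`.
#' @return Object of class `"cell_match"`: list with `pairs` (tibble
#'   `ref_x`, `ref_y`, `ref_class`, `pred_x`, `pred_y`, `pred_class`,
#'   `distance_um`), `unmatched_ref`, `unmatched_pred`, `radius_um`,
#'   `mode`, `roi_id`.
#' @export
#' @examples
#' ref <- annotation_set(0, 0, "pos_tumor", source = "r1")
#' pred <- annotation_set(c(0, 0), c(7.9, 8.1), c("pos_tumor", "pos_tumor"),
#'                        source = "ai")
#' match_points(ref, pred)$pairs
match_points <- function(reference, prediction, radius_um = 8,
                         mode = c("one_to_one", "reference")) {
  mode <- match.arg(mode)
  stopifnot(radius_um > 0)
  ref <- as_annotation_set(reference)
  pred <- as_annotation_set(prediction)
  roi_r <- unique(ref$roi_id); roi_p <- unique(pred$roi_id)
  if (length(roi_r) > 1 || length(roi_p) > 1) {
    stop("match_points() operates on a single ROI per call", call. = FALSE)
  }
  if (length(roi_r) == 1 && length(roi_p) == 1 && roi_r != roi_p) {
    stop(sprintf("reference and prediction are on different ROIs ('%s' vs '%s')",
                 roi_r, roi_p), call. = FALSE)
  }
  nr <- nrow(ref); np <- nrow(pred)
  ref_rank <- if (nr > 0) order(order(ref$y_um, ref$x_um)) else integer()
  pred_rank <- if (np > 0) order(order(pred$y_um, pred$x_um)) else integer()
  pair_i <- integer(0); pair_j <- integer(0); pair_d <- numeric(0)
  if (nr > 0 && np > 0) {
    cd <- candidate_pairs(ref$x_um, ref$y_um, pred$x_um, pred$y_um, radius_um)
    cand <- cd$cand
    if (nrow(cand) > 0) {
      d <- cd$d
      ord <- order(d, ref_rank[cand[, 1]], pred_rank[cand[, 2]])
      cand <- cand[ord, , drop = FALSE]; d <- d[ord]
      if (mode == "one_to_one") {
        ref_used <- logical(nr); pred_used <- logical(np)
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!ref_used[i] && !pred_used[j]) {
            ref_used[i] <- TRUE; pred_used[j] <- TRUE
            pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
            pair_d <- c(pair_d, d[k])
          }
        }
      } else {
        ref_used <- logical(nr)
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]
          if (!ref_used[i]) {
            ref_used[i] <- TRUE
            pair_i <- c(pair_i, i); pair_j <- c(pair_j, cand[k, 2])
            pair_d <- c(pair_d, d[k])
          }
        }
      }
    }
  }
  ord <- order(pair_d, if (length(pair_i)) ref_rank[pair_i] else integer())
  pair_i <- pair_i[ord]; pair_j <- pair_j[ord]; pair_d <- pair_d[ord]
  pairs <- tibble::tibble(
    ref_x = ref$x_um[pair_i], ref_y = ref$y_um[pair_i],
    ref_class = ref$class[pair_i],
    pred_x = pred$x_um[pair_j], pred_y = pred$y_um[pair_j],
    pred_class = pred$class[pair_j],
    distance_um = pair_d)
  structure(
    list(pairs = pairs,
         unmatched_ref = ref[setdiff(seq_len(nr), pair_i), , drop = FALSE],
         unmatched_pred = pred[setdiff(seq_len(np), unique(pair_j)), , drop = FALSE],
         radius_um = radius_um, mode = mode,
         roi_id = if (length(roi_r)) roi_r else if (length(roi_p)) roi_p else "roi",
         ref_source = if (nr > 0) ref$source[1] else NA_character_,
         pred_source = if (np > 0) pred$source[1] else NA_character_),
    class = "cell_match")
}

# All (reference, prediction) index pairs within `radius` of each other.
# Small problems use a dense distance matrix; large ones bucket the
# predictions on a grid of cell size `radius` so memory stays linear.
candidate_pairs <- function(rx, ry, px, py, radius) {
  nr <- length(rx); np <- length(px)
  if (as.double(nr) * np <= 4e6) {
    dmat <- sqrt(outer(rx, px, `-`)^2 + outer(ry, py, `-`)^2)
    cand <- which(dmat <= radius, arr.ind = TRUE)
    dimnames(cand) <- NULL
    return(list(cand = cand, d = dmat[cand]))
  }
  gx <- floor(px / radius); gy <- floor(py / radius)
  buckets <- split(seq_len(np), paste(gx, gy))
  out_i <- vector("list", nr); out_j <- vector("list", nr)
  out_d <- vector("list", nr)
  for (i in seq_len(nr)) {
    cx <- floor(rx[i] / radius); cy <- floor(ry[i] / radius)
    js <- unlist(buckets[paste(rep(cx + (-1:1), each = 3), cy + (-1:1))],
                 use.names = FALSE)
    if (length(js) == 0) next
    d <- sqrt((rx[i] - px[js])^2 + (ry[i] - py[js])^2)
    keep <- d <= radius
    if (any(keep)) {
      out_i[[i]] <- rep.int(i, sum(keep))
      out_j[[i]] <- js[keep]
      out_d[[i]] <- d[keep]
    }
  }
  ii <- unlist(out_i); jj <- unlist(out_j)
  if (is.null(ii)) {
    return(list(cand = matrix(integer(), 0, 2), d = numeric()))
  }
  list(cand = cbind(ii, jj, deparse.level = 0), d = unlist(out_d))
}

#' @export
print.cell_match <- function(x, ...) {
  cat(sprintf("<cell_match> %d pairs, %d unmatched reference, %d unmatched prediction (radius %g um, %s)\n",
              nrow(x$pairs), nrow(x$unmatched_ref), nrow(x$unmatched_pred),
              x$radius_um, x$mode))
  invisible(x)
}

#' Confusion matrix from a match result
#'
#' Builds the 4x4 confusion matrix over the three cell classes plus the
#' `"background"` sentinel: matched pairs count into
#' (reference class, prediction class); a reference without an associated
#' prediction counts into (class, background) — a false negative; a
#' prediction hitting no reference counts into (background, class) — a
#' false positive. The (background, background) cell is structurally zero.
#'
#' @param match A `"cell_match"` from [match_points()].
#' @return Integer matrix with dimnames [confusion_classes()] (rows =
#'   reference, columns = prediction).
#' @export
confusion_from_match <- function(match) {
  stopifnot(inherits(match, "cell_match"))
  lv <- confusion_classes()
  m <- matrix(0L, 4, 4, dimnames = list(reference = lv, prediction = lv))
  p <- match$pairs
  if (nrow(p) > 0) {
    t1 <- table(factor(p$ref_class, lv), factor(p$pred_class, lv))
    m <- m + unclass(t1)
  }
  if (nrow(match$unmatched_ref) > 0) {
    m[, BACKGROUND] <- m[, BACKGROUND] +
      as.integer(table(factor(match$unmatched_ref$class, lv)))
  }
  if (nrow(match$unmatched_pred) > 0) {
    m[BACKGROUND, ] <- m[BACKGROUND, ] +
      as.integer(table(factor(match$unmatched_pred$class, lv)))
  }
  storage.mode(m) <- "integer"
  m
}

#' Fraction of disagreements involving the background class
#'
#' Of all disagreements between two sources (off-diagonal confusion counts),
#' the fraction that are presence/absence disagreements — one source placed
#' a cell where the other saw none — rather than class confusions.
#'
#' @param conf Confusion matrix from [confusion_from_match()] (or a sum of
#'   several).
#' @return Fraction in `[0, 1]`; `NA` (flagged, never 0) when there are no
#'   disagreements at all.
#' @export
background_disagreement_fraction <- function(conf) {
  stopifnot(is.matrix(conf), all(dim(conf) == c(4, 4)))
  off <- sum(conf) - sum(diag(conf))
  if (off == 0) {
    return(structure(NA_real_, reason = "no disagreements"))
  }
  bg <- sum(conf[BACKGROUND, ]) + sum(conf[, BACKGROUND]) -
    2 * conf[BACKGROUND, BACKGROUND]
  as.numeric(bg / off)
}
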