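# Independent oracles used across the test files. These deliberately take
# the slow, literal route (full enumeration, first-principles arithmetic) so
# they stay independent of the package's vectorized implementations.

# Exhaustive closest-first one-to-one matching: enumerate every remaining
# reference-prediction pair, repeatedly accept the globally closest one
# (ties by reference rank then prediction rank after lexicographic (y, x)
# sort), until no pair within the radius remains.
oracle_greedy_match <- function(ref, pred, radius) {
  nr <- nrow(ref); np <- nrow(pred)
  ref_rank <- order(order(ref$y_um, ref$x_um))
  pred_rank <- order(order(pred$y_um, pred$x_um))
  ref_free <- rep(TRUE, nr); pred_free <- rep(TRUE, np)
  pairs <- list()
  repeat {
    best <- NULL
    for (i in seq_len(nr)) {
      if (!ref_free[i]) next
      for (j in seq_len(np)) {
        if (!pred_free[j]) next
        d <- sqrt((ref$x_um[i] - pred$x_um[j])^2 +
                    (ref$y_um[i] - pred$y_um[j])^2)
        if (d > radius) next
        key <- c(d, ref_rank[i], pred_rank[j])
        if (is.null(best) || key[1] < best$key[1] ||
            (key[1] == best$key[1] && (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    if (is.null(best)) break
    ref_free[best$i] <- FALSE; pred_free[best$j] <- FALSE
    pairs[[length(pairs) + 1]] <- c(best$i, best$j)
  }
  if (length(pairs) == 0) return(matrix(integer(), 0, 2))
  do.call(rbind, pairs)
}

# Canonical representation of a pair set for comparison: sorted coordinate
# tuples.
pair_signature <- function(pairs_df) {
  if (nrow(pairs_df) == 0) return(character())
  sort(sprintf("%.9f_%.9f_%.9f_%.9f", pairs_df$ref_x, pairs_df$ref_y,
               pairs_df$pred_x, pairs_df$pred_y))
}

random_instance <- function(n_ref, n_pred, box = 50) {
  list(
    ref = annotation_set(runif(n_ref, 0, box), runif(n_ref, 0, box),
                         sample(cell_classes(), n_ref, replace = TRUE),
                         source = "a"),
    pred = annotation_set(runif(n_pred, 0, box), runif(n_pred, 0, box),
                          sample(cell_classes(), n_pred, replace = TRUE),
                          source = "b"))
}

# First-principles weighted kappa from a k x k contingency table of counts.
oracle_weighted_kappa <- function(tab, weights = c("linear", "unweighted")) {
  weights <- match.arg(weights)
  k <- nrow(tab)
  n <- sum(tab)
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  w <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    w[i, j] <- if (weights == "linear") 1 - abs(i - j) / (k - 1)
               else as.numeric(i == j)
  }
  po <- 0; pe <- 0
  for (i in 1:k) for (j in 1:k) {
    po <- po + w[i, j] * p[i, j]
    pe <- pe + w[i, j] * pr[i] * pc[j]
  }
  (po - pe) / (1 - pe)
}

# Ratings pair drawn from a contingency table of counts.
ratings_from_table <- function(tab) {
  k <- nrow(tab)
  a <- integer(0); b <- integer(0)
  for (i in 1:k) for (j in 1:k) {
    a <- c(a, rep(i - 1L, tab[i, j]))
    b <- c(b, rep(j - 1L, tab[i, j]))
  }
  list(a = a, b = b)
}

# Two-way ANOVA mean squares via stats::aov, as an independent route to the
# ICC(2,1) ingredients.
oracle_icc_2_1 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   case = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ case + rater, data = df))[[1]]
  msr <- tab["case", "Mean Sq"]; msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Point-level enumeration of F1 ingredients from explicit outcomes.
oracle_f1_from_outcomes <- function(pair_ref, pair_pred, un_ref, un_pred) {
  sapply(cell_classes(), function(cl) {
    tp <- sum(pair_ref == cl & pair_pred == cl)
    fn <- sum(pair_ref == cl & pair_pred != cl) + sum(un_ref == cl)
    fp <- sum(pair_pred == cl & pair_ref != cl) + sum(un_pred == cl)
    if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  })
}

# Distribution of a clipped-then-rounded Gaussian TPS estimate, from normal
# CDF mass per rounding bin (clipping folds tail mass onto 0 and 100).
oracle_rounded_tps_sd <- function(true, sd, inc = 5) {
  vals <- seq(0, 100, by = inc)
  probs <- vapply(vals, function(v) {
    lo <- if (v == 0) -Inf else v - inc / 2
    hi <- if (v == 100) Inf else v + inc / 2
    pnorm(hi, true, sd) - pnorm(lo, true, sd)
  }, numeric(1))
  mu <- sum(vals * probs)
  sqrt(sum(vals^2 * probs) - mu^2)
}
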