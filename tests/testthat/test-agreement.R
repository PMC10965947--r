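test_that("TPS is the positive share of tumor cells, others ignored", {
  r <- compute_tps(n_pos = 30, n_neg = 70)
  expect_equal(r$tps_pct, 30)
  ann <- annotation_set(
    x_um = seq_len(600), y_um = rep(1, 600),
    class = c(rep("pos_tumor", 30), rep("neg_tumor", 70), rep("other", 500)),
    source = "ai")
  expect_equal(compute_tps(ann)$tps_pct, 30)
  expect_equal(compute_tps(n_pos = 0, n_neg = 10)$tps_pct, 0)
  expect_error(compute_tps(n_pos = 0, n_neg = 0), "TPS undefined")
  # scale invariance
  expect_equal(compute_tps(n_pos = 12, n_neg = 36)$tps_pct,
               compute_tps(n_pos = 12 * 7, n_neg = 36 * 7)$tps_pct)
})

test_that("TPS discretization boundaries follow the clinical bands", {
  expect_equal(as.character(discretize_tps(c(0, 0.5, 0.999))),
               rep("<1%", 3))
  expect_equal(as.character(discretize_tps(c(1, 25, 49.999))),
               rep("1-49%", 3))
  expect_equal(as.character(discretize_tps(c(50, 75, 100))),
               rep(">=50%", 3))
  codes <- as.integer(discretize_tps(c(0.999, 1, 49.999, 50))) - 1L
  expect_equal(codes, c(0L, 1L, 1L, 2L))
})

test_that("linear weighted kappa matches first-principles arithmetic", {
  expect_equal(linear_kappa(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)

  tab <- matrix(c(5, 2, 0,
                  1, 7, 1,
                  0, 2, 6), 3, 3, byrow = TRUE)
  r <- ratings_from_table(tab)
  expect_equal(linear_kappa(r$a, r$b), oracle_weighted_kappa(tab),
               tolerance = 1e-12)

  # with 2 categories the linear weights reduce to unweighted kappa
  set.seed(14)
  for (i in 1:20) {
    t2 <- matrix(sample(0:8, 4, TRUE), 2, 2)
    if (sum(t2) < 2) next
    r2 <- ratings_from_table(t2)
    expect_equal(linear_kappa(r2$a, r2$b, n_levels = 2),
                 oracle_weighted_kappa(t2, "unweighted"), tolerance = 1e-12)
  }
})

test_that("kappa is near zero for independent ratings and flags degeneracy", {
  set.seed(6)
  n <- 10000
  a <- sample(0:2, n, TRUE); b <- sample(0:2, n, TRUE)
  expect_lt(abs(linear_kappa(a, b)), 0.03)

  expect_equal(linear_kappa(c(1, 1, 1), c(1, 1, 1)), 1)
  # one constant rater against a varying one is chance-level, not undefined
  expect_equal(linear_kappa(c(1, 1, 1, 1), c(1, 1, 1, 0)), 0)
})

test_that("cutoff kappa reproduces the printed 2x2 hand computation", {
  # table {{20,5},{5,20}}: po = 0.8, pe = 0.5, kappa = 0.6
  r <- ratings_from_table(matrix(c(20, 5, 5, 20), 2, 2, byrow = TRUE))
  tps_a <- ifelse(r$a == 1, 60, 10); tps_b <- ifelse(r$b == 1, 70, 20)
  expect_equal(kappa_at_cutoff(tps_a, tps_b, 50), 0.6)

  expect_equal(kappa_at_cutoff(c(60, 10, 80), c(55, 5, 51), 50), 1)
  expect_true(is.na(kappa_at_cutoff(c(60, 70), c(80, 90), 1)))
})

test_that("ICC(2,1) matches the ANOVA oracle and known limits", {
  x <- cbind(c(10, 20, 30, 40, 50, 25),
             c(11, 19, 33, 42, 48, 30),
             c(14, 18, 29, 38, 52, 24))
  got <- icc_2_1(x)
  expect_equal(got$value, oracle_icc_2_1(x), tolerance = 1e-10)
  expect_lt(got$ci_low, got$value)
  expect_gt(got$ci_high, got$value)

  ident <- cbind(1:6, 1:6, 1:6)
  expect_equal(icc_2_1(ident)$value, 1)

  flat <- matrix(5, 4, 3)
  expect_true(is.na(icc_2_1(flat)$value))
})

test_that("ICC recovers the variance-component ratio", {
  set.seed(10)
  n <- 1000; k <- 4
  s_case <- 20; s_noise <- 10
  case <- rnorm(n, 50, s_case)
  x <- sapply(seq_len(k), function(j) case + rnorm(n, 0, s_noise))
  got <- icc_2_1(x)$value
  expect_lt(abs(got - s_case^2 / (s_case^2 + s_noise^2)), 0.03)
})

test_that("ICC is invariant to shift and positive scaling", {
  set.seed(3)
  x <- matrix(rnorm(30, 50, 15), 10, 3)
  base <- icc_2_1(x)$value
  expect_equal(icc_2_1(x + 17)$value, base, tolerance = 1e-12)
  expect_equal(icc_2_1(x * 3.5)$value, base, tolerance = 1e-12)
  # incomplete cases are dropped, not propagated
  xm <- x; xm[4, 2] <- NA
  r <- icc_2_1(xm)
  expect_equal(r$n_dropped, 1)
  expect_equal(r$n, 9)
})

test_that("Bland-Altman mean difference and limits are exact on hand cases", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  shift <- bland_altman(c(10, 20, 30), c(5, 15, 25))
  expect_equal(shift$mean_diff, 5)
  expect_equal(shift$sd_diff, 0)

  h <- bland_altman(c(10, 20, 30), c(12, 18, 33))
  expect_equal(h$mean_diff, -1)
  expect_equal(h$sd_diff, sd(c(-2, 2, -3)))
  expect_equal(h$loa_low, -1 - 1.96 * sd(c(-2, 2, -3)))
})

test_that("majority vote excludes the target reader and handles ties", {
  tps <- tidyr::expand_grid(case_id = c("c1", "c2"),
                            source = paste0("r", 1:5)) |>
    dplyr::mutate(tps_pct = c(60, 60, 60, 10, 10,
                              10, 10, 10, 10, 60))
  # an AI target is not a voter: c1 (pos,pos,pos,neg,neg) -> majority pos,
  # c2 (neg,neg,neg,neg,pos) -> majority neg
  ai <- tibble::tibble(case_id = c("c1", "c2"), source = "ai",
                       tps_pct = c(70, 5))
  mv <- majority_vote_agreement(dplyr::bind_rows(tps, ai), target = "ai",
                                voters = paste0("r", 1:5), cutoff = 50)
  expect_equal(mv$n_ties, 0)
  expect_equal(mv$n_cases, 2)
  expect_equal(as.numeric(mv$kappa), 1)

  # the target's own rating never influences its reference: with r1
  # excluded, c1 becomes a 2-2 tie, so exclusion is observable
  mv1 <- majority_vote_agreement(tps, target = "r1",
                                 voters = paste0("r", 1:5), cutoff = 50)
  expect_equal(mv1$n_ties, 1)

  # even voter counts can tie; ties are excluded and counted by default
  tie_tps <- tibble::tibble(case_id = rep(c("c1", "c2"), each = 5),
                            source = rep(paste0("r", 1:5), 2),
                            tps_pct = c(60, 60, 10, 10, 0,
                                        60, 60, 60, 10, 80))
  mv_tie <- majority_vote_agreement(tie_tps, target = "r5",
                                    voters = paste0("r", 1:4), cutoff = 50)
  expect_equal(mv_tie$n_ties, 1)
  expect_equal(mv_tie$n_cases, 1)
  mv_hi <- majority_vote_agreement(tie_tps, target = "r5",
                                   voters = paste0("r", 1:4), cutoff = 50,
                                   tie = "higher")
  expect_equal(mv_hi$n_cases, 2)

  expect_error(majority_vote_agreement(tps, target = "r1",
                                       voters = c("r1", "r2"), cutoff = 50),
               ">= 3 readers")
})

test_that("a truth-tracking rater tops the majority-vote ranking", {
  set.seed(9)
  true_tps <- sample_true <- c(runif(40, 0, 1), runif(80, 1, 50),
                               runif(40, 50, 100))
  panel <- simulate_tps_panel(true_tps, n_readers = 5, reader_sd_pct = 15,
                              seed = 2)
  oracle_reader <- tibble::tibble(case_id = unique(panel$case_id),
                                  source = "oracle", tps_pct = true_tps)
  tps <- dplyr::bind_rows(panel[, c("case_id", "source", "tps_pct")],
                          oracle_reader)
  readers <- c(sprintf("reader_%d", 1:5), "oracle")
  kappas <- vapply(readers, function(s) {
    as.numeric(majority_vote_agreement(tps, s, voters = readers,
                                       cutoff = 50)$kappa)
  }, numeric(1))
  expect_equal(names(which.max(kappas)), "oracle")
})

test_that("the agreement report bundles pairwise, group and majority views", {
  set.seed(15)
  true_tps <- c(runif(10, 0, 1), runif(25, 1, 50), runif(15, 50, 100))
  panel <- simulate_tps_panel(true_tps, n_readers = 4, reader_sd_pct = 8,
                              seed = 3)
  ai <- tibble::tibble(case_id = unique(panel$case_id), source = "ai",
                       tps_pct = pmin(pmax(true_tps - 3, 0), 100))
  tps <- dplyr::bind_rows(panel[, c("case_id", "source", "tps_pct")], ai)
  readers <- sprintf("reader_%d", 1:4)
  rep <- tps_agreement_report(tps, readers = readers, ai = "ai")
  expect_equal(nrow(rep$pairs), choose(5, 2))
  expect_setequal(unique(rep$pairs$pair_type), c("reader-reader", "reader-ai"))
  expect_true(all(rep$pairs$icc >= -1 & rep$pairs$icc <= 1))
  expect_true(all(rep$pairs$kappa_overall >= -1 & rep$pairs$kappa_overall <= 1))
  expect_equal(nrow(rep$majority), 5 * 2)
  expect_true(!is.null(rep$bland_altman))
  expect_true(rep$bland_altman$loa_low <= rep$bland_altman$mean_diff)
  g <- glance(rep)
  expect_true(is.finite(g$icc_reader_reader))
  expect_true(is.finite(g$bland_altman_mean_diff))
})
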