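test_that("difference vectors are elementwise S - M with validation", {
  expect_equal(diff_vector(c(0, 1, 2, 3), c(0, 1, 2, 3)), rep(0L, 4))
  expect_equal(diff_vector(c(3, 0), c(1, 2)), c(2L, -2L))
  expect_error(diff_vector(0:2, 0:3), "equal length")
  expect_error(diff_vector(c(0, 4), c(0, 0)), "0..3")
})

test_that("diff_summary computes moments and CI of the level differences", {
  s <- diff_summary(c(1L, -1L))
  expect_equal(s$mean, 0)
  expect_equal(s$sd, 1)                  # population SD
  z <- diff_summary(rep(0L, 10))
  expect_equal(z$mean, 0)
  expect_equal(z$sd, 0)
  expect_true(is.na(z$disagreement_mean))
  expect_error(diff_summary(integer(0)), "empty")
  # mean/sd against a naive loop oracle on random tables
  set.seed(31)
  for (i in 1:25) {
    d <- table_diffs(random_agreement_table())
    s <- diff_summary(d)
    m <- sum(d) / length(d)
    expect_equal(s$mean, m)
    expect_equal(s$sd, sqrt(sum((d - m)^2) / length(d)))
    expect_equal(sum(s$proportions), 1)
  }
})

test_that("contingency tables count and conserve all cases", {
  tab <- contingency_table(0:3, 0:3)
  expect_equal(unname(diag(unclass(tab))), rep(1L, 4))
  expect_equal(attr(tab, "n"), 4L)
  set.seed(32)
  S <- sample(0:3, 500, replace = TRUE)
  M <- sample(0:3, 500, replace = TRUE)
  tab <- contingency_table(S, M)
  expect_equal(sum(unclass(tab)), 500L)
  # resampling from the table's cells reproduces the table
  idx <- which(unclass(tab) >= 0, arr.ind = TRUE)
  S2 <- rep(idx[, 1] - 1L, unclass(tab)[idx])
  M2 <- rep(idx[, 2] - 1L, unclass(tab)[idx])
  expect_equal(unclass(contingency_table(S2, M2)), unclass(tab))
})

test_that("cohen_kappa matches closed-form cases and an external oracle", {
  perfect <- as_agreement_table(diag(25L, 4))
  expect_equal(cohen_kappa(perfect)$kappa, 1)
  uniform <- as_agreement_table(matrix(5L, 4, 4))
  expect_equal(cohen_kappa(uniform)$kappa, 0)
  # frozen from statsmodels.stats.inter_rater.cohens_kappa on this table
  toy <- as_agreement_table(matrix(c(10, 3, 0, 1, 2, 20, 5, 0,
                                     1, 4, 15, 3, 0, 1, 2, 8), 4, 4))
  k <- cohen_kappa(toy)
  expect_equal(k$kappa, 0.5924919733267474, tolerance = 1e-12)
  expect_equal(k$se, 0.0736835873493501, tolerance = 1e-9)
  expect_error(cohen_kappa(as_agreement_table(matrix(c(5L, 0L, 0L, 0L), 2))),
               "undefined")
})

test_that("kappa agrees with the brute-force pair-counting oracle", {
  set.seed(33)
  for (i in 1:50) {
    tab <- random_agreement_table()
    if (attr(tab, "n") == 0) next
    expect_equal(cohen_kappa(tab)$kappa, loop_kappa(tab))
  }
})

test_that("kappa is invariant under simultaneous category permutation", {
  set.seed(34)
  tab <- random_agreement_table()
  perm <- sample(4)
  tab2 <- as_agreement_table(unclass(tab)[perm, perm])
  expect_equal(cohen_kappa(tab2)$kappa, cohen_kappa(tab)$kappa)
})

test_that("collapsing to ARDS versus the rest conserves totals", {
  tab <- reference_table()
  coll <- collapse_ards(tab)
  expect_equal(attr(coll, "n"), attr(tab, "n"))
  expect_equal(sum(diag(unclass(coll))), 3312L + 9965L)
  expect_error(collapse_ards(as_agreement_table(matrix(1L, 2, 2))), "4x4")
})

test_that("band discrepancy counts matches and one-level migrations", {
  # constructed toy: 5 moderate cases in the pf 100-174 band, 3 migrate
  grid <- data.frame(pf = c(rep(137, 5), rep(262, 5)),
                     compliance = 50, peep = 10,
                     film = c(2, 2, 2, 2, 2, 1, 1, 1, 1, 1))
  M <- rep(2L, 10)
  S <- c(3L, 3L, 3L, 2L, 2L, rep(2L, 5))
  bd <- band_discrepancy(grid, S, M)
  row <- bd[bd$severity == 2 & bd$variable == "pf" & bd$band_score == 3, ]
  expect_equal(row$n, 5L)
  expect_equal(row$migrate, 3L)
  expect_equal(row$discrepancy, 0.6)
  expect_true(all(bd$match + bd$migrate + bd$other == bd$n))
  # total coincidence: flat zero discrepancy wherever defined
  bd0 <- band_discrepancy(grid, M, M)
  expect_true(all(bd0$discrepancy[!is.na(bd0$discrepancy)] == 0))
  # empty strata are NA, not errors
  expect_true(any(is.na(bd0$discrepancy)))
})

test_that("the pooled two-proportion z-test matches hand computations", {
  eq <- two_prop_test(30, 100, 15, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  t1 <- two_prop_test(60, 100, 40, 100)
  expect_equal(t1$z, 0.2 / sqrt(0.5 * 0.5 * 0.02), tolerance = 1e-12)
  expect_equal(t1$p, 2 * pnorm(-abs(t1$z)))
  expect_equal(t1$z, 2.8284, tolerance = 1e-4)
  # z^2 equals the continuity-uncorrected chi-square statistic
  pt <- prop.test(c(60, 40), c(100, 100), correct = FALSE)
  expect_equal(t1$z^2, unname(pt$statistic))
  expect_lt(two_prop_test(900, 1000, 100, 1000)$p, 1e-4)
  deg <- two_prop_test(0, 10, 0, 10)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  expect_error(two_prop_test(5, 4, 1, 10), "k <= n")
})
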