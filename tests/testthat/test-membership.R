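test_that("vote densities count panel fractions at segment midpoints", {
  spec <- variable_specs()$pf
  # 7 of 12 physicians call the segment containing PaO2/FiO2 = 150 severe
  # (segment 4 spans [150, 200); cut1 >= 4 assigns it to the first category)
  p <- data.frame(physician_id = 1:12, variable = "pf",
                  cut1 = c(rep(4L, 7), rep(3L, 5)), cut2 = 6L)
  d <- vote_densities(p, spec)
  expect_equal(unname(d$density["severe", 4]), 7 / 12)
  expect_equal(unname(round(d$density["severe", 4], 2)), 0.58)
  # per-point densities always sum to one
  expect_equal(colSums(d$density), rep(1, spec$n_segments))
})

test_that("unanimous panels give 0/1 densities", {
  spec <- variable_specs()$peep
  p <- data.frame(physician_id = 1:12, variable = "peep", cut1 = 3L,
                  cut2 = 7L)
  d <- vote_densities(p, spec)
  expect_true(all(d$density %in% c(0, 1)))
  expect_equal(unname(d$density["low", ]), c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
})

test_that("vote_densities validates cuts and segmentation", {
  spec <- variable_specs()$pf
  expect_error(vote_densities(data.frame(physician_id = 1, variable = "pf",
                                         cut1 = 5L, cut2 = 5L), spec),
               "cut1 < cut2")
  expect_error(vote_densities(data.frame(physician_id = 1, variable = "pf",
                                         cut1 = 1L, cut2 = 9L), spec),
               "cut")
  expect_error(vote_densities(data.frame(physician_id = 1,
                                         variable = "compliance",
                                         cut1 = 1L, cut2 = 2L), spec),
               "no partition responses")
})

test_that("membership evaluation stays in [0,1] and respects the domain", {
  mfs <- list(
    mf("gbellmf", c(a = 1, b = 2, c = 5), c(0, 10)),
    mf("zmf", c(a = 2, b = 6), c(0, 10)),
    mf("sigmf", c(a = -3, c = 4), c(0, 10)),
    mf("dsigmf", c(a1 = 5, c1 = 2, a2 = 5, c2 = 8), c(0, 10)),
    mf("gauss2mf", c(sig1 = 1, c1 = 3, sig2 = 2, c2 = 6), c(0, 10)),
    mf("trapmf", c(a = 1, b = 3, c = 6, d = 9), c(0, 10))
  )
  xs <- seq(0, 10, length.out = 1000)
  for (m in mfs) {
    y <- eval_mf(m, xs)
    expect_true(all(y >= 0 & y <= 1), info = m$family)
  }
  bell <- mfs[[1]]
  expect_equal(eval_mf(bell, 5), 1)                 # bell maximum at center
  z <- mfs[[2]]
  expect_gte(eval_mf(z, 0), eval_mf(z, 10))         # Z decreases
  expect_equal(eval_mf(bell, 10 + 1e-12), eval_mf(bell, 10))  # marginal clamp
  expect_error(eval_mf(bell, 11), "domain")
})

test_that("fitting picks a near-exact curve for step-like densities", {
  # exactly 1 below x0, one intermediate 0.5 point, 0 above
  x <- seq(0.5, 9.5, by = 1)
  y <- c(1, 1, 1, 1, 0.5, 0, 0, 0, 0, 0)
  fit <- fit_mf_points(x, y, c(0, 10))
  expect_lte(attr(fit, "sse"), 1e-3)
  # plateau density: fitted curve stays high everywhere
  fit1 <- fit_mf_points(x, rep(1, 10), c(0, 10))
  expect_true(all(eval_mf(fit1, x) >= 0.99))
  # monotone nonincreasing density -> monotone nonincreasing Z/sigmoid fit
  ym <- c(1, 1, 0.9, 0.8, 0.6, 0.3, 0.2, 0.1, 0, 0)
  fitm <- fit_mf_points(x, ym, c(0, 10), families = c("zmf", "sigmf"))
  vals <- eval_mf(fitm, x)
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("every family refits its own sampled curve to SSE <= 1e-6", {
  dom <- c(0, 10)
  x <- seq(0.5, 9.5, by = 1)
  true <- list(
    zmf = c(a = 3, b = 6), smf = c(a = 4, b = 7), sigmf = c(a = 1.5, c = 5),
    dsigmf = c(a1 = 2, c1 = 3, a2 = 2, c2 = 7),
    psigmf = c(a1 = 2, c1 = 3, a2 = -2, c2 = 7),
    gbellmf = c(a = 2, b = 3, c = 5), gaussmf = c(sig = 1.5, c = 5),
    gauss2mf = c(sig1 = 1, c1 = 4, sig2 = 1.5, c2 = 6),
    trapmf = c(a = 2, b = 4, c = 6, d = 8))
  for (f in names(true)) {
    y <- eval_mf(mf(f, true[[f]], dom), x)
    fit <- fit_mf_points(x, y, dom, families = f)
    expect_lte(attr(fit, "sse"), 1e-6)
  }
})

test_that("fit_mf reports the families tried when everything fails", {
  expect_error(fit_mf_points(c(1, 2, 3), c(1, 0, 0), c(0, 4)),
               "at least 4 points")
})

test_that("chest film bells behave like overlapping quantized categories", {
  film <- chest_film_mfs()
  expect_length(film, 5)
  for (k in 0:4) expect_equal(eval_mf(film[[k + 1]], k), 1)
  # 1.5 quadrants belongs to both neighbours
  expect_gt(eval_mf(film[["1"]], 1.5), 0)
  expect_gt(eval_mf(film[["2"]], 1.5), 0)
  # symmetry about each center
  expect_equal(eval_mf(film[["1"]], 0.5), eval_mf(film[["1"]], 1.5))
  expect_error(chest_film_mfs(width = 0), "positive")
  expect_error(chest_film_mfs(slope = -1), "positive")
})

test_that("membership JSON serialization round-trips losslessly", {
  m <- mf("gauss2mf", c(sig1 = 1.25, c1 = 3, sig2 = 0.5, c2 = 6.5), c(0, 10))
  m2 <- mf_from_json(mf_to_json(m))
  expect_identical(m2$family, m$family)
  expect_equal(m2$params, m$params)
  expect_equal(m2$domain, m$domain)
  xs <- seq(0, 10, length.out = 101)
  expect_equal(eval_mf(m2, xs), eval_mf(m, xs))
})
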