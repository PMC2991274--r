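test_that("probor is the probabilistic OR with its algebraic identities", {
  expect_equal(probor(0.5, 0.5), 0.75)
  expect_equal(probor(0.3, 0), 0.3)      # identity element
  expect_equal(probor(1, 0.42), 1)       # absorbing element
  expect_equal(probor(0.2, 0.7), probor(0.7, 0.2))
  expect_error(probor(1.2, 0.5), "\\[0, 1\\]")
  expect_error(probor(0.5, -0.1), "\\[0, 1\\]")
})

test_that("firing strength is the product of the four antecedent degrees", {
  expect_equal(firing_strength(c(1, 1, 1, 1)), 1)
  expect_equal(firing_strength(c(0.5, 0.8, 1, 1)), 0.4)
  expect_equal(firing_strength(c(0.9, 0, 0.8, 1)), 0)
  expect_error(firing_strength(c(0.5, 0.8, 1)), "four")
  expect_error(firing_strength(c(0.5, 0.8, 1, 1.4)), "\\[0, 1\\]")
})

test_that("fuzzify returns one degree per category, all in [0,1]", {
  fis <- toy_fis(toy_full_rules())
  q <- data.frame(pf = 137, compliance = 55, peep = 8, film = 2)
  deg <- fuzzify(fis, q)
  expect_equal(sum(lengths(lapply(deg, as.numeric))), 3 + 3 + 3 + 5)
  expect_true(all(unlist(deg) >= 0 & unlist(deg) <= 1))
  expect_equal(unname(deg$film[1, "2"]), 1)      # film bell maximum at its center
  # domain ends fuzzify without error
  ends <- data.frame(pf = c(0, 450), compliance = c(0, 100),
                     peep = c(0, 20), film = c(0, 4))
  expect_true(all(unlist(fuzzify(fis, ends)) >= 0))
  expect_error(fuzzify(fis, data.frame(pf = 460, compliance = 50, peep = 5,
                                       film = 0)), "domain")
})

test_that("a single fired rule passes its consequent through", {
  rules <- data.frame(pf_cat = 2L, compliance_cat = 2L, peep_cat = 0L,
                      film = 0L, consequent = 2L, weight = 1)
  fis <- toy_fis(rules)
  r <- infer(fis, c(pf = 400, compliance = 90, peep = 2, film = 0))
  expect_equal(r$score, 2)
  expect_equal(r$level, 2L)
  expect_gt(r$firing_mass, 0)
})

test_that("defuzzification is the weighted mean, ties rounding up", {
  # two rules with equal firing and weight, consequents 1 and 2
  rules <- data.frame(pf_cat = 2L, compliance_cat = 2L, peep_cat = 0L,
                      film = 0L, consequent = c(1L, 2L), weight = 0.5)
  fis <- toy_fis(rules)
  r <- infer(fis, c(pf = 400, compliance = 90, peep = 2, film = 0))
  expect_equal(r$score, 1.5)
  expect_equal(r$level, 2L)              # .5 rounds toward more severe
})

test_that("no rule coverage raises an error carrying the quadruplet", {
  rules <- data.frame(pf_cat = 0L, compliance_cat = 0L, peep_cat = 0L,
                      film = 0L, consequent = 3L, weight = 1)
  fis <- toy_fis(rules)
  # crisp trapezoids give exactly zero firing away from the rule's cell;
  # film bell at 0 evaluated at 4 is tiny but positive, so zero the film
  fis$memberships$film[["0"]] <- mf("trapmf",
                                    c(a = -1, b = -1, c = 0.4, d = 0.5),
                                    c(0, 4))
  expect_error(infer(fis, c(pf = 400, compliance = 90, peep = 2, film = 4)),
               "no rule coverage.*pf=400")
})

test_that("scores are convex in the fired consequents and levels round them", {
  set.seed(21)
  fis <- toy_fis(toy_full_rules())
  q <- random_quadruplets(300)
  out <- predict(fis, q)
  expect_true(all(out$score >= 0 & out$score <= 3))
  expect_identical(out$level, as.integer(pmin(3, floor(out$score + 0.5))))
  # single-quadruplet inference agrees with the vectorized path
  r1 <- infer(fis, q[7, ])
  expect_equal(r1$score, out$score[7])
})

test_that("rescaling all rule weights leaves the score unchanged", {
  set.seed(22)
  fis <- toy_fis(toy_full_rules())
  q <- random_quadruplets(100)
  s0 <- predict(fis, q, type = "score")
  for (const in c(0.2, 3, 17)) {
    fis2 <- fis
    fis2$rulebase$weight <- fis$rulebase$weight * const
    expect_equal(predict(fis2, q, type = "score"), s0)
  }
})

test_that("scores are nondecreasing in film when consequents are", {
  # consequent = film level for every antecedent cell
  lines <- all_rule_lines()
  rules <- cbind(lines, consequent = lines$film, weight = 1)
  fis <- toy_fis(rules)
  set.seed(23)
  base <- random_quadruplets(50)
  scores <- sapply(0:4, function(k) {
    base$film <- k
    predict(fis, base, type = "score")
  })
  expect_true(all(diff(t(scores)) >= -1e-9))
})

test_that("a fitted FIS serializes to JSON and back without changing output", {
  sv <- simulate_survey(behavior = behavior_model("overweight"), seed = 5)
  fis <- fis_fit(sv)
  path <- withr::local_tempfile(fileext = ".json")
  fis_to_json(fis, path)
  fis2 <- fis_from_json(path)
  set.seed(24)
  q <- random_quadruplets(100)
  expect_equal(predict(fis2, q), predict(fis, q))
})
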