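test_that("partition responses are structurally valid for every physician", {
  b <- behavior_model("overweight", seed = 3)
  p <- gen_partition_responses(behavior = b, n_physicians = 12)
  expect_equal(nrow(p), 36)              # 12 physicians x 3 variables
  specs <- variable_specs()
  for (v in names(specs)) {
    pv <- p[p$variable == v, ]
    n <- specs[[v]]$n_segments
    expect_true(all(pv$cut1 >= 1 & pv$cut1 < pv$cut2 & pv$cut2 <= n - 1))
  }
})

test_that("zero jitter collapses the panel to identical crisp partitions", {
  b <- behavior_model("faithful", seed = 1)
  p <- gen_partition_responses(behavior = b, n_physicians = 12)
  for (v in unique(p$variable)) {
    pv <- p[p$variable == v, ]
    expect_equal(length(unique(pv$cut1)), 1L)
    expect_equal(length(unique(pv$cut2)), 1L)
    d <- vote_densities(pv, variable_specs()[[v]])
    expect_true(all(d$density %in% c(0, 1)))
  }
  # nominal frontiers snap to the Murray 0|1 and 3|4 band boundaries
  expect_equal(unique(p[p$variable == "pf", "cut1"]), 2L)      # 100 / 50
  expect_equal(unique(p[p$variable == "pf", "cut2"]), 6L)      # 300 / 50
})

test_that("surveys are reproducible by seed and vary across seeds", {
  b <- behavior_model("overweight")
  s1 <- simulate_survey(behavior = b, seed = 9)
  s2 <- simulate_survey(behavior = b, seed = 9)
  expect_identical(s1$partitions, s2$partitions)
  expect_identical(s1$rules, s2$rules)
  draws <- lapply(1:20, function(s)
    gen_partition_responses(behavior = b, seed = s)$cut1)
  expect_gt(length(unique(draws)), 1L)
})

test_that("faithful zero-noise panels tick the crisp Murray level of each line", {
  b <- behavior_model("faithful", seed = 2)
  resp <- gen_rule_responses(behavior = b, n_physicians = 12)
  ticks <- as.matrix(resp[paste0("n", 0:3)])
  expect_true(all(rowSums(ticks) == 12))
  # independent oracle: representative quadruplet per category run
  reps <- list(pf = c((0 + 100) / 2, (100 + 300) / 2, (300 + 450) / 2),
               compliance = c(10, 50, 90),
               peep = c(3, 10.5, 17.5))
  expected <- murray_level(murray_score(data.frame(
    pf = reps$pf[resp$pf_cat + 1],
    compliance = reps$compliance[resp$compliance_cat + 1],
    peep = reps$peep[resp$peep_cat + 1],
    film = resp$film)))
  ticked <- max.col(ticks) - 1L
  expect_true(all(ticks[cbind(seq_len(nrow(ticks)), ticked + 1L)] == 12))
  expect_equal(ticked, expected)
})

test_that("zero noise gives unanimity whatever the weights", {
  b <- behavior_model("overweight", diagnosis_noise_sd = 0, seed = 4)
  resp <- gen_rule_responses(behavior = b, n_physicians = 12)
  ticks <- as.matrix(resp[paste0("n", 0:3)])
  expect_true(all(apply(ticks, 1, max) == 12))
})

test_that("overweighting gas exchange raises severity on the worst-pf lines", {
  mean_level <- function(b) {
    resp <- gen_rule_responses(behavior = b, n_physicians = 12)
    ticks <- as.matrix(resp[paste0("n", 0:3)])
    lev <- as.numeric(ticks %*% 0:3) / 12
    mean(lev[resp$pf_cat == 0])          # lines whose pf category is worst
  }
  eq <- behavior_model("faithful")
  ow <- behavior_model("faithful",
                       diagnosis_weights = c(pf = 2, compliance = 1,
                                             peep = 1, film = 2))
  expect_gte(mean_level(ow), mean_level(eq))
})

test_that("behavior and survey inputs are validated", {
  expect_error(behavior_model(frontier_means = list(pf = c(500, 600),
                                                    compliance = c(20, 80),
                                                    peep = c(6, 15))),
               "inside")
  expect_error(behavior_model(diagnosis_noise_sd = -1), ">= 0")
  expect_error(behavior_model(diagnosis_weights = c(pf = 0, compliance = 0,
                                                    peep = 0, film = 0)),
               "positive sum")
  expect_error(gen_rule_responses(all_rule_lines()[0, ],
                                  behavior_model()), "empty")
  expect_error(simulate_survey(n_physicians = 0), ">= 1")
})
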