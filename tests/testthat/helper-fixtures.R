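# Hand-built single-variable-per-category FIS for engine tests: crisp
# trapezoid memberships on the three continuous variables (tiling each
# domain at the default nominal frontiers) and the default film bells.
toy_memberships <- function() {
  tile <- function(dom, f1, f2) {
    eps <- diff(dom) * 1e-3
    list(
      lo = mf("trapmf", c(a = dom[1] - 1, b = dom[1] - 1, c = f1 - eps,
                          d = f1 + eps), dom),
      mid = mf("trapmf", c(a = f1 - eps, b = f1 + eps, c = f2 - eps,
                           d = f2 + eps), dom),
      hi = mf("trapmf", c(a = f2 - eps, b = f2 + eps, c = dom[2] + 1,
                          d = dom[2] + 1), dom)
    )
  }
  list(pf = tile(c(0, 450), 100, 300),
       compliance = tile(c(0, 100), 20, 80),
       peep = tile(c(0, 20), 6, 15),
       film = chest_film_mfs())
}

toy_fis <- function(rules, panel_size = 12L) {
  rb <- structure(rules,
                  panel_size = panel_size,
                  line_count = nrow(unique(rules[c("pf_cat", "compliance_cat",
                                                   "peep_cat", "film")])),
                  class = c("rule_base", "data.frame"))
  structure(list(memberships = toy_memberships(), rulebase = rb,
                 specs = variable_specs(), panel_size = panel_size,
                 fit = NULL),
            class = "sugeno_fis")
}

# a rule for every antecedent combination, consequent = Murray level of the
# representative quadruplet; gives full coverage of the input space
toy_full_rules <- function() {
  lines <- all_rule_lines()
  reps <- list(pf = c(50, 200, 375), compliance = c(10, 50, 90),
               peep = c(3, 10.5, 17.5))
  cons <- murray_level(murray_score(data.frame(
    pf = reps$pf[lines$pf_cat + 1], compliance = reps$compliance[lines$compliance_cat + 1],
    peep = reps$peep[lines$peep_cat + 1], film = lines$film)))
  cbind(lines, consequent = cons, weight = 1)
}

# expand an agreement table into the S - M difference vector
table_diffs <- function(tab) {
  m <- unclass(tab)
  idx <- which(m > 0, arr.ind = TRUE)
  rep(idx[, 1] - idx[, 2], m[idx])
}

random_agreement_table <- function(max_cell = 20L) {
  as_agreement_table(matrix(sample(0:max_cell, 16, replace = TRUE), 4, 4,
                            dimnames = list(survey = 0:3, murray = 0:3)))
}

# brute-force kappa oracle: expand the table into rating pairs and count
loop_kappa <- function(tab) {
  m <- unclass(tab)
  idx <- which(m >= 0, arr.ind = TRUE)
  S <- rep(idx[, 1] - 1L, m[idx])
  M <- rep(idx[, 2] - 1L, m[idx])
  n <- length(S)
  po <- sum(S == M) / n
  pe <- 0
  for (k in 0:3) pe <- pe + (sum(S == k) / n) * (sum(M == k) / n)
  (po - pe) / (1 - pe)
}

random_quadruplets <- function(n) {
  data.frame(pf = runif(n, 0, 450), compliance = runif(n, 0, 100),
             peep = runif(n, 0, 20), film = sample(0:4, n, replace = TRUE))
}
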