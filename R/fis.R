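#' Fit the survey-derived Sugeno fuzzy inference system
#'
#' The model-fitting entry point of the package. From a (real or simulated)
#' two-questionnaire physician survey it
#' \enumerate{
#'   \item computes vote densities per variable and category from the
#'     questionnaire-1 partitions and fits a membership function to each of
#'     the nine (variable, category) densities by least squares over the
#'     offered families;
#'   \item attaches the five generalized-bell chest-film memberships;
#'   \item converts the questionnaire-2 tick counts into the weighted rule
#'     base (one rule per chosen (line, level) cell, weight = ticks / panel).
#' }
#' The result is a first-order-zero (constant-consequent) Sugeno system:
#' rule firing strengths are products of the four antecedent membership
#' degrees, and the defuzzified severity is the firing-and-weight weighted
#' mean of the crisp consequents.
#'
#' @param survey A `lis_survey` (from [simulate_survey()]), or `NULL` if
#'   `partitions`, `rules` and `panel_size` are given directly.
#' @param partitions,rules,panel_size Questionnaire data, see
#'   [gen_partition_responses()] and [gen_rule_responses()]; ignored when
#'   `survey` is supplied.
#' @param specs Named list of `variable_spec`s.
#' @param families Membership families offered to the fitter.
#' @param film_width,film_slope Chest-film bell parameters, see
#'   [chest_film_mfs()].
#' @return An object of class `sugeno_fis` with elements `memberships`
#'   (per variable, a named list of `mf`s), `rulebase`, `specs`,
#'   `panel_size` and `fit` (chosen family and SSE per fitted membership).
#' @examples
#' sv <- simulate_survey(behavior = behavior_model("faithful"), seed = 1)
#' fis <- fis_fit(sv)
#' predict(fis, data.frame(pf = 250, compliance = 55, peep = 8, film = 1))
#' @export
fis_fit <- function(survey = NULL, partitions = NULL, rules = NULL,
                    panel_size = NULL, specs = variable_specs(),
                    families = mf_families(),
                    film_width = 0.5, film_slope = 3) {
  if (!is.null(survey)) {
    stopifnot(inherits(survey, "lis_survey"))
    partitions <- survey$partitions
    rules <- survey$rules
    panel_size <- survey$panel_size
    specs <- survey$specs
  }
  if (is.null(partitions) || is.null(rules) || is.null(panel_size))
    stop("supply either `survey` or all of `partitions`, `rules`, `panel_size`")

  memberships <- list()
  fit_rows <- list()
  for (v in c("pf", "compliance", "peep")) {
    dens <- vote_densities(partitions, specs[[v]])
    ms <- list()
    for (k in 1:3) {
      m <- fit_mf(dens, k, families)
      ms[[specs[[v]]$categories[k]]] <- m
      fit_rows[[length(fit_rows) + 1L]] <-
        data.frame(variable = v, category = specs[[v]]$categories[k],
                   family = m$family, sse = attr(m, "sse"))
    }
    memberships[[v]] <- ms
  }
  memberships$film <- chest_film_mfs(film_width, film_slope)

  rb <- build_rules(rules, panel_size)
  structure(list(memberships = memberships, rulebase = rb, specs = specs,
                 panel_size = as.integer(panel_size),
                 fit = do.call(rbind, fit_rows)),
            class = "sugeno_fis")
}

#' Fuzzify a patient quadruplet
#'
#' Evaluates every category membership function at the quadruplet's values:
#' three degrees each for PaO2/FiO2, compliance and PEEP plus five for the
#' chest film, 14 in all, each in \[0, 1\].
#'
#' @param fis A `sugeno_fis`.
#' @param q A single quadruplet (named vector or one-row data frame) or a
#'   quadruplet data frame.
#' @return A list of per-variable degree matrices (rows = quadruplets,
#'   columns = categories).
#' @export
fuzzify <- function(fis, q) {
  stopifnot(inherits(fis, "sugeno_fis"))
  q <- as_quadruplets(q)
  out <- list()
  for (v in c("pf", "compliance", "peep", "film")) {
    ms <- fis$memberships[[v]]
    deg <- vapply(ms, function(m) eval_mf(m, q[[v]]), numeric(nrow(q)))
    if (nrow(q) == 1L) deg <- matrix(deg, nrow = 1L,
                                     dimnames = list(NULL, names(ms)))
    out[[v]] <- deg
  }
  out
}

#' Rule firing strength under the product T-norm
#'
#' The conjunction of the four antecedent clauses is the product of their
#' membership degrees.
#'
#' @param degrees Numeric vector of the four antecedent degrees in \[0, 1\].
#' @return Their product, in \[0, 1\].
#' @export
firing_strength <- function(degrees) {
  degrees <- unlist(degrees)
  if (length(degrees) != 4L || any(!is.finite(degrees)))
    stop("all four antecedent degrees must be present and finite")
  if (any(degrees < 0 | degrees > 1)) stop("degrees must lie in [0, 1]")
  prod(degrees)
}

#' Probabilistic OR
#'
#' The s-norm `a + b - a * b`, the package's declared OR operator
#' (commutative, with identity 0 and absorbing element 1).
#'
#' @param a,b Degrees in \[0, 1\] (vectorized).
#' @return `a + b - a * b`.
#' @examples
#' probor(0.5, 0.5)   # 0.75
#' @export
probor <- function(a, b) {
  if (any(!is.finite(a) | a < 0 | a > 1) || any(!is.finite(b) | b < 0 | b > 1))
    stop("probor arguments must lie in [0, 1]")
  a + b - a * b
}

# n x R firing matrix for all rules of the FIS at the fuzzified degrees
.firing_matrix <- function(fis, deg) {
  rb <- fis$rulebase
  deg$pf[, rb$pf_cat + 1L, drop = FALSE] *
    deg$compliance[, rb$compliance_cat + 1L, drop = FALSE] *
    deg$peep[, rb$peep_cat + 1L, drop = FALSE] *
    deg$film[, rb$film + 1L, drop = FALSE]
}

#' Severity inference for one quadruplet
#'
#' Fuzzifies the quadruplet, fires every rule with the product T-norm, and
#' defuzzifies to the continuous degree of severity
#' `sum(firing * weight * consequent) / sum(firing * weight)`, a convex
#' combination of the fired crisp consequents. The severity level is the
#' nearest integer in 0–3, ties at .5 rounding up.
#'
#' @param fis A `sugeno_fis`.
#' @param q One patient quadruplet.
#' @return A list of class `severity_result`: `score` (in \[0, 3\]),
#'   `level` (integer 0–3) and `firing_mass` (`sum(firing * weight)`,
#'   diagnostic).
#' @export
infer <- function(fis, q) {
  q <- as_quadruplets(q)
  if (nrow(q) != 1L) stop("`infer()` takes a single quadruplet; use predict()")
  deg <- fuzzify(fis, q)
  f <- .firing_matrix(fis, deg)[1L, ]
  w <- fis$rulebase$weight
  mass <- sum(f * w)
  if (mass <= 0)
    stop(sprintf("no rule coverage for quadruplet (pf=%g, compliance=%g, peep=%g, film=%g)",
                 q$pf, q$compliance, q$peep, q$film))
  score <- sum(f * w * fis$rulebase$consequent) / mass
  structure(list(score = score, level = .round_level(score),
                 firing_mass = mass),
            class = "severity_result")
}

# nearest level in 0..3, .5 ties upward
.round_level <- function(score) as.integer(pmin(3L, floor(score + 0.5)))

#' @export
print.severity_result <- function(x, ...) {
  cat(sprintf("severity %.4f -> level %d (firing mass %.4g)\n",
              x$score, x$level, x$firing_mass))
  invisible(x)
}

#' Predict severity for patient quadruplets
#'
#' Vectorized inference over a quadruplet data frame.
#'
#' @param object A `sugeno_fis`.
#' @param newdata Data frame with columns `pf`, `compliance`, `peep`,
#'   `film`.
#' @param type `"both"` (default) returns a data frame with `score` and
#'   `level`; `"score"` or `"level"` return the bare vector.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.sugeno_fis <- function(object, newdata,
                               type = c("both", "score", "level"), ...) {
  type <- match.arg(type)
  q <- as_quadruplets(newdata)
  deg <- fuzzify(object, q)
  f <- .firing_matrix(object, deg)
  w <- object$rulebase$weight
  mass <- as.numeric(f %*% w)
  if (any(mass <= 0)) {
    i <- which(mass <= 0)[1]
    stop(sprintf("no rule coverage for quadruplet row %d (pf=%g, compliance=%g, peep=%g, film=%g)",
                 i, q$pf[i], q$compliance[i], q$peep[i], q$film[i]))
  }
  score <- as.numeric(f %*% (w * object$rulebase$consequent)) / mass
  level <- .round_level(score)
  switch(type,
         score = score,
         level = level,
         both = data.frame(score = score, level = level))
}

#' @export
print.sugeno_fis <- function(x, ...) {
  cat(sprintf("<sugeno_fis> panel of %d, %d rules over %d antecedent lines\n",
              x$panel_size, nrow(x$rulebase), attr(x$rulebase, "line_count")))
  cat("  fitted memberships:\n")
  for (i in seq_len(nrow(x$fit)))
    cat(sprintf("    %-10s %-22s %-9s SSE %.2e\n", x$fit$variable[i],
                x$fit$category[i], x$fit$family[i], x$fit$sse[i]))
  invisible(x)
}

#' @export
summary.sugeno_fis <- function(object, ...) {
  rb <- object$rulebase
  per_line <- tapply(rb$weight,
                     interaction(rb$pf_cat, rb$compliance_cat, rb$peep_cat,
                                 rb$film, drop = TRUE), sum)
  cat(sprintf("Sugeno FIS fitted from a panel of %d physicians\n",
              object$panel_size))
  cat(sprintf("  rules: %d over %d lines; per-line weight sums in [%.3f, %.3f]\n",
              nrow(rb), attr(rb, "line_count"), min(per_line), max(per_line)))
  cat(sprintf("  consequent distribution: %s\n",
              paste(sprintf("%d:%d", 0:3, tabulate(rb$consequent + 1L, 4L)),
                    collapse = " ")))
  cat("  membership fits:\n")
  print(object$fit, row.names = FALSE)
  invisible(object)
}

#' Plot fitted membership functions
#'
#' One panel per variable, with the category membership curves of the fitted
#' system; the style of the usual fuzzy-partition figure.
#'
#' @param x A `sugeno_fis`.
#' @param n Number of curve sample points per panel.
#' @param ... Passed to `matplot`.
#' @export
plot.sugeno_fis <- function(x, n = 200L, ...) {
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in c("pf", "compliance", "peep", "film")) {
    ms <- x$memberships[[v]]
    dom <- ms[[1]]$domain
    xs <- seq(dom[1], dom[2], length.out = n)
    ys <- sapply(ms, function(m) eval_mf(m, xs))
    graphics::matplot(xs, ys, type = "l", lty = 1, lwd = 2,
                      xlab = v, ylab = "membership", ylim = c(0, 1),
                      main = v, ...)
  }
  invisible(x)
}

#' Serialize a fitted FIS to JSON and back
#'
#' The document carries the memberships (family, params, domain per
#' category), the rule base and the panel size; the round trip is lossless.
#'
#' @param fis A `sugeno_fis`.
#' @param path Optional file path; if given the JSON is written there.
#' @return `fis_to_json()`: the JSON string, invisibly if `path` is given.
#' @export
fis_to_json <- function(fis, path = NULL) {
  stopifnot(inherits(fis, "sugeno_fis"))
  doc <- list(
    panel_size = fis$panel_size,
    memberships = lapply(fis$memberships, function(ms)
      lapply(ms, function(m) list(family = m$family,
                                  params = as.list(m$params),
                                  domain = m$domain))),
    rules = as.data.frame(fis$rulebase),
    line_count = attr(fis$rulebase, "line_count"),
    fit = fis$fit
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname fis_to_json
#' @param json A JSON string, or a path to one written by [fis_to_json()].
#' @export
fis_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  doc <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  mem <- lapply(doc$memberships, function(ms)
    lapply(ms, function(m) mf(m$family, unlist(m$params), m$domain)))
  rb <- structure(doc$rules, panel_size = as.integer(doc$panel_size),
                  line_count = as.integer(doc$line_count),
                  class = c("rule_base", "data.frame"))
  structure(list(memberships = mem, rulebase = rb, specs = variable_specs(),
                 panel_size = as.integer(doc$panel_size), fit = doc$fit),
            class = "sugeno_fis")
}
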