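#' Simulated-physician behavior model
#'
#' Governs how a synthetic panel answers both questionnaires. Each physician
#' places their two category frontiers per variable at the nominal frontier
#' plus independent Gaussian jitter, snapped to the nearest segment boundary
#' and clamped so all three categories stay non-empty. For the severity
#' questionnaire, each physician scores a rule line's representative
#' quadruplet with a weighted mean of Murray component scores plus bias and
#' Gaussian noise, and ticks the severity level of that score.
#'
#' Two presets are provided. `"faithful"` uses equal diagnostic weights,
#' zero bias, zero jitter and zero noise: the panel then reproduces the
#' crisp Murray reading of each line exactly and unanimously.
#' `"overweight"` doubles the PaO2/FiO2 and chest-film weights and adds
#' moderate frontier jitter and diagnostic noise, emulating a panel that
#' grades gas exchange and consolidations as more decisive than the linear
#' Murray equation does.
#'
#' @param preset `"faithful"` or `"overweight"`.
#' @param frontier_means Named list (pf, compliance, peep), each a length-2
#'   numeric of nominal frontiers in domain units. Defaults are the
#'   boundaries between Murray component-score bands 0|1 and 3|4 of each
#'   variable.
#' @param frontier_jitter_sd Named numeric (pf, compliance, peep), SD of the
#'   per-physician frontier displacement, domain units, `>= 0`.
#' @param diagnosis_weights Named numeric (pf, compliance, peep, film),
#'   nonnegative with positive sum.
#' @param diagnosis_noise_sd Scalar `>= 0`, SD of the additive score noise.
#' @param severity_bias Scalar shift added to every physician's score.
#' @param seed Default RNG seed used by the simulators when they are not
#'   given one explicitly.
#' @return An object of class `behavior_model`.
#' @export
behavior_model <- function(preset = c("faithful", "overweight"),
                           frontier_means = NULL,
                           frontier_jitter_sd = NULL,
                           diagnosis_weights = NULL,
                           diagnosis_noise_sd = NULL,
                           severity_bias = 0,
                           seed = 1L) {
  preset <- match.arg(preset)
  def_means <- list(pf = c(100, 300), compliance = c(20, 80), peep = c(6, 15))
  if (preset == "faithful") {
    jit <- c(pf = 0, compliance = 0, peep = 0)
    w <- c(pf = 1, compliance = 1, peep = 1, film = 1)
    noise <- 0
  } else {
    jit <- c(pf = 25, compliance = 5, peep = 1)
    w <- c(pf = 2, compliance = 1, peep = 1, film = 2)
    noise <- 0.25
  }
  m <- if (is.null(frontier_means)) def_means else frontier_means
  jit <- if (is.null(frontier_jitter_sd)) jit else frontier_jitter_sd
  w <- if (is.null(diagnosis_weights)) w else diagnosis_weights
  noise <- if (is.null(diagnosis_noise_sd)) noise else diagnosis_noise_sd

  if (!all(c("pf", "compliance", "peep") %in% names(m)))
    stop("`frontier_means` needs entries pf, compliance, peep")
  if (any(unlist(jit) < 0) || noise < 0)
    stop("jitter and noise SDs must be >= 0")
  if (any(w < 0) || sum(w) <= 0)
    stop("diagnosis weights must be nonnegative with a positive sum")
  specs <- variable_specs()
  for (v in c("pf", "compliance", "peep")) {
    dom <- specs[[v]]$domain
    if (any(m[[v]] <= dom[1]) || any(m[[v]] >= dom[2]) ||
        m[[v]][1] >= m[[v]][2])
      stop(sprintf("frontier means for '%s' must be ordered and strictly inside [%g, %g]",
                   v, dom[1], dom[2]))
  }
  structure(list(preset = preset, frontier_means = m,
                 frontier_jitter_sd = unlist(jit),
                 diagnosis_weights = w[c("pf", "compliance", "peep", "film")],
                 diagnosis_noise_sd = noise, severity_bias = severity_bias,
                 seed = as.integer(seed)),
            class = "behavior_model")
}

#' @export
print.behavior_model <- function(x, ...) {
  cat(sprintf("<behavior_model> preset '%s'\n", x$preset))
  cat("  weights:", paste(sprintf("%s=%g", names(x$diagnosis_weights),
                                  x$diagnosis_weights), collapse = " "), "\n")
  cat(sprintf("  jitter SD: pf=%g compliance=%g peep=%g; noise SD %g; bias %g\n",
              x$frontier_jitter_sd["pf"], x$frontier_jitter_sd["compliance"],
              x$frontier_jitter_sd["peep"], x$diagnosis_noise_sd,
              x$severity_bias))
  invisible(x)
}

#' All antecedent rule lines
#'
#' The full factorial set of antecedent combinations: three categories each
#' for PaO2/FiO2, compliance and PEEP (indices 0–2 in spec label order) and
#' five chest-film levels, 135 lines in all. The original survey retained a
#' 107-line "probable" subset it did not enumerate; pass a filtered subset
#' to restrict the questionnaire.
#'
#' @return Data frame with columns `pf_cat`, `compliance_cat`, `peep_cat`
#'   (0–2) and `film` (0–4).
#' @export
all_rule_lines <- function() {
  g <- expand.grid(film = 0:4, peep_cat = 0:2, compliance_cat = 0:2,
                   pf_cat = 0:2)
  g[, c("pf_cat", "compliance_cat", "peep_cat", "film")]
}

#' Simulate questionnaire-1 partition responses
#'
#' Each physician partitions each variable's segment sequence into three
#' contiguous, exhaustive, non-empty category runs. Frontiers are the
#' behavior model's nominal means plus Gaussian jitter, snapped to the
#' nearest segment boundary, then clamped to keep `1 <= cut1 < cut2 <=
#' n_segments - 1`.
#'
#' @param specs Named list of `variable_spec`s, default [variable_specs()].
#' @param behavior A `behavior_model`.
#' @param n_physicians Panel size, `>= 1`.
#' @param seed RNG seed (defaults to the behavior model's seed).
#' @return Data frame with columns `physician_id`, `variable`, `cut1`,
#'   `cut2`.
#' @export
gen_partition_responses <- function(specs = variable_specs(),
                                    behavior = behavior_model(),
                                    n_physicians = 12L,
                                    seed = behavior$seed) {
  stopifnot(inherits(behavior, "behavior_model"), n_physicians >= 1L)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (spec in specs) {
    v <- spec$name
    w <- segment_width(spec)
    n <- spec$n_segments
    m <- behavior$frontier_means[[v]]
    sd <- behavior$frontier_jitter_sd[[v]]
    f1 <- m[1] + stats::rnorm(n_physicians, 0, sd)
    f2 <- m[2] + stats::rnorm(n_physicians, 0, sd)
    cut1 <- round((f1 - spec$domain[1]) / w)
    cut2 <- round((f2 - spec$domain[1]) / w)
    cut1 <- pmin(pmax(cut1, 1L), n - 2L)
    cut2 <- pmin(pmax(cut2, cut1 + 1L), n - 1L)
    out[[v]] <- data.frame(physician_id = seq_len(n_physicians), variable = v,
                           cut1 = as.integer(cut1), cut2 = as.integer(cut2))
  }
  r <- do.call(rbind, out)
  rownames(r) <- NULL
  r
}

# representative value of each category run under the nominal frontiers:
# the run midpoint (film levels are taken verbatim)
.category_representatives <- function(spec, frontiers) {
  lo <- spec$domain[1]; hi <- spec$domain[2]
  c((lo + frontiers[1]) / 2, (frontiers[1] + frontiers[2]) / 2,
    (frontiers[2] + hi) / 2)
}

#' Simulate questionnaire-2 severity ticks
#'
#' Each physician reads every antecedent line, mentally instantiates it as
#' its representative quadruplet (category-run midpoints under the nominal
#' frontiers; film level verbatim), computes a weighted mean of the Murray
#' component scores of those representatives, adds bias and personal noise,
#' and ticks the severity level of the resulting score. Ticks are
#' aggregated per line.
#'
#' @param lines Data frame of antecedent lines, see [all_rule_lines()].
#' @param behavior A `behavior_model`.
#' @param n_physicians Panel size.
#' @param specs Named list of `variable_spec`s.
#' @param bands `murray_bands` table used for component scoring.
#' @param seed RNG seed (defaults to the behavior model's seed).
#' @return Data frame: the line columns plus tick counts `n0`..`n3`, each
#'   row summing to `n_physicians`.
#' @export
gen_rule_responses <- function(lines = all_rule_lines(),
                               behavior = behavior_model(),
                               n_physicians = 12L,
                               specs = variable_specs(),
                               bands = murray_bands(),
                               seed = behavior$seed) {
  stopifnot(inherits(behavior, "behavior_model"))
  if (nrow(lines) == 0L) stop("empty rule-line list")
  if (!is.null(seed)) set.seed(seed)
  w <- behavior$diagnosis_weights
  rep_scores <- sapply(c("pf", "compliance", "peep"), function(v) {
    reps <- .category_representatives(specs[[v]],
                                      behavior$frontier_means[[v]])
    murray_component(v, reps, bands)
  })
  base <- (w["pf"] * rep_scores[lines$pf_cat + 1L, "pf"] +
             w["compliance"] * rep_scores[lines$compliance_cat + 1L, "compliance"] +
             w["peep"] * rep_scores[lines$peep_cat + 1L, "peep"] +
             w["film"] * lines$film) / sum(w) + behavior$severity_bias
  ticks <- matrix(0L, nrow = nrow(lines), ncol = 4L,
                  dimnames = list(NULL, paste0("n", 0:3)))
  for (p in seq_len(n_physicians)) {
    sev <- base + stats::rnorm(nrow(lines), 0, behavior$diagnosis_noise_sd)
    lev <- murray_level(pmax(sev, 0))
    for (k in 0:3) ticks[, k + 1L] <- ticks[, k + 1L] + (lev == k)
  }
  cbind(lines, as.data.frame(ticks))
}

#' Simulate a complete two-questionnaire survey
#'
#' Runs both questionnaire simulators for one panel under one seed and
#' bundles the results.
#'
#' @inheritParams gen_rule_responses
#' @inheritParams gen_partition_responses
#' @return Object of class `lis_survey`: list with `partitions`, `rules`
#'   (tick counts per line), `panel_size`, `behavior`, `specs`.
#' @examples
#' sv <- simulate_survey(behavior = behavior_model("faithful"), seed = 7)
#' head(sv$partitions)
#' @export
simulate_survey <- function(n_physicians = 12L,
                            behavior = behavior_model(),
                            specs = variable_specs(),
                            lines = all_rule_lines(),
                            bands = murray_bands(),
                            seed = behavior$seed) {
  if (n_physicians < 1L) stop("`n_physicians` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  part <- gen_partition_responses(specs, behavior, n_physicians, seed = NULL)
  rules <- gen_rule_responses(lines, behavior, n_physicians, specs, bands,
                              seed = NULL)
  structure(list(partitions = part, rules = rules,
                 panel_size = as.integer(n_physicians),
                 behavior = behavior, specs = specs),
            class = "lis_survey")
}

#' @export
print.lis_survey <- function(x, ...) {
  cat(sprintf("<lis_survey> %d physicians ('%s' preset)\n", x$panel_size,
              x$behavior$preset))
  cat(sprintf("  questionnaire 1: %d partition responses over %d variables\n",
              nrow(x$partitions), length(unique(x$partitions$variable))))
  cat(sprintf("  questionnaire 2: %d antecedent lines, %d ticks each\n",
              nrow(x$rules), x$panel_size))
  invisible(x)
}

#' Write survey responses as CSV
#'
#' `write_survey()` writes `questionnaire1.csv` (columns physician_id,
#' variable, cut1, cut2) and `questionnaire2.csv` (antecedent indices plus
#' tick counts n0..n3) into `dir`.
#'
#' @param survey A `lis_survey`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "lis_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "questionnaire1.csv")
  p2 <- file.path(dir, "questionnaire2.csv")
  utils::write.csv(survey$partitions, p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(survey$rules, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
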