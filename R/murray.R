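#' Default Murray score band table
#'
#' Component-score bands of the original lung injury score. Each continuous
#' variable is divided into five ordered, exhaustive, non-overlapping bands
#' mapped to component scores 0 to 4; the chest film maps k consolidated
#' quadrants directly to score k. Band bounds (`lo`, `hi`) are stored as
#' printed in the original score table (hence `hi` of one band need not equal
#' `lo` of the next for integer-valued tables); score lookup uses the `lo`
#' cut points, so the bands tile the whole domain. Band centers, used by the
#' hypothetical-patient grid, are `(lo + hi) / 2` — e.g. the PaO2/FiO2 band
#' 100–174 has center 137.
#'
#' @return A named list of class `murray_bands` with one data.frame per
#'   continuous variable (columns `score`, `lo`, `hi`), rows ordered by
#'   ascending `lo`.
#' @examples
#' b <- murray_bands()
#' murray_component("pf", 137, b)   # 3
#' @export
murray_bands <- function() {
  structure(list(
    pf = data.frame(score = c(4L, 3L, 2L, 1L, 0L),
                    lo = c(0, 100, 175, 225, 300),
                    hi = c(99, 174, 224, 299, 450)),
    compliance = data.frame(score = c(4L, 3L, 2L, 1L, 0L),
                            lo = c(0, 20, 40, 60, 80),
                            hi = c(19, 39, 59, 79, 100)),
    peep = data.frame(score = 0:4,
                      lo = c(0, 6, 9, 12, 15),
                      hi = c(5, 8, 11, 14, 20))
  ), class = "murray_bands")
}

.validate_bands <- function(bands) {
  if (!inherits(bands, "murray_bands"))
    stop("`bands` must be a murray_bands object")
  for (v in c("pf", "compliance", "peep")) {
    b <- bands[[v]]
    if (is.null(b) || !all(c("score", "lo", "hi") %in% names(b)) ||
        nrow(b) != 5L || is.unsorted(b$lo, strictly = TRUE) ||
        !setequal(b$score, 0:4))
      stop("invalid band table for variable '", v, "'")
  }
  invisible(bands)
}

.band_domain <- function(bands, variable) {
  b <- bands[[variable]]
  c(b$lo[1], b$hi[nrow(b)])
}

#' Murray component score of a single variable
#'
#' Looks up the 0–4 component score of `value` in the band table. For the
#' chest film the mapping is the identity on the integers 0–4.
#'
#' @param variable One of `"pf"`, `"compliance"`, `"peep"`, `"film"`.
#' @param value Numeric vector of values within the variable's domain.
#' @param bands A `murray_bands` table, by default [murray_bands()].
#' @return Integer vector of component scores in 0–4.
#' @export
murray_component <- function(variable, value, bands = murray_bands()) {
  variable <- match.arg(variable, c("pf", "compliance", "peep", "film"))
  if (variable == "film") {
    if (any(!is.finite(value) | value != round(value) | value < 0 | value > 4))
      stop("chest film must be an integer in 0..4")
    return(as.integer(value))
  }
  .validate_bands(bands)
  b <- bands[[variable]]
  dom <- .band_domain(bands, variable)
  if (any(!is.finite(value) | value < dom[1] | value > dom[2]))
    stop(sprintf("'%s' value outside domain [%g, %g]", variable,
                 dom[1], dom[2]))
  b$score[findInterval(value, b$lo)]
}

#' Crisp Murray lung injury score
#'
#' The arithmetic mean of the four 0–4 component scores (PaO2/FiO2,
#' compliance, PEEP, consolidated chest-film quadrants).
#'
#' @param q Data frame of patient quadruplets with columns `pf`,
#'   `compliance`, `peep`, `film` (or a single named quadruplet coercible to
#'   one row).
#' @param bands A `murray_bands` table.
#' @return Numeric vector of scores in \[0, 4\], one per row of `q`.
#' @examples
#' murray_score(data.frame(pf = 250, compliance = 55, peep = 8, film = 1)) # 1.25
#' @export
murray_score <- function(q, bands = murray_bands()) {
  q <- as_quadruplets(q)
  (murray_component("pf", q$pf, bands) +
     murray_component("compliance", q$compliance, bands) +
     murray_component("peep", q$peep, bands) +
     murray_component("film", q$film, bands)) / 4
}

#' Severity level of a Murray score
#'
#' Maps scores to the four severity levels: 0 (no injury) on \[0, 0.1\],
#' 1 (mild) on (0.1, 1.5\], 2 (moderate) on (1.5, 2.5\] and 3 (ARDS) on
#' (2.5, Inf). The split of the original mild-to-moderate band at 1.5
#' distinguishes injury without from injury with ALI.
#'
#' @param score Numeric vector of nonnegative scores.
#' @return Integer severity levels in 0–3.
#' @export
murray_level <- function(score) {
  if (any(!is.finite(score) | score < 0))
    stop("Murray scores must be finite and nonnegative")
  ifelse(score <= 0.1, 0L, ifelse(score <= 1.5, 1L,
                                  ifelse(score <= 2.5, 2L, 3L)))
}

#' Coerce to a quadruplet data frame
#'
#' Validates the quadruplet columns and domains (pf in \[0,450\], compliance
#' in \[0,100\], peep in \[0,20\], film integer 0–4).
#'
#' @param q A data.frame with columns `pf`, `compliance`, `peep`, `film`, or
#'   a named numeric vector/list with those names.
#' @return A validated data.frame.
#' @export
as_quadruplets <- function(q) {
  if (!is.data.frame(q)) q <- as.data.frame(as.list(q))
  need <- c("pf", "compliance", "peep", "film")
  if (!all(need %in% names(q)))
    stop("quadruplets need columns: ", paste(need, collapse = ", "))
  q <- q[need]
  rng <- list(pf = c(0, 450), compliance = c(0, 100), peep = c(0, 20),
              film = c(0, 4))
  for (v in need) {
    x <- q[[v]]
    if (any(!is.finite(x) | x < rng[[v]][1] | x > rng[[v]][2]))
      stop(sprintf("'%s' outside its domain [%g, %g]", v,
                   rng[[v]][1], rng[[v]][2]))
  }
  if (any(q$film != round(q$film))) stop("'film' must be integral")
  q
}
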