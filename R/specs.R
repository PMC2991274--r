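#' Default Murray-variable survey specifications
#'
#' The three continuous Murray variables surveyed in questionnaire 1, each
#' with its closed domain, its equal-width segmentation and the ordered
#' three-category division physicians partition it into. PaO2/FiO2 is
#' segmented into 9 segments of 50 mmHg-ratio over \[0, 450\]; respiratory
#' compliance into 10 segments of 10 ml/cmH2O over \[0, 100\]; PEEP into 10
#' segments of 2 cmH2O over \[0, 20\]. Category labels are ordered worst to
#' best for PaO2/FiO2 and compliance, and low/moderate/high for PEEP (where
#' low PEEP is the least severe).
#'
#' @return A named list of `variable_spec` objects with elements `name`,
#'   `domain` (length-2 numeric), `n_segments`, `categories` (ordered
#'   character triple) and `units`.
#' @examples
#' specs <- variable_specs()
#' specs$pf$n_segments       # 9
#' segment_width(specs$pf)   # 50
#' @export
variable_specs <- function() {
  list(
    pf = variable_spec("pf", c(0, 450), 9L,
                       c("severe", "moderate", "normal"), "mmHg ratio"),
    compliance = variable_spec("compliance", c(0, 100), 10L,
                               c("severely.diminished", "moderately.diminished",
                                 "normal"), "ml/cmH2O"),
    peep = variable_spec("peep", c(0, 20), 10L,
                         c("low", "moderate", "high"), "cmH2O")
  )
}

#' Construct a single variable specification
#'
#' @param name Variable label.
#' @param domain Closed numeric interval `c(lo, hi)` with `lo < hi`.
#' @param n_segments Positive integer count of equal-width segments.
#' @param categories Ordered character triple of category labels.
#' @param units Unit string (informational).
#' @return A `variable_spec` object.
#' @export
variable_spec <- function(name, domain, n_segments, categories, units = "") {
  stopifnot(is.character(name), length(name) == 1L)
  domain <- as.numeric(domain)
  if (length(domain) != 2L || !all(is.finite(domain)) || domain[1] >= domain[2])
    stop("`domain` must be a finite interval c(lo, hi) with lo < hi")
  n_segments <- as.integer(n_segments)
  if (is.na(n_segments) || n_segments < 2L)
    stop("`n_segments` must be an integer >= 2")
  if (length(categories) != 3L)
    stop("exactly three category labels are required")
  structure(
    list(name = name, domain = domain, n_segments = n_segments,
         categories = as.character(categories), units = units),
    class = "variable_spec"
  )
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s: [%g, %g] %s, %d segments of width %g\n",
              x$name, x$domain[1], x$domain[2], x$units, x$n_segments,
              segment_width(x)))
  cat("  categories:", paste(x$categories, collapse = " < "), "\n")
  invisible(x)
}

#' Segment geometry of a variable specification
#'
#' @param spec A `variable_spec`.
#' @return `segment_width()`: the common segment width;
#'   `segment_boundaries()`: the `n_segments + 1` boundary values including
#'   both domain endpoints; `segment_midpoints()`: the `n_segments` midpoints.
#' @export
segment_width <- function(spec) diff(spec$domain) / spec$n_segments

#' @rdname segment_width
#' @export
segment_boundaries <- function(spec)
  seq(spec$domain[1], spec$domain[2], length.out = spec$n_segments + 1L)

#' @rdname segment_width
#' @export
segment_midpoints <- function(spec) {
  b <- segment_boundaries(spec)
  (b[-1] + b[-length(b)]) / 2
}
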