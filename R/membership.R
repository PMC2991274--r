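#' Membership function objects
#'
#' A membership function maps a variable's domain to degrees in \[0, 1\].
#' Nine parametric families are supported, matching the repertoire of
#' classical fuzzy toolboxes:
#'
#' * `zmf(a, b)` — Z-shaped spline, 1 left of `a`, 0 right of `b`;
#' * `smf(a, b)` — S-shaped mirror image of `zmf`;
#' * `sigmf(a, c)` — sigmoid `1 / (1 + exp(-a (x - c)))`;
#' * `dsigmf(a1, c1, a2, c2)` — difference of two sigmoids (clamped to \[0,1\]);
#' * `psigmf(a1, c1, a2, c2)` — product of two sigmoids;
#' * `gbellmf(a, b, c)` — generalized bell `1 / (1 + |(x - c)/a|^(2b))`;
#' * `gaussmf(sig, c)` — Gaussian bump;
#' * `gauss2mf(sig1, c1, sig2, c2)` — two-sided Gaussian with a flat top;
#' * `trapmf(a, b, c, d)` — trapezoid.
#'
#' @param family Family label, one of [mf_families()].
#' @param params Named numeric parameter vector for the family.
#' @param domain Closed interval `c(lo, hi)` on which the function is defined.
#' @return An object of class `mf`.
#' @examples
#' bell <- mf("gbellmf", c(a = 0.5, b = 3, c = 2), c(0, 4))
#' eval_mf(bell, 2)     # 1
#' eval_mf(bell, 1.5)   # 0.5
#' @export
mf <- function(family, params, domain) {
  family <- match.arg(family, mf_families())
  fam <- .mf_registry[[family]]
  params <- unlist(params)
  if (length(params) != length(fam$par_names))
    stop(sprintf("family '%s' needs parameters %s", family,
                 paste(fam$par_names, collapse = ", ")))
  names(params) <- fam$par_names
  if (!all(is.finite(params))) stop("membership parameters must be finite")
  fam$validate(params)
  domain <- as.numeric(domain)
  if (length(domain) != 2L || domain[1] >= domain[2])
    stop("`domain` must be c(lo, hi) with lo < hi")
  structure(list(family = family, params = params, domain = domain),
            class = "mf")
}

#' Membership family labels
#' @return Character vector of the nine supported family names.
#' @export
mf_families <- function() names(.mf_registry)

.sig <- function(x, a, c) 1 / (1 + exp(-a * (x - c)))

.zmf_core <- function(x, a, b) {
  y <- numeric(length(x))
  m <- (a + b) / 2
  y[x <= a] <- 1
  i <- x > a & x <= m
  y[i] <- 1 - 2 * ((x[i] - a) / (b - a))^2
  i <- x > m & x < b
  y[i] <- 2 * ((x[i] - b) / (b - a))^2
  y
}

# registry: eval in canonical params; fitting metadata in raw parameter
# space (raw2canon enforces ordering/positivity so nls.lm box bounds suffice)
.mf_registry <- list(
  zmf = list(
    par_names = c("a", "b"),
    validate = function(p) if (p["b"] <= p["a"]) stop("zmf needs a < b"),
    eval = function(p, x) .zmf_core(x, p["a"], p["b"]),
    raw_names = c("a", "w"),
    raw2canon = function(r) c(a = unname(r[1]), b = unname(r[1] + r[2])),
    bounds = function(dom) {
      w <- diff(dom)
      list(lower = c(dom[1] - w, 1e-6 * w), upper = c(dom[2] + w, 2 * w))
    },
    start = function(x, y, dom) {
      cr <- .cross_down(x, y)
      w <- .grid_step(x)
      t(sapply(c(1, 2, 4) * w, function(wd) c(cr - wd / 2, wd)))
    }
  ),
  smf = list(
    par_names = c("a", "b"),
    validate = function(p) if (p["b"] <= p["a"]) stop("smf needs a < b"),
    eval = function(p, x) 1 - .zmf_core(x, p["a"], p["b"]),
    raw_names = c("a", "w"),
    raw2canon = function(r) c(a = unname(r[1]), b = unname(r[1] + r[2])),
    bounds = function(dom) {
      w <- diff(dom)
      list(lower = c(dom[1] - w, 1e-6 * w), upper = c(dom[2] + w, 2 * w))
    },
    start = function(x, y, dom) {
      cr <- .cross_up(x, y)
      w <- .grid_step(x)
      t(sapply(c(1, 2, 4) * w, function(wd) c(cr - wd / 2, wd)))
    }
  ),
  sigmf = list(
    par_names = c("a", "c"),
    validate = function(p) invisible(TRUE),
    eval = function(p, x) .sig(x, p["a"], p["c"]),
    raw_names = c("a", "c"),
    raw2canon = function(r) c(a = unname(r[1]), c = unname(r[2])),
    bounds = function(dom) {
      w <- diff(dom)
      list(lower = c(-1e4 / w, dom[1] - w), upper = c(1e4 / w, dom[2] + w))
    },
    start = function(x, y, dom) {
      up <- y[length(y)] >= y[1]
      cr <- if (up) .cross_up(x, y) else .cross_down(x, y)
      w <- .grid_step(x)
      c(if (up) 4 / w else -4 / w, cr)
    }
  ),
  dsigmf = list(
    par_names = c("a1", "c1", "a2", "c2"),
    validate = function(p) invisible(TRUE),
    eval = function(p, x)
      pmin(1, pmax(0, .sig(x, p["a1"], p["c1"]) - .sig(x, p["a2"], p["c2"]))),
    raw_names = c("a1", "c1", "a2", "dc"),
    raw2canon = function(r) c(a1 = unname(r[1]), c1 = unname(r[2]),
                              a2 = unname(r[3]), c2 = unname(r[2] + r[4])),
    bounds = function(dom) {
      w <- diff(dom)
      list(lower = c(1e-4 / w, dom[1] - w, 1e-4 / w, 0),
           upper = c(1e4 / w, dom[2] + w, 1e4 / w, 3 * w))
    },
    start = function(x, y, dom) {
      b <- .bump_edges(x, y)
      w <- .grid_step(x)
      c(4 / w, b[1], 4 / w, max(b[2] - b[1], w / 2))
    }
  ),
  psigmf = list(
    par_names = c("a1", "c1", "a2", "c2"),
    validate = function(p) invisible(TRUE),
    eval = function(p, x) .sig(x, p["a1"], p["c1"]) * .sig(x, p["a2"], p["c2"]),
    raw_names = c("a1", "c1", "a2", "dc"),
    raw2canon = function(r) c(a1 = unname(r[1]), c1 = unname(r[2]),
                              a2 = unname(-r[3]), c2 = unname(r[2] + r[4])),
    bounds = function(dom) {
      w <- diff(dom)
      list(lower = c(1e-4 / w, dom[1] - w, 1e-4 / w, 0),
           upper = c(1e4 / w, dom[2] + w, 1e4 / w, 3 * w))
    },
    start = function(x, y, dom) {
      b <- .bump_edges(x, y)
      w <- .grid_step(x)
      c(4 / w, b[1], 4 / w, max(b[2] - b[1], w / 2))
    }
  ),
  gbellmf = list(
    par_names = c("a", "b", "c"),
    validate = function(p) {
      if (p["a"] <= 0 || p["b"] <= 0) stop("gbellmf needs a > 0 and b > 0")
    },
    eval = function(p, x) 1 / (1 + abs((x - p["c"]) / p["a"])^(2 * p["b"])),
    raw_names = c("a", "b", "c"),
    raw2canon = function(r) c(a = unname(r[1]), b = unname(r[2]),
                              c = unname(r[3])),
    bounds = function(dom) {
      w <- diff(dom)
      list(lower = c(1e-6 * w, 0.25, dom[1] - w),
           upper = c(5 * w, 50, dom[2] + w))
    },
    start = function(x, y, dom) {
      b <- .bump_edges(x, y)
      c(max((b[2] - b[1]) / 2, .grid_step(x) / 2), 2, (b[1] + b[2]) / 2)
    }
  ),
  gaussmf = list(
    par_names = c("sig", "c"),
    validate = function(p) if (p["sig"] <= 0) stop("gaussmf needs sig > 0"),
    eval = function(p, x) exp(-(x - p["c"])^2 / (2 * p["sig"]^2)),
    raw_names = c("sig", "c"),
    raw2canon = function(r) c(sig = unname(r[1]), c = unname(r[2])),
    bounds = function(dom) {
      w <- diff(dom)
      list(lower = c(1e-6 * w, dom[1] - w), upper = c(5 * w, dom[2] + w))
    },
    start = function(x, y, dom) {
      b <- .bump_edges(x, y)
      c(max((b[2] - b[1]) / 2.35, .grid_step(x) / 2), (b[1] + b[2]) / 2)
    }
  ),
  gauss2mf = list(
    par_names = c("sig1", "c1", "sig2", "c2"),
    validate = function(p) {
      if (p["sig1"] <= 0 || p["sig2"] <= 0) stop("gauss2mf needs sig > 0")
      if (p["c2"] < p["c1"]) stop("gauss2mf needs c1 <= c2")
    },
    eval = function(p, x) {
      y <- rep(1, length(x))
      i <- x < p["c1"]
      y[i] <- exp(-(x[i] - p["c1"])^2 / (2 * p["sig1"]^2))
      i <- x > p["c2"]
      y[i] <- exp(-(x[i] - p["c2"])^2 / (2 * p["sig2"]^2))
      y
    },
    raw_names = c("sig1", "c1", "sig2", "dc"),
    raw2canon = function(r) c(sig1 = unname(r[1]), c1 = unname(r[2]),
                              sig2 = unname(r[3]), c2 = unname(r[2] + r[4])),
    bounds = function(dom) {
      w <- diff(dom)
      list(lower = c(1e-6 * w, dom[1] - w, 1e-6 * w, 0),
           upper = c(5 * w, dom[2] + w, 5 * w, 3 * w))
    },
    start = function(x, y, dom) {
      b <- .bump_edges(x, y)
      s <- max(.grid_step(x) / 2, (b[2] - b[1]) / 10)
      c(s, b[1], s, max(b[2] - b[1], 0))
    }
  ),
  trapmf = list(
    par_names = c("a", "b", "c", "d"),
    validate = function(p) {
      if (is.unsorted(p[c("a", "b", "c", "d")]))
        stop("trapmf needs a <= b <= c <= d")
      if (p["d"] <= p["a"]) stop("trapmf must have positive support")
    },
    eval = function(p, x) {
      y <- numeric(length(x))
      a <- p["a"]; b <- p["b"]; cc <- p["c"]; d <- p["d"]
      i <- x >= b & x <= cc
      y[i] <- 1
      if (b > a) {
        i <- x > a & x < b
        y[i] <- (x[i] - a) / (b - a)
      }
      if (d > cc) {
        i <- x > cc & x < d
        y[i] <- (d - x[i]) / (d - cc)
      }
      y
    },
    raw_names = c("a", "w1", "w2", "w3"),
    raw2canon = function(r) c(a = unname(r[1]), b = unname(r[1] + r[2]),
                              c = unname(r[1] + r[2] + r[3]),
                              d = unname(r[1] + r[2] + r[3] + r[4])),
    bounds = function(dom) {
      w <- diff(dom)
      list(lower = c(dom[1] - w, 1e-6 * w, 0, 1e-6 * w),
           upper = c(dom[2] + w, 2 * w, 2 * w, 2 * w))
    },
    start = function(x, y, dom) {
      b <- .bump_edges(x, y)
      w <- .grid_step(x)
      c(b[1] - w / 2, w, max(b[2] - b[1], w / 2), w)
    }
  )
)

.grid_step <- function(x) if (length(x) > 1L) min(diff(sort(x))) else 1

# abscissa of the downward 0.5 crossing (Z-like data); domain-end fallbacks
.cross_down <- function(x, y) {
  o <- order(x); x <- x[o]; y <- y[o]
  for (i in seq_len(length(x) - 1L)) {
    if (y[i] >= 0.5 && y[i + 1L] < 0.5) {
      if (y[i] == y[i + 1L]) return(x[i])
      return(x[i] + (y[i] - 0.5) / (y[i] - y[i + 1L]) * (x[i + 1L] - x[i]))
    }
  }
  if (y[1] < 0.5) x[1] else x[length(x)]
}

.cross_up <- function(x, y) .cross_down(x, 1 - y)

# left and right half-maximum edges of a bump-like density
.bump_edges <- function(x, y) {
  o <- order(x); x <- x[o]; y <- y[o]
  pk <- which.max(y)
  left <- if (pk > 1L) .cross_up(x[1:pk], y[1:pk]) else x[1]
  n <- length(x)
  right <- if (pk < n) .cross_down(x[pk:n], y[pk:n]) else x[n]
  if (right < left) right <- left
  c(left, right)
}

#' Evaluate a membership function
#'
#' Values marginally outside the domain (within a 1e-9 relative tolerance)
#' are clamped to the nearest endpoint; values grossly outside raise an
#' error. Degrees are clamped into \[0, 1\] so every family honours the
#' membership range on its whole domain.
#'
#' @param object An `mf` object.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of degrees in \[0, 1\].
#' @export
eval_mf <- function(object, x) {
  stopifnot(inherits(object, "mf"))
  dom <- object$domain
  tol <- 1e-9 * max(1, abs(dom[1]), abs(dom[2]))
  if (any(!is.finite(x) | x < dom[1] - tol | x > dom[2] + tol))
    stop(sprintf("value outside membership domain [%g, %g]", dom[1], dom[2]))
  x <- pmin(pmax(x, dom[1]), dom[2])
  y <- .mf_registry[[object$family]]$eval(object$params, x)
  unname(pmin(1, pmax(0, y)))
}

#' @rdname eval_mf
#' @param newdata Numeric vector of evaluation points (alias of `x`).
#' @param ... Unused.
#' @export
predict.mf <- function(object, newdata, ...) eval_mf(object, newdata)

#' @export
print.mf <- function(x, ...) {
  cat(sprintf("<mf> %s(%s) on [%g, %g]\n", x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              x$domain[1], x$domain[2]))
  invisible(x)
}

#' Vote densities from questionnaire-1 partitions
#'
#' For every segment midpoint of the variable's segmentation, the fraction
#' of the panel assigning that segment to each of the three categories. The
#' three densities at any midpoint sum to exactly 1 because each physician's
#' partition is contiguous and exhaustive.
#'
#' @param partitions Data frame of partition responses with columns
#'   `physician_id`, `variable`, `cut1`, `cut2` (segment-boundary indices,
#'   `1 <= cut1 < cut2 <= n_segments - 1`).
#' @param spec The `variable_spec` the responses refer to.
#' @return An object of class `vote_density`: list with `variable`, `grid`
#'   (segment midpoints), `density` (3 x n matrix, rows = categories) and
#'   `panel` (panel size).
#' @examples
#' p <- data.frame(physician_id = 1:2, variable = "peep", cut1 = 3, cut2 = 7)
#' vote_densities(p, variable_specs()$peep)
#' @export
vote_densities <- function(partitions, spec) {
  stopifnot(inherits(spec, "variable_spec"))
  partitions <- partitions[partitions$variable == spec$name, , drop = FALSE]
  if (nrow(partitions) == 0L)
    stop("no partition responses for variable '", spec$name, "'")
  n <- spec$n_segments
  if (any(partitions$cut1 < 1L | partitions$cut2 > n - 1L |
          partitions$cut1 >= partitions$cut2))
    stop("invalid cuts: need 1 <= cut1 < cut2 <= n_segments - 1")
  P <- nrow(partitions)
  dens <- matrix(0, nrow = 3L, ncol = n,
                 dimnames = list(spec$categories, NULL))
  for (i in seq_len(P)) {
    cat_of_seg <- rep(3L, n)
    cat_of_seg[seq_len(partitions$cut2[i])] <- 2L
    cat_of_seg[seq_len(partitions$cut1[i])] <- 1L
    for (k in 1:3) dens[k, ] <- dens[k, ] + (cat_of_seg == k)
  }
  structure(list(variable = spec$name, grid = segment_midpoints(spec),
                 density = dens / P, panel = P),
            class = "vote_density")
}

#' @export
print.vote_density <- function(x, ...) {
  cat(sprintf("<vote_density> %s: panel of %d over %d segment midpoints\n",
              x$variable, x$panel, length(x$grid)))
  m <- rbind(midpoint = x$grid, x$density)
  print(round(m, 3))
  invisible(x)
}

#' Fit a membership function to a vote density
#'
#' Least-squares fit of each offered parametric family to the category's
#' density points; the family with the smallest sum of squared residuals
#' wins (ties broken by family order). Initial parameters are data-driven
#' (half-maximum crossings of the density), so fits are deterministic.
#' Optimization uses Levenberg–Marquardt with box bounds.
#'
#' @param density A `vote_density` object.
#' @param category Category index 1–3 or category label.
#' @param families Character vector of families to try, default all nine.
#' @return The winning `mf`, with attributes `sse` (its residual sum of
#'   squares) and `fit_report` (per-family SSE, `NA` for failed fits).
#' @export
fit_mf <- function(density, category, families = mf_families()) {
  stopifnot(inherits(density, "vote_density"))
  if (is.character(category))
    category <- match(category, rownames(density$density))
  y <- density$density[category, ]
  x <- density$grid
  dom <- c(x[1] - .grid_step(x) / 2, x[length(x)] + .grid_step(x) / 2)
  fit_mf_points(x, y, dom, families)
}

#' @rdname fit_mf
#' @param x,y Density points (abscissa and degree in \[0,1\]).
#' @param domain The membership domain for the fitted function.
#' @export
fit_mf_points <- function(x, y, domain, families = mf_families()) {
  if (length(x) < 4L) stop("need at least 4 points to fit")
  families <- match.arg(families, mf_families(), several.ok = TRUE)
  best <- NULL
  report <- stats::setNames(rep(NA_real_, length(families)), families)
  for (f in families) {
    fam <- .mf_registry[[f]]
    fit <- tryCatch({
      bb <- fam$bounds(domain)
      starts <- fam$start(x, y, domain)
      if (is.null(dim(starts))) starts <- matrix(starts, nrow = 1L)
      fam_best <- NULL
      for (s in seq_len(nrow(starts))) {
        start <- pmin(pmax(starts[s, ], bb$lower), bb$upper)
        res <- minpack.lm::nls.lm(
          par = start, lower = bb$lower, upper = bb$upper,
          fn = function(r) y - pmin(1, pmax(0, fam$eval(fam$raw2canon(r), x))),
          control = minpack.lm::nls.lm.control(maxiter = 200))
        m <- mf(f, fam$raw2canon(res$par), domain)
        sse <- sum((y - eval_mf(m, x))^2)
        if (is.null(fam_best) || sse < attr(fam_best, "sse"))
          fam_best <- structure(m, sse = sse)
      }
      fam_best
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      report[f] <- attr(fit, "sse")
      if (is.null(best) || attr(fit, "sse") < attr(best, "sse")) best <- fit
    }
  }
  if (is.null(best))
    stop("membership fit failed in every family tried: ",
         paste(families, collapse = ", "))
  attr(best, "fit_report") <- report
  best
}

#' Chest-film membership functions
#'
#' Five generalized bell functions over \[0, 4\], centered at 0–4
#' consolidated quadrants. With the default width 0.5 and slope exponent 3,
#' adjacent bells both have degree 0.5 at the midpoint between their
#' centers, so e.g. 1.5 quadrants belongs partly to "one" and partly to
#' "two" consolidations.
#'
#' @param width Bell half-width `a` (> 0).
#' @param slope Bell slope exponent `b` (> 0).
#' @return List of 5 `mf` objects named `"0"`..`"4"`.
#' @export
chest_film_mfs <- function(width = 0.5, slope = 3) {
  if (!is.finite(width) || width <= 0 || !is.finite(slope) || slope <= 0)
    stop("`width` and `slope` must be positive")
  out <- lapply(0:4, function(k)
    mf("gbellmf", c(a = width, b = slope, c = k), c(0, 4)))
  names(out) <- as.character(0:4)
  out
}

#' Serialize membership functions to and from JSON
#'
#' @param x An `mf` object (or, internally, lists of them).
#' @return `mf_to_json()`: a JSON string; `mf_from_json()`: the `mf`.
#' @export
mf_to_json <- function(x) {
  stopifnot(inherits(x, "mf"))
  jsonlite::toJSON(list(family = x$family, params = as.list(x$params),
                        domain = x$domain),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname mf_to_json
#' @param json JSON string produced by `mf_to_json()`.
#' @export
mf_from_json <- function(json) {
  d <- jsonlite::fromJSON(json)
  mf(d$family, unlist(d$params), d$domain)
}
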