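#' Default per-variable value lists for the hypothetical-patient grid
#'
#' Reconstructs the factorial evaluation grid: for each continuous variable
#' the list contains every Murray band's center (`(lo + hi) / 2` of the
#' configured bands) plus a flanking pair at `frontier +/- delta` around
#' each of the four interior band frontiers; the film list is 0..4. Lists
#' shorter than their declared length are padded by deterministic greedy
#' gap bisection: the midpoint of the currently widest gap (domain
#' endpoints included as gap bounds) is inserted repeatedly, ties going to
#' the leftmost gap. With the defaults this yields 18 PaO2/FiO2 values, 18
#' compliance values and 13 PEEP values (5 centers + 4 flank pairs exactly).
#'
#' @param bands A `murray_bands` table.
#' @param delta Named flank offsets per variable, domain units.
#' @param lengths Named target list lengths.
#' @return Named list of sorted numeric value vectors (`pf`, `compliance`,
#'   `peep`, `film`).
#' @examples
#' lists <- murray_value_lists()
#' lengths(lists)          # 18 18 13 5
#' 137 %in% lists$pf       # TRUE: center of the 100-174 band
#' @export
murray_value_lists <- function(bands = murray_bands(),
                               delta = c(pf = 1, compliance = 1, peep = 0.5),
                               lengths = c(pf = 18L, compliance = 18L,
                                           peep = 13L, film = 5L)) {
  .validate_bands(bands)
  out <- list()
  for (v in c("pf", "compliance", "peep")) {
    b <- bands[[v]]
    centers <- (b$lo + b$hi) / 2
    frontiers <- b$lo[-1]
    vals <- sort(c(centers, frontiers - delta[[v]], frontiers + delta[[v]]))
    if (anyDuplicated(vals))
      stop("duplicate values in the '", v, "' list after assembly")
    dom <- .band_domain(bands, v)
    while (length(vals) < lengths[[v]]) {
      gaps <- diff(c(dom[1], vals, dom[2]))
      g <- which.max(gaps)                       # ties -> leftmost
      ends <- c(dom[1], vals, dom[2])[c(g, g + 1L)]
      vals <- sort(c(vals, mean(ends)))
    }
    if (length(vals) != lengths[[v]])
      stop(sprintf("cannot reach %d values for '%s' (have %d)",
                   lengths[[v]], v, length(vals)))
    out[[v]] <- vals
  }
  out$film <- as.numeric(seq_len(lengths[["film"]]) - 1L)
  out
}

#' Full factorial quadruplet grid
#'
#' Cartesian product of the four value lists, with PaO2/FiO2 varying
#' slowest and the chest film fastest.
#'
#' @param lists Named list of value vectors, see [murray_value_lists()].
#' @return Data frame of quadruplets with `length(pf) * length(compliance)
#'   * length(peep) * length(film)` rows.
#' @examples
#' nrow(quadruplet_grid(murray_value_lists()))   # 21060
#' @export
quadruplet_grid <- function(lists = murray_value_lists()) {
  need <- c("pf", "compliance", "peep", "film")
  if (!all(need %in% names(lists)) || any(lengths(lists[need]) == 0L))
    stop("all four value lists must be present and non-empty")
  g <- expand.grid(film = lists$film, peep = lists$peep,
                   compliance = lists$compliance, pf = lists$pf,
                   KEEP.OUT.ATTRS = FALSE)
  g[, need]
}

#' Default grid exclusion predicates
#'
#' Extreme combinations that a real patient could never present, dismissed
#' from the evaluation grid: (1) a fully normal gas exchange
#' (PaO2/FiO2 = 450) together with all four quadrants consolidated;
#' (2) a severely impaired gas exchange (PaO2/FiO2 <= 137) with an almost
#' clear film (0 or 1 quadrants). Predicates are pure functions from a
#' quadruplet data frame to a logical vector; matching rows are removed.
#'
#' @return Named list of predicate functions.
#' @export
default_exclusions <- function() {
  list(
    normal_pf_full_film = function(q) q$pf == 450 & q$film == 4,
    low_pf_clear_film = function(q) q$pf <= 137 & q$film %in% c(0, 1)
  )
}

#' Apply exclusion predicates to a quadruplet grid
#'
#' @param grid Quadruplet data frame.
#' @param predicates List of predicate functions; rows matching any are
#'   removed.
#' @return The retained rows, with attributes `n_before` and `n_removed`.
#' @examples
#' g <- quadruplet_grid()
#' kept <- apply_exclusions(g)
#' attr(kept, "n_removed")
#' @export
apply_exclusions <- function(grid, predicates = default_exclusions()) {
  drop <- rep(FALSE, nrow(grid))
  for (p in predicates) drop <- drop | p(grid)
  kept <- grid[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "n_before") <- nrow(grid)
  attr(kept, "n_removed") <- sum(drop)
  kept
}
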