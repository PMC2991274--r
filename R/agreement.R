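#' Survey-minus-Murray level differences
#'
#' Elementwise difference of the two severity-level vectors: the FIS
#' ("survey") level S and the crisp Murray level M, each in 0–3, so the
#' difference lies in -3..3. Positive values mean the survey grades the
#' case as more severe than the Murray equation.
#'
#' @param S,M Integer severity-level vectors of equal length, values 0–3.
#' @return Integer vector `S - M`.
#' @export
diff_vector <- function(S, M) {
  if (length(S) != length(M)) stop("S and M must have equal length")
  if (any(!S %in% 0:3) || any(!M %in% 0:3))
    stop("severity levels must be integers in 0..3")
  as.integer(S) - as.integer(M)
}

#' Summary of the level-difference distribution
#'
#' Histogram over -3..3, proportions, the weighted mean and population
#' standard deviation of the differences, a normal-approximation 95%
#' confidence interval for the mean, and the signed mean over the
#' disagreements only (`d != 0`).
#'
#' @param d Integer difference vector, values in -3..3.
#' @return Object of class `diff_summary`: `histogram` (named counts),
#'   `proportions`, `n`, `mean`, `sd` (population SD), `ci95`,
#'   `disagreement_mean`.
#' @export
diff_summary <- function(d) {
  if (length(d) == 0L) stop("empty difference vector")
  if (any(!d %in% -3:3)) stop("differences must lie in -3..3")
  n <- length(d)
  h <- table(factor(d, levels = -3:3))
  m <- mean(d)
  s <- sqrt(mean((d - m)^2))
  ci <- m + c(-1, 1) * 1.96 * s / sqrt(n)
  dm <- if (any(d != 0)) mean(d[d != 0]) else NA_real_
  structure(list(histogram = h, proportions = as.numeric(h) / n, n = n,
                 mean = m, sd = s, ci95 = ci, disagreement_mean = dm),
            class = "diff_summary")
}

#' @export
print.diff_summary <- function(x, ...) {
  cat(sprintf("<diff_summary> n = %d\n", x$n))
  print(x$histogram)
  cat(sprintf("  mean %.3f +/- %.3f (SD), 95%% CI %.3f - %.3f\n",
              x$mean, x$sd, x$ci95[1], x$ci95[2]))
  if (!is.na(x$disagreement_mean))
    cat(sprintf("  mean over disagreements: %.3f\n", x$disagreement_mean))
  invisible(x)
}

#' Survey-versus-Murray contingency table
#'
#' 4x4 count matrix, rows = survey (FIS) level 0–3, columns = Murray level
#' 0–3.
#'
#' @param S,M Severity-level vectors as in [diff_vector()].
#' @return Object of class `agreement_table` (an integer matrix with a
#'   grand total attribute `n`).
#' @export
contingency_table <- function(S, M) {
  if (length(S) != length(M)) stop("S and M must have equal length")
  tab <- table(factor(S, levels = 0:3), factor(M, levels = 0:3))
  m <- matrix(as.integer(tab), 4, 4,
              dimnames = list(survey = 0:3, murray = 0:3))
  as_agreement_table(m)
}

#' @rdname contingency_table
#' @param counts A 4x4 (or, for collapsed tables, kxk) nonnegative integer
#'   matrix.
#' @export
as_agreement_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("agreement table must be square")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("agreement table cells must be nonnegative integers")
  structure(counts, n = sum(counts), class = c("agreement_table", "matrix"))
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf("<agreement_table> n = %d (rows: survey, cols: Murray)\n",
              attr(x, "n")))
  print(unclass(x))
  invisible(x)
}

#' Cohen's kappa for an agreement table
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with the
#' asymptotic (delta-method) standard error of Fleiss, Cohen and Everitt
#' and a normal 95% confidence interval.
#'
#' @param table An `agreement_table` (or square count matrix).
#' @return Object of class `kappa_result`: `kappa`, `se`, `ci95`, `po`,
#'   `pe`, `n`.
#' @export
cohen_kappa <- function(table) {
  tab <- as_agreement_table(table)
  n <- attr(tab, "n")
  if (n <= 0) stop("empty agreement table")
  p <- unclass(tab) / n
  po <- sum(diag(p))
  pr <- rowSums(p)
  pc <- colSums(p)
  pe <- sum(pr * pc)
  if (pe >= 1) stop("kappa undefined: chance agreement is 1")
  k <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt asymptotic variance of kappa-hat
  A <- sum(diag(p) * (1 - (pr + pc) * (1 - k))^2)
  off <- outer(pc, pr, "+")^2 * p         # element [i,j]: p_ij (pc_i + pr_j)^2
  B <- (1 - k)^2 * (sum(off) - sum(diag(off)))
  C <- (k - pe * (1 - k))^2
  se <- sqrt(max(A + B - C, 0) / (n * (1 - pe)^2))
  structure(list(kappa = k, se = se, ci95 = k + c(-1, 1) * 1.96 * se,
                 po = po, pe = pe, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa %.4f +/- %.4f (SE), 95%% CI %.4f - %.4f\n",
              x$kappa, x$se, x$ci95[1], x$ci95[2]))
  cat(sprintf("  observed agreement %.4f, chance agreement %.4f, n = %d\n",
              x$po, x$pe, x$n))
  invisible(x)
}

#' Collapse an agreement table to ARDS versus the rest
#'
#' Merges severity levels 0–2 into a single "non-ARDS" category against
#' level 3 (ARDS), conserving the grand total.
#'
#' @param table A 4x4 `agreement_table`.
#' @return A 2x2 `agreement_table` with dimnames `non-ARDS` / `ARDS`.
#' @export
collapse_ards <- function(table) {
  tab <- unclass(as_agreement_table(table))
  if (!all(dim(tab) == c(4L, 4L))) stop("expected a 4x4 table")
  m <- matrix(c(sum(tab[1:3, 1:3]), sum(tab[4, 1:3]),
                sum(tab[1:3, 4]), sum(tab[4, 4])), 2, 2,
              dimnames = list(survey = c("non-ARDS", "ARDS"),
                              murray = c("non-ARDS", "ARDS")))
  as_agreement_table(m)
}

#' Band-wise discrepancy analysis
#'
#' For each Murray severity level 1–3, each variable and each of its Murray
#' bands: how many Murray-level cases fall in that band, how many of those
#' the survey also grades at that level (match), how many it pushes one
#' level up (migration), and the discrepancy proportion
#' `migrated / band count`. Under total coincidence every discrepancy
#' proportion is 0 (the curve is flat). Empty band strata report `NA`
#' proportions rather than erroring.
#'
#' @param grid Quadruplet data frame, aligned with `S` and `M`.
#' @param S,M Severity-level vectors.
#' @param bands A `murray_bands` table.
#' @return Long data frame: `severity`, `variable`, `band_score`, `n`
#'   (Murray-level cases in the band), `match`, `migrate`, `other`,
#'   `discrepancy`.
#' @export
band_discrepancy <- function(grid, S, M, bands = murray_bands()) {
  if (nrow(grid) != length(S) || length(S) != length(M))
    stop("grid, S and M must be aligned")
  rows <- list()
  for (lev in 1:3) {
    sel <- M == lev
    for (v in c("pf", "compliance", "peep", "film")) {
      comp <- murray_component(v, grid[[v]], bands)
      for (b in 0:4) {
        i <- sel & comp == b
        n <- sum(i)
        mt <- sum(S[i] == lev)
        mg <- if (lev < 3L) sum(S[i] == lev + 1L) else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          severity = lev, variable = v, band_score = b, n = n,
          match = mt, migrate = mg, other = n - mt - mg,
          discrepancy = if (n > 0) mg / n else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled two-proportion z-test
#'
#' Classic two-sided z-test for `k1/n1` versus `k2/n2` with the pooled
#' variance estimate. When the pooled proportion is degenerate (0 or 1)
#' both samples are constant and identical in rate, so `z = 0`, `p = 1` is
#' reported with `degenerate = TRUE`.
#'
#' @param k1,n1,k2,n2 Successes and totals of the two samples.
#' @return List: `z`, `p`, `p1`, `p2`, `degenerate`.
#' @examples
#' two_prop_test(60, 100, 40, 100)$z   # ~2.83
#' @export
two_prop_test <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2)
    stop("need 0 <= k <= n and n >= 1 in both samples")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  if (pp <= 0 || pp >= 1)
    return(list(z = 0, p = 1, p1 = p1, p2 = p2, degenerate = TRUE))
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2,
       degenerate = FALSE)
}

#' Full agreement analysis between survey and Murray levels
#'
#' Convenience wrapper computing the difference summary, the contingency
#' table, both kappa analyses (full 4x4 and collapsed ARDS-versus-rest)
#' and, when the grid is given, the band-wise discrepancy table.
#'
#' @param S,M Severity-level vectors.
#' @param grid Optional aligned quadruplet data frame for the band
#'   analysis.
#' @param bands A `murray_bands` table.
#' @return Object of class `severity_agreement`.
#' @export
severity_agreement <- function(S, M, grid = NULL, bands = murray_bands()) {
  tab <- contingency_table(S, M)
  structure(list(
    table = tab,
    diff = diff_summary(diff_vector(S, M)),
    kappa = cohen_kappa(tab),
    kappa_ards = cohen_kappa(collapse_ards(tab)),
    bands = if (!is.null(grid)) band_discrepancy(grid, S, M, bands)
  ), class = "severity_agreement")
}

#' @export
print.severity_agreement <- function(x, ...) {
  print(x$table)
  cat(sprintf("agreement %.1f%%, one-level overestimation %.1f%%\n",
              100 * sum(diag(unclass(x$table))) / attr(x$table, "n"),
              100 * sum(x$diff$histogram[c("1")]) / x$diff$n))
  cat("overall: "); print(x$kappa)
  cat("ARDS vs rest: "); print(x$kappa_ards)
  invisible(x)
}
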