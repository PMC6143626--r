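#' Closed-form direct-bias adoption probability
#'
#' The probability that a randomly chosen individual ends up demonstrating
#' variant A after one observation round, when the preferred variant is
#' always copied on exposure and the less-preferred one with probability
#' `q`:
#'
#' `Prob(A) = p * (p + r (1 - p) (1 - q)) + (1 - p) * (r p + (1 - r) p q)`
#'
#' where `p` is the frequency of variant A and `r` the fraction of
#' individuals preferring A. The first term is the probability that the
#' observer initially exhibits A and continues to do so; the second that it
#' initially exhibits B but switches. Special cases: `r = 0.5` or `q = 1`
#' give the identity line; `r = 1, q < 1` the concave ("r-shaped")
#' direct-bias curve; `r = 0, q < 1` its convex mirror.
#'
#' @param p Frequency of variant A, in \[0, 1\] (vectorized).
#' @param q Probability of copying the less-preferred variant, in \[0, 1\].
#' @param r Fraction of individuals preferring A, in \[0, 1\].
#' @return Adoption probability, same length as the recycled arguments.
#' @export
prob_adopt_a <- function(p, q, r) {
  for (nm in c("p", "q", "r")) {
    v <- get(nm)
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 1)) {
      stop("domain error: ", nm, " must lie in [0, 1]")
    }
  }
  p * (p + r * (1 - p) * (1 - q)) + (1 - p) * (r * p + (1 - r) * p * q)
}

#' Regime-union artefact curve
#'
#' The piecewise curve produced by pooling runs that only ever visit one
#' half of the frequency range: below p = 0.5 all data come from
#' B-preferring populations (`r = 0`), above from A-preferring ones
#' (`r = 1`). At p = 0.5 both branch values are reported. With `q = 1` the
#' bias vanishes and both branches collapse to the identity line.
#'
#' @param q Less-preferred copying probability.
#' @param grid Frequencies at which to evaluate (default 0..1 by 0.001).
#' @return Data frame with columns `p`, `r` (the branch) and `prob`.
#' @export
regime_union_curve <- function(q, grid = seq(0, 1, by = 0.001)) {
  if (any(grid < 0 | grid > 1)) stop("grid must lie in [0, 1]")
  grid <- sort(grid)
  lo <- grid[grid < 0.5]
  hi <- grid[grid > 0.5]
  mid <- grid[grid == 0.5]
  p <- c(lo, rep(mid, 2L), hi)
  r <- c(rep(0, length(lo)), rep(0, length(mid)), rep(1, length(mid)),
         rep(1, length(hi)))
  data.frame(p = p, r = r, prob = prob_adopt_a(p, q, r))
}

#' Weighted mixture of two component lines
#'
#' Evaluates `y3(x) = w(x) * b1 * x + (1 - w(x)) * b2 * x`, the weighted
#' average of the slope-`b1` and slope-`b2` adoption lines. With weights
#' taken from the relative per-bin event densities of the two preference
#' strata this reconstructs the concave-up pooled curve of the
#' uniform-start variant-preference simulation.
#'
#' @param b1,b2 Component slopes (defaults 1 and 0.2).
#' @param w Weight on the `b1` line: a function of x, or a numeric vector
#'   aligned with `grid` (values in \[0, 1\]; NA allowed where no events
#'   exist).
#' @param grid Frequencies at which to evaluate.
#' @return Data frame with columns `x`, `w`, `y`.
#' @export
mixture_of_lines <- function(b1 = 1, b2 = 0.2, w = function(x) 0.5,
                             grid = seq(0, 1, by = 0.001)) {
  wv <- if (is.function(w)) w(grid) else rep_len(as.numeric(w), length(grid))
  ok <- !is.na(wv)
  if (any(wv[ok] < 0 | wv[ok] > 1)) {
    stop("domain error: weights must lie in [0, 1]")
  }
  data.frame(x = grid, w = wv, y = wv * b1 * grid + (1 - wv) * b2 * grid)
}

#' Empirical mixture weights from two stratified curves
#'
#' Per-bin weight of the first stratum: its counted events divided by the
#' two strata's total, `NA` where neither stratum has events. Curves must
#' share a binning.
#'
#' @param curve1,curve2 Two [build_curve()] results on the same bins.
#' @return Data frame with `bin_centre` and `w`.
#' @export
mixture_weights_from_curves <- function(curve1, curve2) {
  stopifnot(nrow(curve1) == nrow(curve2),
            isTRUE(all.equal(curve1$bin_centre, curve2$bin_centre)))
  tot <- curve1$counted + curve2$counted
  data.frame(bin_centre = curve1$bin_centre,
             w = ifelse(tot > 0L, curve1$counted / tot, NA_real_))
}
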