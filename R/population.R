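#' Construct a population state
#'
#' A population state holds the current behavioural variant ("A" or "B") of
#' each of `n` individuals, together with the attributes some learning rules
#' need: a shared preferred variant (variant-preference rule) and a fixed
#' demonstrator subgroup (demonstrator-subgroup rule). Individuals are
#' indexed 1..n.
#'
#' @param variants Character vector of "A"/"B" labels, one per individual.
#' @param preferred_variant "A", "B", or `NA` (no shared preference).
#' @param subgroup_ids Integer indices of the demonstrator subgroup
#'   (possibly empty). Must be a subset of `1:length(variants)`.
#' @return An object of class `population_state`: a list with elements
#'   `variants`, `preferred_variant`, `subgroup_ids`, `n_individuals`.
#' @seealso [init_population()]
#' @export
population_state <- function(variants, preferred_variant = NA_character_,
                             subgroup_ids = integer(0)) {
  variants <- as.character(variants)
  if (length(variants) < 2L) {
    stop("invalid population: need at least 2 individuals, got ",
         length(variants))
  }
  if (!all(variants %in% c("A", "B"))) {
    stop("invalid population: variants must all be \"A\" or \"B\"")
  }
  if (!is.na(preferred_variant) && !preferred_variant %in% c("A", "B")) {
    stop("preferred_variant must be \"A\", \"B\" or NA")
  }
  subgroup_ids <- sort(unique(as.integer(subgroup_ids)))
  n <- length(variants)
  if (length(subgroup_ids) &&
      (min(subgroup_ids) < 1L || max(subgroup_ids) > n)) {
    stop("subgroup_ids must be indices in 1..", n)
  }
  structure(
    list(variants = variants,
         preferred_variant = as.character(preferred_variant),
         subgroup_ids = subgroup_ids,
         n_individuals = n),
    class = "population_state"
  )
}

#' Initialize a two-variant population
#'
#' @param n Number of individuals (>= 2).
#' @param p0 Initial probability (or, in `exact_round` mode, proportion) of
#'   variant "A".
#' @param mode `"binomial"`: each individual is independently "A" with
#'   probability `p0` (the stochastic "approximately 50%" convention).
#'   `"exact_round"`: exactly `round(n * p0)` individuals are "A", at
#'   randomized positions.
#' @param preferred_variant,subgroup_ids Passed to [population_state()].
#' @return A [population_state()].
#' @examples
#' set.seed(1)
#' init_population(100, 0.5)
#' @export
init_population <- function(n, p0, mode = c("binomial", "exact_round"),
                            preferred_variant = NA_character_,
                            subgroup_ids = integer(0)) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("invalid population: n must be >= 2")
  if (!is.numeric(p0) || is.na(p0) || p0 < 0 || p0 > 1) {
    stop("p0 must be a probability in [0, 1]")
  }
  is_a <- switch(mode,
    binomial = stats::rbinom(n, 1L, p0) == 1L,
    exact_round = {
      k <- as.integer(round(n * p0))
      pos <- logical(n)
      if (k > 0L) pos[sample.int(n, k)] <- TRUE
      pos
    }
  )
  population_state(ifelse(is_a, "A", "B"),
                   preferred_variant = preferred_variant,
                   subgroup_ids = subgroup_ids)
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> n =", x$n_individuals,
      "| freq(A) =", format(mean(x$variants == "A"), digits = 4), "\n")
  if (!is.na(x$preferred_variant)) {
    cat("  preferred variant:", x$preferred_variant, "\n")
  }
  if (length(x$subgroup_ids)) {
    cat("  demonstrator subgroup (Dm =", length(x$subgroup_ids), "):",
        paste(utils::head(x$subgroup_ids, 10L), collapse = " "),
        if (length(x$subgroup_ids) > 10L) "..." else "", "\n")
  }
  invisible(x)
}
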