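#' Learning-rule configuration
#'
#' Bundles a copying rule with its parameters.
#'
#' Rules:
#' \describe{
#'   \item{random_copy}{Copy a uniformly chosen demonstrator's variant,
#'     always. The neutral baseline.}
#'   \item{variant_preference}{A direct bias: the shared preferred variant
#'     is always copied on exposure; the less-preferred variant is copied
#'     with probability `p_less`.}
#'   \item{demonstrator_subgroup}{A model bias: demonstrators are drawn only
#'     from a fixed subgroup of size `dm`; their variant is always copied.
#'     Subgroup members, when focal, also copy from the subgroup.}
#'   \item{conformist_reference}{A genuinely conformist positive control:
#'     sample `conformist_sample` distinct demonstrators and adopt the
#'     majority variant among them. Not one of the rules under scrutiny;
#'     included so the detection machinery can be shown to flag true
#'     conformity.}
#' }
#'
#' @param rule One of `"random_copy"`, `"variant_preference"`,
#'   `"demonstrator_subgroup"`, `"conformist_reference"`.
#' @param p_less Probability of copying the less-preferred variant on
#'   exposure (the pLess/q parameter), in \[0, 1\].
#' @param dm Demonstrator-subgroup size (>= 1).
#' @param conformist_sample Odd number (>= 3) of demonstrators sampled by
#'   the conformist reference rule.
#' @param allow_self_as_demonstrator If `TRUE`, individuals may draw
#'   themselves as demonstrators (off by default; self-copying confounds
#'   social learning and is exposed only as a replication switch).
#' @return An object of class `rule_config`.
#' @export
rule_config <- function(rule = c("random_copy", "variant_preference",
                                 "demonstrator_subgroup",
                                 "conformist_reference"),
                        p_less = 0.2, dm = 5L, conformist_sample = 3L,
                        allow_self_as_demonstrator = FALSE) {
  rule <- match.arg(rule)
  if (!is.numeric(p_less) || is.na(p_less) || p_less < 0 || p_less > 1) {
    stop("p_less must be in [0, 1]")
  }
  dm <- as.integer(dm)
  if (is.na(dm) || dm < 1L) stop("dm must be an integer >= 1")
  conformist_sample <- as.integer(conformist_sample)
  if (is.na(conformist_sample) || conformist_sample < 3L ||
      conformist_sample %% 2L == 0L) {
    stop("conformist_sample must be an odd integer >= 3")
  }
  structure(
    list(rule = rule, p_less = p_less, dm = dm,
         conformist_sample = conformist_sample,
         allow_self_as_demonstrator = isTRUE(allow_self_as_demonstrator)),
    class = "rule_config"
  )
}

#' Select a demonstrator for one copying event
#'
#' Under the whole-population rules the demonstrator is uniform over all
#' individuals (excluding the focal unless self-copying is allowed); under
#' the demonstrator-subgroup rule it is uniform over the subgroup (minus the
#' focal if it is a member and self-copying is disallowed).
#'
#' @param state A [population_state()].
#' @param focal Index of the focal individual.
#' @param config A [rule_config()].
#' @return A demonstrator index, or `NA_integer_` when the candidate set is
#'   empty (the no-demonstrator signal; such an event records no change).
#' @export
select_demonstrator <- function(state, focal, config) {
  n <- state$n_individuals
  focal <- as.integer(focal)
  if (is.na(focal) || focal < 1L || focal > n) stop("focal index out of range")
  candidates <- if (config$rule == "demonstrator_subgroup") {
    if (!length(state$subgroup_ids)) {
      stop("demonstrator_subgroup rule needs a nonempty subgroup in the state")
    }
    state$subgroup_ids
  } else {
    seq_len(n)
  }
  if (!config$allow_self_as_demonstrator) {
    candidates <- candidates[candidates != focal]
  }
  if (!length(candidates)) return(NA_integer_)
  candidates[sample.int(length(candidates), 1L)]
}

#' Apply a learning rule to one focal/demonstrator pairing
#'
#' @param focal_variant,demo_variant "A" or "B".
#' @param config A [rule_config()].
#' @param preferred_variant The population's shared preferred variant
#'   (required for the variant-preference rule).
#' @return A list with `new_variant` ("A"/"B") and `copy_succeeded`
#'   (logical). Under random copying, the subgroup rule and the conformist
#'   reference the demonstrated variant is always copied; under variant
#'   preference the preferred variant is copied with probability 1 and the
#'   less-preferred one with probability `p_less` (on failure the focal
#'   retains its variant).
#' @export
apply_rule <- function(focal_variant, demo_variant, config,
                       preferred_variant = NA_character_) {
  stopifnot(focal_variant %in% c("A", "B"), demo_variant %in% c("A", "B"))
  succeeded <- switch(config$rule,
    variant_preference = {
      if (is.na(preferred_variant)) {
        stop("variant_preference rule needs preferred_variant")
      }
      demo_variant == preferred_variant || stats::runif(1L) < config$p_less
    },
    TRUE
  )
  list(new_variant = if (succeeded) demo_variant else focal_variant,
       copy_succeeded = succeeded)
}
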