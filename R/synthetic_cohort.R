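#' Recipe for a synthetic patient cohort
#'
#' Marginal probabilities default to the baseline characteristics of the
#' emulated cohort (sex, smoking, metastatic-site prevalences, mutation
#' mix, treatment-line distributions); the outcome is drawn from a
#' logistic model: baseline odds times the recipe's per-attribute odds
#' multipliers for each attribute the patient carries.
#'
#' @param n_patients cohort size.
#' @param effects named list of odds multipliers on the outcome. For a
#'   logical attribute the multiplier applies when it is `TRUE`; for a
#'   categorical attribute supply a named vector of per-level multipliers.
#' @param baseline_p outcome probability for a patient with no effect
#'   attributes (default 0.4, the emulated cohort's overall T790M rate).
#' @param marginals optional overrides for the attribute marginals (see
#'   defaults in the function body).
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return A list of class `CohortRecipe`.
#' @export
cohort_recipe <- function(n_patients = 68L, effects = list(),
                          baseline_p = 0.4, marginals = list(),
                          seed = 1L) {
  stopifnot(n_patients >= 0L, baseline_p >= 0, baseline_p <= 1)
  defaults <- list(
    age_mean = 66, age_sd = 9, age_range = c(40, 90),
    p_male = 0.21,
    p_smoking = c(never = 0.85, chronic = 0.03, ex = 0.12),
    p_sites = c(lung_met = 0.87, pleural_met = 0.44, brain_met = 0.22,
                liver_met = 0.16, bone_met = 0.50, distant_ln_met = 0.26),
    p_mutation = c(exon19_LRE_delE746_A750 = 0.456,
                   exon19_LRE_other = 0.044,
                   exon19_nonLRE = 0.044,
                   L858R = 0.456),
    p_lines_tki = c("1" = 0.78, "2" = 0.18, "3" = 0.04),
    p_lines_chemo = c("0" = 0.65, "1" = 0.23, "2" = 0.09, "3" = 0.03),
    p_first_tki = c(gefitinib = 0.79, erlotinib = 0.105, afatinib = 0.105)
  )
  defaults[names(marginals)] <- marginals
  structure(list(n_patients = as.integer(n_patients), effects = effects,
                 baseline_p = baseline_p, marginals = defaults,
                 seed = as.integer(seed)),
            class = "CohortRecipe")
}

#' Generate a synthetic patient cohort
#'
#' Attributes are drawn independently from the recipe marginals, except
#' that the six age-threshold booleans derive from one latent age draw
#' (preserving their monotonicity), `number_sites_met` is the count of
#' drawn metastatic sites (coerced to at least one site), and treatment
#' usage flags derive from the drawn line counts. The outcome follows the
#' recipe's logistic model.
#'
#' @param recipe a [cohort_recipe()].
#' @return A validated cohort `data.frame` of `n_patients` rows (empty
#'   `data.frame` with the right columns when `n_patients = 0`).
#' @export
generate_cohort <- function(recipe) {
  stopifnot(inherits(recipe, "CohortRecipe"))
  n <- recipe$n_patients
  m <- recipe$marginals
  withr_seed(recipe$seed, {
    age <- pmin(pmax(round(stats::rnorm(n, m$age_mean, m$age_sd)),
                     m$age_range[1L]), m$age_range[2L])
    df <- data.frame(row.names = seq_len(n))
    for (thr in c(55, 60, 65, 70, 75, 80)) {
      df[[paste0("age_", thr)]] <- age >= thr
    }
    df$sex <- ifelse(stats::runif(n) < m$p_male, "male", "female")
    df$smoking <- sample_levels(n, m$p_smoking)
    for (s in names(m$p_sites)) {
      df[[s]] <- stats::runif(n) < m$p_sites[[s]]
    }
    none <- rowSums(df[, SITE_COLS, drop = FALSE]) == 0
    df$lung_met[none] <- TRUE
    # the site-count attribute is capped at 5 levels; a rare draw of all
    # six sites sheds the least prevalent one
    all6 <- rowSums(df[, SITE_COLS, drop = FALSE]) == 6
    df$liver_met[all6] <- FALSE
    df$number_sites_met <- as.integer(
      rowSums(df[, SITE_COLS, drop = FALSE]))
    df$initial_egfr_mutation <- sample_levels(n, m$p_mutation)
    df$number_lines_tki <- as.integer(sample_levels(n, m$p_lines_tki))
    df$number_lines_chemo <- as.integer(sample_levels(n, m$p_lines_chemo))
    df$first_tki <- sample_levels(n, m$p_first_tki)
    df$second_tki_used <- df$number_lines_tki >= 2L
    df$third_tki_used <- df$number_lines_tki >= 3L
    df$first_chemo_used <- df$number_lines_chemo >= 1L
    df$second_chemo_used <- df$number_lines_chemo >= 2L
    df$third_chemo_used <- df$number_lines_chemo >= 3L

    logit <- stats::qlogis(recipe$baseline_p)
    eta <- rep(logit, n)
    for (a in names(recipe$effects)) {
      eff <- recipe$effects[[a]]
      v <- df[[a]]
      if (is.null(v)) stop("effect on unknown attribute: ", a,
                           call. = FALSE)
      if (is.logical(v)) {
        eta <- eta + log(eff) * v
      } else {
        mult <- eff[as.character(v)]
        mult[is.na(mult)] <- 1
        eta <- eta + log(mult)
      }
    }
    df$t790m <- stats::runif(n) < stats::plogis(eta)
    rownames(df) <- NULL
    df <- df[, c(COHORT_ATTRIBUTES, "t790m"), drop = FALSE]
    if (n == 0L) df else validate_cohort(df)
  })
}

sample_levels <- function(n, probs) {
  if (n == 0L) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}
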