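# Shannon entropy in bits of a categorical vector
entropy_bits <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of an attribute about the outcome
#'
#' `H(outcome) - H(outcome | attribute)`, in bits, on categorical
#' encodings. A constant attribute scores 0; an attribute identical to the
#' outcome scores `H(outcome)`.
#'
#' @param attr,outcome equal-length vectors, treated as categorical.
#' @return Information gain in bits (>= 0 up to floating point).
#' @export
info_gain <- function(attr, outcome) {
  attr <- as.character(attr)
  h <- entropy_bits(outcome)
  cond <- 0
  for (v in unique(attr)) {
    sel <- attr == v
    cond <- cond + mean(sel) * entropy_bits(outcome[sel])
  }
  max(0, h - cond)
}

#' Symmetrical uncertainty of an attribute and the outcome
#'
#' `2 IG / (H(attribute) + H(outcome))`, a normalisation of information
#' gain to `[0, 1]`; 0 when either variable is constant.
#'
#' @inheritParams info_gain
#' @return Symmetrical uncertainty in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(attr, outcome) {
  denom <- entropy_bits(as.character(attr)) + entropy_bits(outcome)
  if (denom == 0) return(0)
  min(1, 2 * info_gain(attr, outcome) / denom)
}

# Pearson chi-squared statistic of the attribute x outcome table;
# degenerate (single-level) tables score 0
chi2_score <- function(attr, outcome) {
  tab <- table(as.character(attr), as.character(outcome))
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  unname(suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic))
}

# mean absolute Pearson correlation between the one-hot (indicator)
# encodings of the attribute levels and the binary outcome; a two-level
# attribute reduces to the single |r| of its indicator
correlation_score <- function(attr, outcome) {
  attr <- as.character(attr)
  y <- as.numeric(factor(outcome)) - 1
  if (stats::sd(y) == 0) return(0)
  levels <- unique(attr)
  if (length(levels) < 2L) return(0)
  if (length(levels) == 2L) levels <- levels[1L]
  r <- vapply(levels, function(v) {
    x <- as.numeric(attr == v)
    if (stats::sd(x) == 0) 0 else abs(stats::cor(x, y))
  }, 0)
  mean(r)
}

#' ReliefF scores for categorical attributes
#'
#' Kononenko's ReliefF with k nearest hits and misses under Hamming
#' distance on the categorical attribute encodings: for each probe
#' instance, each attribute is penalised for differing from the k nearest
#' same-class instances and rewarded, weighted by the prior of each other
#' class, for differing from that class's k nearest instances. All
#' instances are probed when `n <= exhaustive_limit`; larger cohorts probe
#' `m = exhaustive_limit` instances sampled without replacement under
#' `seed` (deterministic given the seed).
#'
#' @param data `data.frame` of categorical attributes.
#' @param outcome categorical outcome vector.
#' @param k number of neighbours per class (default 10).
#' @param exhaustive_limit probe-all threshold / sample size (default 1000).
#' @param seed RNG seed for the sampling branch.
#' @return Named numeric vector of attribute weights.
#' @export
relieff_scores <- function(data, outcome, k = 10L,
                           exhaustive_limit = 1000L, seed = 1L) {
  X <- vapply(data, function(col) as.integer(factor(as.character(col))),
              integer(nrow(data)))
  X <- matrix(X, nrow(data), ncol(data))
  Xt <- t(X)                       # p x n: column access per instance
  y <- as.character(outcome)
  n <- nrow(data)
  p <- ncol(data)
  classes <- sort(unique(y))
  prior <- vapply(classes, function(cl) mean(y == cl), 0)
  names(prior) <- classes
  probes <- if (n <= exhaustive_limit) seq_len(n) else {
    withr_seed(seed, sort(sample.int(n, exhaustive_limit)))
  }
  m <- length(probes)
  W <- numeric(p)
  class_idx <- split(seq_len(n), y)
  for (i in probes) {
    diffs <- Xt != Xt[, i]          # p x n attribute inequality
    d <- colSums(diffs)             # Hamming distances to every instance
    for (cl in classes) {
      cand <- class_idx[[cl]]
      cand <- cand[cand != i]
      if (length(cand) == 0L) next
      nb <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
      contrib <- rowSums(diffs[, nb, drop = FALSE]) /
        (m * length(nb))
      if (cl == y[i]) {
        W <- W - contrib
      } else {
        W <- W + prior[[cl]] / (1 - prior[[y[i]]]) * contrib
      }
    }
  }
  stats::setNames(W, names(data))
}

RANKING_EVALUATORS <- c("chi2", "info_gain", "symmetrical_uncertainty",
                        "correlation", "relieff", "filtered")

#' Rank attributes by association with the outcome
#'
#' Scores every ranking attribute with the chosen evaluator and sorts
#' descending (Ranker-style search: each attribute evaluated
#' individually). Evaluators: `chi2` (Pearson chi-squared statistic of the
#' attribute-by-outcome table), `info_gain` (bits), `symmetrical_uncertainty`,
#' `correlation` (mean absolute Pearson correlation on indicator
#' encodings), `relieff` (see [relieff_scores()]), and `filtered` —
#' information gain computed after the package's cohort validation filter,
#' the package's rendition of a filtered information-based evaluator.
#' Ties are broken by attribute name.
#'
#' @param cohort cohort `data.frame` ([load_cohort()] /
#'   [generate_cohort()]).
#' @param evaluator one of `"chi2"`, `"info_gain"`,
#'   `"symmetrical_uncertainty"`, `"correlation"`, `"relieff"`,
#'   `"filtered"`.
#' @param outcome outcome column name (default `"t790m"`); must take at
#'   least two levels.
#' @param attributes attribute columns to score (default: the 24 canonical
#'   ranking attributes present in the cohort).
#' @param relieff_k,seed ReliefF neighbour count and sampling seed.
#' @return A `data.frame` of class `AttributeRanking` with columns
#'   `attribute` and `score`, sorted by descending score; attribute
#'   `evaluator`.
#' @export
rank_attributes <- function(cohort,
                            evaluator = RANKING_EVALUATORS,
                            outcome = "t790m",
                            attributes = intersect(COHORT_ATTRIBUTES,
                                                   names(cohort)),
                            relieff_k = 10L, seed = 1L) {
  evaluator <- match.arg(evaluator)
  if (nrow(cohort) < 2L) stop("need at least 2 patients", call. = FALSE)
  y <- as.character(cohort[[outcome]])
  if (length(unique(y)) < 2L) {
    stop("outcome must take both levels", call. = FALSE)
  }
  if (evaluator == "filtered") {
    cohort <- validate_cohort(cohort)
    evaluator <- "info_gain"
    label <- "filtered"
  } else {
    label <- evaluator
  }
  scores <- switch(evaluator,
    chi2 = vapply(attributes, function(a) chi2_score(cohort[[a]], y), 0),
    info_gain = vapply(attributes,
                       function(a) info_gain(cohort[[a]], y), 0),
    symmetrical_uncertainty =
      vapply(attributes,
             function(a) symmetrical_uncertainty(cohort[[a]], y), 0),
    correlation = vapply(attributes,
                         function(a) correlation_score(cohort[[a]], y), 0),
    relieff = relieff_scores(cohort[, attributes, drop = FALSE], y,
                             k = relieff_k, seed = seed)
  )
  ord <- order(-scores, attributes)
  out <- data.frame(attribute = attributes[ord],
                    score = unname(scores[ord]), row.names = NULL)
  attr(out, "evaluator") <- label
  class(out) <- c("AttributeRanking", "data.frame")
  out
}
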