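# The 24 ranking attributes (clinical baseline + treatment modality),
# snake_case, in canonical order; the outcome column is `t790m`.
COHORT_ATTRIBUTES <- c(
  "age_55", "age_60", "age_65", "age_70", "age_75", "age_80",
  "sex", "smoking",
  "lung_met", "pleural_met", "brain_met", "liver_met", "bone_met",
  "distant_ln_met", "number_sites_met",
  "initial_egfr_mutation",
  "number_lines_tki", "number_lines_chemo",
  "first_tki", "second_tki_used", "third_tki_used",
  "first_chemo_used", "second_chemo_used", "third_chemo_used"
)

MUTATION_LEVELS <- c("exon19_LRE_delE746_A750", "exon19_LRE_other",
                     "exon19_nonLRE", "L858R")
TKI_LEVELS <- c("gefitinib", "erlotinib", "afatinib")
SMOKING_LEVELS <- c("never", "chronic", "ex")
SEX_LEVELS <- c("male", "female")

AGE_COLS <- paste0("age_", c(55, 60, 65, 70, 75, 80))
SITE_COLS <- c("lung_met", "pleural_met", "brain_met", "liver_met",
               "bone_met", "distant_ln_met")
BOOL_COLS <- c(AGE_COLS, SITE_COLS, "second_tki_used", "third_tki_used",
               "first_chemo_used", "second_chemo_used", "third_chemo_used",
               "t790m")

#' Load and validate a patient cohort table
#'
#' Reads a CSV whose header contains the 24 categorical ranking attributes
#' plus the binary `t790m` outcome (acquired-T790M status from liquid/tumor
#' re-biopsy). Additional columns (e.g. per-drug exposure flags) are kept
#' as-is. Validation enforces the record invariants: monotone
#' age-threshold booleans, known category levels, `number_sites_met` in
#' 1..5. All violations are reported together, each naming its row and
#' column.
#'
#' @param path CSV path.
#' @return A validated cohort `data.frame`.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Validate a cohort data frame in place
#' @param df cohort `data.frame` (see [load_cohort()] for the schema).
#' @return `df`, with boolean columns coerced to logical.
#' @export
validate_cohort <- function(df) {
  if (nrow(df) == 0L) stop("cohort is empty", call. = FALSE)
  missing_cols <- setdiff(c(COHORT_ATTRIBUTES, "t790m"), names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cl in intersect(BOOL_COLS, names(df))) {
    v <- df[[cl]]
    if (is.character(v)) v <- toupper(v) %in% c("TRUE", "T", "YES", "1")
    df[[cl]] <- as.logical(v)
  }
  problems <- character(0)
  bad_level <- function(col, levels) {
    bad <- which(!df[[col]] %in% levels)
    if (length(bad) > 0L) {
      problems <<- c(problems, paste0(
        "row ", bad, ", column ", col, ": unknown level '",
        df[[col]][bad], "'"))
    }
  }
  bad_level("sex", SEX_LEVELS)
  bad_level("smoking", SMOKING_LEVELS)
  bad_level("initial_egfr_mutation", MUTATION_LEVELS)
  bad_level("first_tki", TKI_LEVELS)
  for (i in seq_len(length(AGE_COLS) - 1L)) {
    lo <- AGE_COLS[i]; hi <- AGE_COLS[i + 1L]
    bad <- which(df[[hi]] & !df[[lo]])
    if (length(bad) > 0L) {
      problems <- c(problems, paste0(
        "row ", bad, ", column ", hi, ": TRUE requires ", lo, " TRUE ",
        "(age thresholds must be monotone)"))
    }
  }
  bad_n <- which(!df$number_sites_met %in% 1:5)
  if (length(bad_n) > 0L) {
    problems <- c(problems, paste0(
      "row ", bad_n, ", column number_sites_met: must be an integer 1..5"))
  }
  if (length(problems) > 0L) {
    stop("cohort validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  df
}

#' Contingency table of an attribute against the outcome
#'
#' @param cohort validated cohort `data.frame`.
#' @param attribute attribute column name.
#' @param outcome outcome column name (default `"t790m"`).
#' @return An integer matrix (levels of `attribute` in rows, outcome levels
#'   in columns) of class `ContingencyTable`. Logical variables order
#'   `TRUE` before `FALSE` so that 2x2 tables read
#'   `[[exposed+, exposed-], [unexposed+, unexposed-]]`.
#' @export
build_contingency <- function(cohort, attribute, outcome = "t790m") {
  for (cl in c(attribute, outcome)) {
    if (!cl %in% names(cohort)) {
      stop("no such column: ", cl, call. = FALSE)
    }
  }
  lev <- function(v) {
    if (is.logical(v)) factor(v, levels = c(TRUE, FALSE))
    else factor(v, levels = sort(unique(v)))
  }
  tab <- table(lev(cohort[[attribute]]), lev(cohort[[outcome]]))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- c(attribute, outcome)
  class(m) <- c("ContingencyTable", class(m))
  m
}

#' Row proportion of a contingency table, with printed-style rounding
#'
#' @param table a [build_contingency()] matrix (or any count matrix).
#' @param row,col row/column index or name.
#' @return A list with `count`, `total`, `percent` (exact) and
#'   `percent_printed` — the percentage rounded half-up to one decimal, the
#'   convention used when printing clinical proportions. A zero row total
#'   yields `NA` percentages (undefined).
#' @export
proportion <- function(table, row, col) {
  count <- table[row, col]
  total <- sum(table[row, ])
  if (total == 0L) {
    return(list(count = 0L, total = 0L, percent = NA_real_,
                percent_printed = NA_real_))
  }
  pct <- 100 * count / total
  list(count = as.integer(count), total = as.integer(total),
       percent = pct, percent_printed = round_half_up(pct, 1L))
}

#' Round half away from zero at a given number of decimals
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector (half-up, not banker's rounding).
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with the point-probability rule: the p-value
#' is the sum, over all tables with the observed margins, of the
#' hypergeometric probabilities no greater than that of the observed table
#' (with the customary 1e-7 relative slack guarding against ties lost to
#' floating point). This matches the two-sided convention of the standard
#' exact-test implementations in statistics software.
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @return The two-sided p-value.
#' @export
fisher_exact_two_sided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    stop("fisher_exact_two_sided requires a 2x2 table", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  m <- sum(table[1L, ])          # margin of row 1
  n <- sum(table[2L, ])          # margin of row 2
  k <- sum(table[, 1L])          # margin of column 1
  if (m + n == 0L) stop("empty table", call. = FALSE)
  x <- table[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  p <- sum(d[d <= d[support == x] * (1 + 1e-7)])
  min(1, p)
}

#' Mutation-by-TKI outcome table
#'
#' Cross-tabulates acquired-T790M counts by initial EGFR mutation class and
#' by exposure to each TKI (a patient exposed to two drugs appears under
#' both), over the evaluable subset: patients whose initial mutation is
#' delE746_A750, another exon 19 non-LRE deletion, or L858R (exon 19 LRE
#' deletions other than delE746_A750 are excluded). Requires per-drug
#' exposure columns `tki_gefitinib`, `tki_erlotinib`, `tki_afatinib` in the
#' cohort (the packaged fixture carries them).
#'
#' @param cohort validated cohort `data.frame` with TKI exposure columns.
#' @return A `data.frame` with one row per TKI plus an overall row, and for
#'   each mutation class and overall: `<class>_pos`, `<class>_n`,
#'   `<class>_pct` (printed rounding; `NA` where the denominator is 0).
#' @export
mutation_tki_table <- function(cohort) {
  need <- paste0("tki_", TKI_LEVELS)
  if (!all(need %in% names(cohort))) {
    stop("cohort lacks TKI exposure columns: ",
         paste(setdiff(need, names(cohort)), collapse = ", "),
         call. = FALSE)
  }
  classes <- c(delE746_A750 = "exon19_LRE_delE746_A750",
               nonLRE = "exon19_nonLRE",
               L858R = "L858R")
  evaluable <- cohort$initial_egfr_mutation %in% classes
  rows <- c(TKI_LEVELS, "overall")
  out <- data.frame(tki = rows, stringsAsFactors = FALSE)
  for (ci in seq_along(classes)) {
    lab <- names(classes)[ci]
    in_class <- evaluable & cohort$initial_egfr_mutation == classes[ci]
    pos <- n <- integer(length(rows))
    for (ri in seq_along(rows)) {
      sel <- if (rows[ri] == "overall") in_class
             else in_class & cohort[[paste0("tki_", rows[ri])]]
      n[ri] <- sum(sel)
      pos[ri] <- sum(cohort$t790m[sel])
    }
    out[[paste0(lab, "_pos")]] <- pos
    out[[paste0(lab, "_n")]] <- n
    out[[paste0(lab, "_pct")]] <-
      ifelse(n > 0, round_half_up(100 * pos / n, 1L), NA_real_)
  }
  pos <- n <- integer(length(rows))
  for (ri in seq_along(rows)) {
    sel <- if (rows[ri] == "overall") evaluable
           else evaluable & cohort[[paste0("tki_", rows[ri])]]
    n[ri] <- sum(sel)
    pos[ri] <- sum(cohort$t790m[sel])
  }
  out$overall_pos <- pos
  out$overall_n <- n
  out$overall_pct <- ifelse(n > 0, round_half_up(100 * pos / n, 1L),
                            NA_real_)
  out
}
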