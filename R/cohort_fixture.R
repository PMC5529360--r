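#' Reconstructed 68-patient T790M cohort fixture
#'
#' A synthetic per-patient table that reproduces the published summary
#' counts of the motivating cohort: 68 patients with metastatic
#' EGFR-mutated NSCLC, 27 (39.7%) acquiring T790M; mutation classes
#' 31 delE746_A750 / 3 other exon 19 LRE deletions / 3 exon 19 non-LRE
#' deletions / 31 L858R; the full mutation-by-TKI outcome grid over the 65
#' evaluable patients (19/31, 0/3, 8/31, 27/65 overall; per-drug rows
#' 17/28, 0/3, 7/23; 4/9, 0/1, 0/5; 4/6, 0/0, 1/5); bone metastasis in
#' 34 patients of whom 21 acquired T790M (6 of the 34 without); 15 of 18
#' patients with both bone metastasis and delE746_A750 acquiring T790M;
#' 15 single-site patients of whom 14 did not acquire T790M; and the
#' baseline margins for sex (14/54), smoking (58/2/8), metastatic sites
#' (lung 59, pleura 30, brain 15, liver 11, bone 34, distant nodes 18),
#' number of sites (15/22/19/9/3), TKI lines (53/12/3), chemotherapy lines
#' (44/16/6/2), first TKI (54/7/7) and age (median 66, range 47--87).
#'
#' Only these published counts are constrained; every remaining cell
#' (which patient carries which age, sex, smoking status, or non-bone
#' metastatic site) is an arbitrary deterministic fill and carries no
#' information. The table is constructed fully in code — no per-patient
#' registry was ever published — and is synthetic in that sense.
#'
#' @return A cohort `data.frame` (validated; 68 rows) with the 24 ranking
#'   attributes, the `t790m` outcome, and per-drug exposure flags
#'   `tki_gefitinib`, `tki_erlotinib`, `tki_afatinib`.
#' @export
t790m_cohort <- function() {
  # patient blocks: mutation class, outcome, drug exposure, bone count
  g <- function(n, mutation, t790m, drugs, bone) {
    list(n = n, mutation = mutation, t790m = t790m, drugs = drugs,
         bone = bone)
  }
  blocks <- list(
    g(13L, "exon19_LRE_delE746_A750", TRUE,  "G",  13L),
    g(2L,  "exon19_LRE_delE746_A750", TRUE,  "GE", 2L),
    g(2L,  "exon19_LRE_delE746_A750", TRUE,  "GA", 0L),
    g(2L,  "exon19_LRE_delE746_A750", TRUE,  "EA", 0L),
    g(5L,  "exon19_LRE_delE746_A750", FALSE, "G",  3L),
    g(5L,  "exon19_LRE_delE746_A750", FALSE, "GE", 0L),
    g(1L,  "exon19_LRE_delE746_A750", FALSE, "GA", 0L),
    g(1L,  "exon19_LRE_delE746_A750", FALSE, "A",  0L),
    g(2L,  "exon19_nonLRE",           FALSE, "G",  1L),
    g(1L,  "exon19_nonLRE",           FALSE, "GE", 0L),
    g(7L,  "L858R",                   TRUE,  "G",  6L),
    g(1L,  "L858R",                   TRUE,  "A",  0L),
    g(14L, "L858R",                   FALSE, "G",  7L),
    g(2L,  "L858R",                   FALSE, "GE", 0L),
    g(3L,  "L858R",                   FALSE, "E",  1L),
    g(4L,  "L858R",                   FALSE, "A",  1L),
    g(3L,  "exon19_LRE_other",        FALSE, "G",  0L)
  )
  n <- sum(vapply(blocks, `[[`, 0L, "n"))
  rep_block <- function(field) {
    unlist(lapply(blocks, function(b) rep(b[[field]], b$n)))
  }
  df <- data.frame(
    initial_egfr_mutation = rep_block("mutation"),
    t790m = rep_block("t790m"),
    stringsAsFactors = FALSE
  )
  drugs <- rep_block("drugs")
  df$tki_gefitinib <- grepl("G", drugs)
  df$tki_erlotinib <- grepl("E", drugs)
  df$tki_afatinib <- grepl("A", drugs)
  df$bone_met <- unlist(lapply(blocks, function(b) {
    rep(c(TRUE, FALSE), c(b$bone, b$n - b$bone))
  }))

  # number of metastatic sites: 15 single-site patients, exactly one of
  # whom acquired T790M (a bone-free L858R responder), then 22/19/9/3
  # patients with 2/3/4/5 sites
  single_pos <- which(df$t790m & !df$bone_met &
                      df$initial_egfr_mutation == "L858R")[1L]
  single_neg <- utils::head(which(!df$t790m & !df$bone_met), 14L)
  single <- c(single_pos, single_neg)
  multi <- setdiff(seq_len(n), single)
  nsites <- integer(n)
  nsites[single] <- 1L
  nsites[multi] <- rep(c(5L, 4L, 3L, 2L), c(3L, 9L, 19L, 22L))
  df$number_sites_met <- nsites

  # fill the remaining site flags to the published per-site margins:
  # single-site patients get lung only (unless bone already is the site);
  # multi-site rows receive lung/pleura/nodes/brain/liver by a
  # largest-remaining-capacity greedy so that columns hit their totals
  sites <- matrix(FALSE, n, length(SITE_COLS),
                  dimnames = list(NULL, SITE_COLS))
  sites[, "bone_met"] <- df$bone_met
  sites[single, "lung_met"] <- TRUE
  demand <- c(lung_met = 59L, pleural_met = 30L, distant_ln_met = 18L,
              brain_met = 15L, liver_met = 11L)
  demand["lung_met"] <- demand["lung_met"] - length(single)
  capacity <- nsites - as.integer(df$bone_met)
  capacity[single] <- 0L
  for (col in names(demand)) {
    take <- order(-capacity, seq_len(n))[seq_len(demand[[col]])]
    stopifnot(all(capacity[take] > 0L))
    sites[take, col] <- TRUE
    capacity[take] <- capacity[take] - 1L
  }
  stopifnot(all(capacity == 0L),
            all(rowSums(sites) == df$number_sites_met))
  for (col in SITE_COLS) df[[col]] <- sites[, col]

  # deterministic arbitrary fill for the unconstrained attributes; the
  # multiplicative permutations just decorrelate them from block order
  scatter <- function(mult) (seq_len(n) * mult) %% n
  ages <- c(round(seq(47, 66, length.out = 34)), 66,
            round(seq(67, 87, length.out = 33)))
  df$age <- ages[order(scatter(29L))]
  for (thr in c(55, 60, 65, 70, 75, 80)) {
    df[[paste0("age_", thr)]] <- df$age >= thr
  }
  df$age <- NULL
  df$sex <- ifelse(scatter(13L) < 14L, "male", "female")
  smk <- scatter(23L)
  df$smoking <- ifelse(smk < 2L, "chronic", ifelse(smk < 10L, "ex",
                                                   "never"))
  chemo <- scatter(31L)
  df$number_lines_chemo <- ifelse(chemo < 2L, 3L,
                           ifelse(chemo < 8L, 2L,
                           ifelse(chemo < 24L, 1L, 0L)))
  df$first_chemo_used <- df$number_lines_chemo >= 1L
  df$second_chemo_used <- df$number_lines_chemo >= 2L
  df$third_chemo_used <- df$number_lines_chemo >= 3L

  # TKI lines: the 15 multi-drug patients are the multi-line patients;
  # the last three of them took three lines (one drug repeated)
  n_drugs <- df$tki_gefitinib + df$tki_erlotinib + df$tki_afatinib
  multi_drug <- which(n_drugs >= 2L)
  df$number_lines_tki <- 1L
  df$number_lines_tki[multi_drug] <- 2L
  df$number_lines_tki[utils::tail(multi_drug, 3L)] <- 3L
  df$second_tki_used <- df$number_lines_tki >= 2L
  df$third_tki_used <- df$number_lines_tki >= 3L

  # first TKI: gefitinib when exposed, with deterministic exceptions
  # bringing the first-line margins to 54/7/7
  df$first_tki <- ifelse(df$tki_gefitinib, "gefitinib",
                  ifelse(df$tki_erlotinib, "erlotinib", "afatinib"))
  ea <- which(drugs == "EA")
  df$first_tki[ea] <- c("erlotinib", "afatinib")
  ge_delneg <- which(drugs == "GE" & !df$t790m &
                     df$initial_egfr_mutation == "exon19_LRE_delE746_A750")
  df$first_tki[utils::head(ge_delneg, 3L)] <- "erlotinib"

  extra <- c("tki_gefitinib", "tki_erlotinib", "tki_afatinib")
  df <- df[, c(COHORT_ATTRIBUTES, "t790m", extra)]
  validate_cohort(df)
}
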