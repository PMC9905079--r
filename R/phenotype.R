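# Proxy AD/dementia phenotype: a pseudo-linear score in [0, 2] built from an
# individual's own diagnosis and the diagnoses and ages of their two parents.

#' Per-parent contribution to the proxy score
#'
#' An affected parent contributes 1. An unaffected parent contributes an
#' age weight (100 - age)/100, capped at 0.32 and floored at 0, so that
#' parents who stayed unaffected to old age down-weight the subject's score
#' while younger unaffected parents are uninformative (cap binds at age <= 68).
#'
#' @param affected logical vector; `NA` means the parent's status is unknown.
#' @param age numeric vector of parental ages in years; may be `NA`.
#' @param cap maximum contribution of an unaffected parent (default 0.32).
#' @param missing_status_contribution contribution when `affected` is `NA`
#'   (default 0: an unreported parent is uninformative).
#' @param missing_age_contribution contribution of an unaffected parent of
#'   unknown age (default the cap, i.e. treated as uninformative-young).
#' @return numeric vector of contributions in `[0, 1]`.
#' @keywords internal
parent_contribution <- function(affected, age, cap = 0.32,
                                missing_status_contribution = 0,
                                missing_age_contribution = cap) {
  out <- numeric(length(affected))
  out[is.na(affected)] <- missing_status_contribution
  aff <- !is.na(affected) & affected
  out[aff] <- 1
  unaff <- !is.na(affected) & !affected
  w <- pmax(0, pmin(cap, (100 - age[unaff]) / 100))
  w[is.na(age[unaff])] <- missing_age_contribution
  out[unaff] <- w
  out
}

#' Compute the proxy AD/dementia score for one subject
#'
#' Subjects with their own diagnosis receive the scale maximum 2, the same
#' score as a subject with two affected parents. Otherwise the score is the
#' sum of the two parental contributions (see [parent_contribution()]).
#'
#' @param own_diagnosis logical scalar.
#' @param parents a list of two parental records, each a list with elements
#'   `affected` (logical or `NA`) and `age` (years or `NA`).
#' @param cap,missing_status_contribution,missing_age_contribution passed to
#'   [parent_contribution()].
#' @return a single numeric score in `[0, 2]`.
#' @examples
#' compute_proxy_score(FALSE, list(
#'   list(affected = FALSE, age = 60), list(affected = NA, age = NA)))
#' @export
compute_proxy_score <- function(own_diagnosis, parents, cap = 0.32,
                                missing_status_contribution = 0,
                                missing_age_contribution = cap) {
  stopifnot(is.logical(own_diagnosis), length(own_diagnosis) == 1L,
            !is.na(own_diagnosis), length(parents) == 2L)
  affected <- vapply(parents, function(p) as.logical(p$affected), NA)
  age <- vapply(parents, function(p) {
    a <- p$age
    if (is.null(a) || is.na(a)) NA_real_ else as.numeric(a)
  }, NA_real_)
  bad <- !is.na(age) & (age < 0 | age > 120)
  if (any(bad)) {
    stop("implausible parental age (must be in [0, 120]): ",
         paste(age[bad], collapse = ", "))
  }
  if (own_diagnosis) return(2)
  sum(parent_contribution(affected, age, cap,
                          missing_status_contribution,
                          missing_age_contribution))
}

#' Score a phenotype/family-history table
#'
#' Takes the tab-delimited family-history layout (`subject_id`,
#' `own_diagnosis`, `father_affected`, `father_age`, `mother_affected`,
#' `mother_age`; affection coded 0/1/NA) and appends `proxy_score`,
#' `n_affected_parents`, `case_control` and a `flag_missing_parent` /
#' `flag_missing_age` pair marking subjects scored under a missing-data rule.
#'
#' @param pheno a `data.frame` in the layout above.
#' @param cap,missing_status_contribution,missing_age_contribution see
#'   [parent_contribution()].
#' @param drop_missing_parent drop subjects with an unknown parental status
#'   instead of scoring them with the missing-status rule (default `FALSE`).
#' @return a `data.table` with the appended columns.
#' @export
score_phenotypes <- function(pheno, cap = 0.32,
                             missing_status_contribution = 0,
                             missing_age_contribution = cap,
                             drop_missing_parent = FALSE) {
  need <- c("subject_id", "own_diagnosis", "father_affected", "father_age",
            "mother_affected", "mother_age")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("phenotype table is missing columns: ",
                         paste(miss, collapse = ", "))
  dt <- data.table::as.data.table(pheno)
  for (col in c("father_age", "mother_age")) {
    a <- dt[[col]]
    bad <- !is.na(a) & (a < 0 | a > 120)
    if (any(bad)) {
      stop("implausible parental age for subject(s): ",
           paste(utils::head(dt$subject_id[bad], 5), collapse = ", "))
    }
  }
  own <- as.logical(dt$own_diagnosis)
  if (anyNA(own)) stop("own_diagnosis must be 0/1 with no missing values")
  fa <- as.logical(dt$father_affected)
  ma <- as.logical(dt$mother_affected)
  contrib_f <- parent_contribution(fa, dt$father_age, cap,
                                   missing_status_contribution,
                                   missing_age_contribution)
  contrib_m <- parent_contribution(ma, dt$mother_age, cap,
                                   missing_status_contribution,
                                   missing_age_contribution)
  score <- ifelse(own, 2, contrib_f + contrib_m)
  n_aff <- (!is.na(fa) & fa) + (!is.na(ma) & ma)
  dt[, `:=`(
    proxy_score = score,
    n_affected_parents = as.integer(n_aff),
    flag_missing_parent = is.na(fa) | is.na(ma),
    flag_missing_age = (!is.na(fa) & !fa & is.na(father_age)) |
      (!is.na(ma) & !ma & is.na(mother_age))
  )]
  dt[, case_control := ifelse(own | n_affected_parents >= 1L,
                              "case", "control")]
  if (drop_missing_parent) dt <- dt[flag_missing_parent == FALSE]
  dt[]
}

#' Case/control recoding of the proxy phenotype
#'
#' A case is a subject with their own diagnosis or at least one affected
#' parent; a control has neither.
#'
#' @param pheno a scored phenotype table (see [score_phenotypes()]).
#' @return a factor with levels `control`, `case`, aligned to `pheno` rows;
#'   label counts are attached as attribute `counts`.
#' @export
derive_case_control <- function(pheno) {
  if (!all(c("own_diagnosis", "n_affected_parents") %in% names(pheno))) {
    pheno <- score_phenotypes(pheno)
  }
  lab <- factor(
    ifelse(as.logical(pheno$own_diagnosis) | pheno$n_affected_parents >= 1L,
           "case", "control"),
    levels = c("control", "case"))
  attr(lab, "counts") <- table(lab)
  lab
}

#' Drop subjects with their own diagnosis
#'
#' Restricts the cohort to subjects whose phenotype is determined purely by
#' parental disease status, for the sensitivity analysis of diagnosed
#' individuals' influence.
#'
#' @param pheno a phenotype table with an `own_diagnosis` column.
#' @return the filtered table; warns if every subject is dropped.
#' @export
exclude_diagnosed <- function(pheno) {
  keep <- !as.logical(pheno$own_diagnosis)
  out <- data.table::as.data.table(pheno)[keep]
  if (nrow(out) == 0L) warning("all subjects carry a diagnosis; empty cohort")
  out
}

#' Stratify a scored cohort into the four reporting strata
#'
#' The strata are mutually exclusive and exhaustive: own diagnosis; two
#' affected parents; one affected parent; no affected parents and no own
#' diagnosis (proxy score < 1).
#'
#' @param pheno a scored phenotype table.
#' @return named integer vector of stratum counts.
#' @export
phenotype_strata <- function(pheno) {
  own <- as.logical(pheno$own_diagnosis)
  n_aff <- pheno$n_affected_parents
  c(unaffected = sum(!own & n_aff == 0L),
    one_parent = sum(!own & n_aff == 1L),
    two_parents = sum(!own & n_aff == 2L),
    own_diagnosis = sum(own))
}
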