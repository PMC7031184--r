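# Analysis-ready phenotypes for the human cohort: parental longevity
# score, grip-strength summaries, and the covariate encoding shared by all
# association models.

# closed category lists used across the cohort
EDUCATION_LEVELS <- c("none", "elementary", "secondary", "high school",
                      "professional school", "university")
SMOKING_LEVELS <- c("none", "<20", "20-39", "40+")
SEX_LEVELS <- c("male", "female")
SITE_LEVELS <- c("Greve", "Bagno")
WBC_COLUMNS <- c("pct_neutrophils", "pct_lymphocytes", "pct_monocytes",
                 "pct_eosinophils")

#' Combined parental longevity score (PLS)
#'
#' Participants aged `age_min`+ years are scored for parental longevity.
#' Parents who died prematurely (mothers before `premature_mother`, fathers
#' before `premature_father` years) are excluded from the score. Each
#' remaining parental age at death is standardized to a Z-score against the
#' eligible, non-premature parents of the same sex (sample SD, ddof = 1);
#' the PLS is the unweighted mean of the available parental Z-scores,
#' deliberately not re-standardized (a both-parent average of two
#' imperfectly correlated Z-scores has SD < 1, matching cohort summaries).
#'
#' Short/intermediate/long-lived categories per parent are also reported,
#' from the tertiles of a normal distribution fitted to the eligible
#' non-premature ages at death.
#'
#' @param records cohort data.frame with columns `participant_id`, `age`,
#'   `mother_death_age`, `father_death_age` (NA = missing).
#' @param age_min eligibility age in years (default 65).
#' @param premature_mother,premature_father exclusion cut-offs in years:
#'   deaths strictly below are premature (defaults 49 and 52).
#' @param require_both if TRUE, a PLS is only assigned when both parental
#'   Z-scores are available (default FALSE: single-parent PLS allowed).
#' @return data.frame with columns `participant_id`, `z_maternal`,
#'   `z_paternal`, `pls`, `excluded_reason` (one of `under_65`,
#'   `no_parent_data`, `premature_mother`, `premature_father`, `none`),
#'   `mother_category`, `father_category`.
#' @export
compute_pls <- function(records, age_min = 65, premature_mother = 49,
                        premature_father = 52, require_both = FALSE) {
  assert_columns(records, c("participant_id", "age", "mother_death_age",
                            "father_death_age"), "records")
  eligible <- !is.na(records$age) & records$age >= age_min
  m_age <- records$mother_death_age
  f_age <- records$father_death_age
  m_prem <- !is.na(m_age) & m_age < premature_mother
  f_prem <- !is.na(f_age) & f_age < premature_father
  m_use <- eligible & !is.na(m_age) & !m_prem
  f_use <- eligible & !is.na(f_age) & !f_prem

  zscore <- function(x, use) {
    vals <- x[use]
    if (length(vals) < 2L || stats::sd(vals) == 0) {
      warnf("fewer than 2 usable parental ages (or zero variance); %s",
            "Z-scores undefined")
      return(list(z = rep(NA_real_, length(x)), mean = NA_real_,
                  sd = NA_real_))
    }
    mu <- mean(vals)
    sdv <- stats::sd(vals)  # sample SD, ddof = 1
    z <- rep(NA_real_, length(x))
    z[use] <- (x[use] - mu) / sdv
    list(z = z, mean = mu, sd = sdv)
  }
  zm <- zscore(m_age, m_use)
  zf <- zscore(f_age, f_use)

  pls <- rowMeans(cbind(zm$z, zf$z), na.rm = !require_both)
  pls[is.nan(pls)] <- NA_real_

  reason <- rep("none", nrow(records))
  reason[m_prem] <- "premature_mother"
  reason[f_prem & !m_prem] <- "premature_father"
  reason[eligible & is.na(m_age) & is.na(f_age)] <- "no_parent_data"
  reason[!eligible] <- "under_65"
  pls[!eligible] <- NA_real_
  zm$z[!eligible] <- NA_real_
  zf$z[!eligible] <- NA_real_

  categorize <- function(x, mu, sdv, use) {
    out <- rep(NA_character_, length(x))
    if (is.na(mu)) return(out)
    cuts <- stats::qnorm(c(1 / 3, 2 / 3), mean = mu, sd = sdv)
    labs <- c("short", "intermediate", "long")
    out[use] <- labs[findInterval(x[use], cuts) + 1L]
    out
  }

  data.frame(participant_id = records$participant_id,
             z_maternal = zm$z,
             z_paternal = zf$z,
             pls = pls,
             excluded_reason = reason,
             mother_category = categorize(m_age, zm$mean, zm$sd, m_use),
             father_category = categorize(f_age, zf$mean, zf$sd, f_use),
             stringsAsFactors = FALSE)
}

#' Summarize repeated grip-strength measurements
#'
#' Arithmetic mean of the available repeats per participant; all-missing
#' rows summarize to NA.
#'
#' @param measurements numeric matrix or data.frame, one row per
#'   participant, one column per repeat (NA allowed).
#' @return numeric vector of per-participant means (kg).
#' @export
summarize_grip <- function(measurements) {
  m <- as.matrix(measurements)
  out <- rowMeans(m, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Model-ready covariate encoding
#'
#' Encodes the confounder set shared by the association models: sex and
#' study site as binary indicators, education and smoking as single
#' ordinal integer columns (0-based; a flag switches education to dummy
#' coding), BMI and white-blood-cell percentages as continuous columns.
#' Age is included as a covariate for the PLS and grip models and excluded
#' from the age model itself. Rows with any missing covariate are flagged
#' for listwise deletion in the `complete` attribute.
#'
#' @param records cohort data.frame (see [simulate_cohort()] for the
#'   column dictionary).
#' @param model which association model the covariates are for: `"age"`
#'   drops the age column, anything else keeps it.
#' @param education_coding `"ordinal"` (default, one integer column) or
#'   `"dummy"` (indicator per non-reference level).
#' @return numeric data.frame of covariates with attribute `complete`
#'   (logical: row has no missing covariate).
#' @export
build_covariates <- function(records, model = c("pls", "grip", "age"),
                             education_coding = c("ordinal", "dummy")) {
  model <- match.arg(model)
  education_coding <- match.arg(education_coding)
  assert_columns(records, c("age", "sex", "bmi", "education", "site",
                            "smoking", WBC_COLUMNS), "records")
  check_levels <- function(x, levels, name) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad))
      stopf("unknown %s label(s): %s", name,
            paste(unique(x[bad]), collapse = ", "))
  }
  check_levels(records$sex, SEX_LEVELS, "sex")
  check_levels(records$site, SITE_LEVELS, "site")
  check_levels(records$education, EDUCATION_LEVELS, "education")
  check_levels(records$smoking, SMOKING_LEVELS, "smoking")

  cov <- data.frame(
    sex_male = as.numeric(records$sex == "male"),
    site_bagno = as.numeric(records$site == "Bagno"),
    smoking_ord = as.numeric(match(records$smoking, SMOKING_LEVELS) - 1L),
    bmi = records$bmi)
  cov$sex_male[is.na(records$sex)] <- NA
  cov$site_bagno[is.na(records$site)] <- NA
  if (education_coding == "ordinal") {
    cov$education_ord <- as.numeric(match(records$education,
                                          EDUCATION_LEVELS) - 1L)
  } else {
    for (lev in EDUCATION_LEVELS[-1]) {
      nm <- paste0("education_", gsub(" ", "_", lev))
      cov[[nm]] <- as.numeric(records$education == lev)
      cov[[nm]][is.na(records$education)] <- NA
    }
  }
  for (w in WBC_COLUMNS) cov[[w]] <- records[[w]]
  if (model != "age") cov$age <- records$age

  attr(cov, "complete") <- stats::complete.cases(cov)
  cov
}
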