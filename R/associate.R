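# Inferential layers: qPCR global-mean normalization, cohort
# expression-phenotype regressions with Bonferroni control, senescence
# early/late comparison, dysregulation counting, and mouse strain-lifespan
# regression.

#' Global-mean qPCR normalization
#'
#' Normalizes a Ct matrix to relative expression in four steps:
#' (1) technical replicates collapsed by median Ct;
#' (2) per sample, delta-Ct against the arithmetic mean Ct across assays
#'     (arithmetic mean of Ct is the geometric mean on the 2^-Ct
#'     expression scale);
#' (3) expression `E = 2^(-dCt)`;
#' (4) each assay divided by its geometric mean across samples (the
#'     "global mean" of that transcript), so each assay's geometric mean
#'     relative expression over the retained samples is exactly 1.
#'
#' "Undetermined" wells must arrive as NA (never as Ct = 50). Samples with
#' no usable Ct at all are dropped with a warning; assays missing in more
#' than half of the retained samples are flagged but kept.
#'
#' @param ct_data long-format data.frame with columns `assay_id`,
#'   `sample_id`, `technical_replicate`, `ct` (NA allowed).
#' @return object of class `qpcr_norm`: list with `expression` (numeric
#'   matrix, assays x samples, relative expression), `ct_median` (the
#'   collapsed Ct matrix), `dropped_samples`, `flagged_assays`.
#' @export
normalize_qpcr <- function(ct_data) {
  assert_columns(ct_data, c("assay_id", "sample_id",
                            "technical_replicate", "ct"), "ct_data")
  if (any(!is.na(ct_data$ct) & (ct_data$ct <= 0 | ct_data$ct > 50)))
    stopf("Ct values must lie in (0, 50] or be NA")
  assays <- unique(ct_data$assay_id)
  samples <- unique(ct_data$sample_id)
  if (length(assays) < 2L || length(samples) < 2L)
    stopf("need at least 2 assays and 2 samples to normalize")

  # step 1: collapse technical replicates by median
  ctm <- matrix(NA_real_, length(assays), length(samples),
                dimnames = list(assays, samples))
  agg <- stats::aggregate(ct ~ assay_id + sample_id, data = ct_data,
                          FUN = stats::median, na.action = stats::na.omit)
  ctm[cbind(match(agg$assay_id, assays), match(agg$sample_id, samples))] <-
    agg$ct

  dropped <- colnames(ctm)[colSums(!is.na(ctm)) == 0L]
  if (length(dropped) > 0L) {
    warnf("dropping sample(s) with no usable Ct: %s",
          paste(dropped, collapse = ", "))
    ctm <- ctm[, !(colnames(ctm) %in% dropped), drop = FALSE]
  }

  # step 2-3: delta-Ct against per-sample mean across assays, to expression
  sample_mean <- colMeans(ctm, na.rm = TRUE)
  dct <- sweep(ctm, 2, sample_mean, "-")
  expr <- 2^(-dct)

  # step 4: per-assay global (geometric) mean scaling
  assay_gm <- apply(expr, 1, geo_mean)
  expr <- sweep(expr, 1, assay_gm, "/")

  flagged <- rownames(ctm)[rowMeans(is.na(ctm)) > 0.5]
  if (length(flagged) > 0L)
    warnf("assay(s) missing in >50%% of samples: %s",
          paste(flagged, collapse = ", "))

  structure(list(expression = expr, ct_median = ctm,
                 dropped_samples = dropped, flagged_assays = flagged),
            class = "qpcr_norm")
}

#' Bonferroni significance threshold
#'
#' `alpha / n_tests`, with a rounded (half-up) version for reporting. The
#' unrounded value is what significance flags compare against; the rounded
#' value is what goes in tables (0.05/15 reports as 0.003, 0.05/4 as
#' 0.013).
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests in the family.
#' @param decimals decimal places for the reported threshold (default 3).
#' @return list with `raw` (use for flagging) and `reported` (rounded).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests, decimals = 3) {
  assert_scalar_number(alpha, "alpha", min = 0, max = 1)
  assert_scalar_number(n_tests, "n_tests", min = 1, integer = TRUE)
  assert_scalar_number(decimals, "decimals", min = 0, integer = TRUE)
  raw <- alpha / n_tests
  list(raw = raw, reported = round_half_up(raw, decimals))
}

# Run one OLS fit and extract the row for `term`. Errors on
# rank-deficient designs, naming the aliased columns.
ols_term <- function(formula, data, term, conf_level = 0.95) {
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit))))
    stopf("rank-deficient design; collinear column(s): %s",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                collapse = ", "))
  sm <- summary(fit)$coefficients
  if (!(term %in% rownames(sm)))
    stopf("term '%s' absent from the fitted model", term)
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  df <- stats::df.residual(fit)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  list(beta = est, se = se, p = sm[term, "Pr(>|t|)"],
       ci_low = est - tcrit * se, ci_high = est + tcrit * se,
       n_used = length(stats::residuals(fit)), df = df)
}

#' Covariate-adjusted expression-phenotype association
#'
#' Fits one ordinary-least-squares model per circRNA relating its
#' expression to an aging outcome, adjusted for the shared confounder set
#' (BMI, sex, education, study site, smoking, WBC differentials; age added
#' for the non-age models). Listwise deletion is applied per model.
#'
#' Model orientation follows the reported coefficient scales per outcome:
#' for `age` and `pls`, expression is the dependent variable (beta =
#' change in relative expression per year / per PLS unit); for grip
#' outcomes, grip strength is the dependent variable and expression the
#' exposure (beta = kg per relative-expression unit). `orientation`
#' overrides the default. The orientation used is recorded in every
#' result row.
#'
#' The grip models come in two designs: `grip_cross_sectional` pairs
#' expression with same-wave grip (`grip_fu3`); `grip_longitudinal` pairs
#' baseline expression with follow-up grip (`grip_fu4`), without baseline
#' grip adjustment unless `adjust_baseline_grip = TRUE`.
#'
#' @param expression numeric matrix, participants x circRNAs (rownames =
#'   participant ids optional), or a single numeric vector.
#' @param records cohort data.frame aligned row-wise with `expression`;
#'   must contain the covariate columns and the outcome column (`age`,
#'   `pls`, `grip_fu3`, `grip_fu4`).
#' @param outcome one of `"age"`, `"pls"`, `"grip_cross_sectional"`,
#'   `"grip_longitudinal"`.
#' @param orientation `"expression_dependent"`, `"outcome_dependent"` or
#'   NULL for the per-outcome default described above.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param adjust_baseline_grip add `grip_fu3` as covariate in the
#'   longitudinal grip model.
#' @param education_coding passed to [build_covariates()].
#' @return data.frame (`AssociationResult`) with one row per circRNA:
#'   `circ_id`, `outcome`, `orientation`, `beta`, `se`, `p`, `ci_low`,
#'   `ci_high`, `n_used`, `significant_adjusted`.
#' @export
fit_phenotype_association <- function(expression, records,
                                      outcome = c("age", "pls",
                                                  "grip_cross_sectional",
                                                  "grip_longitudinal"),
                                      orientation = NULL, alpha = 0.05,
                                      adjust_baseline_grip = FALSE,
                                      education_coding = "ordinal") {
  outcome <- match.arg(outcome)
  if (is.null(dim(expression)))
    expression <- matrix(expression, ncol = 1,
                         dimnames = list(NULL, "circRNA"))
  if (nrow(expression) != nrow(records))
    stopf("expression and records must have the same number of rows")

  outcome_col <- switch(outcome, age = "age", pls = "pls",
                        grip_cross_sectional = "grip_fu3",
                        grip_longitudinal = "grip_fu4")
  assert_columns(records, outcome_col, "records")
  default_orient <- if (outcome %in% c("age", "pls"))
    "expression_dependent" else "outcome_dependent"
  if (is.null(orientation)) orientation <- default_orient
  orientation <- match.arg(orientation, c("expression_dependent",
                                          "outcome_dependent"))

  cov <- build_covariates(records,
                          model = if (outcome == "age") "age" else
                            if (outcome == "pls") "pls" else "grip",
                          education_coding = education_coding)
  if (outcome == "grip_longitudinal" && adjust_baseline_grip)
    cov$grip_baseline <- records$grip_fu3
  cov_terms <- names(cov)

  thr <- bonferroni_threshold(alpha, ncol(expression))
  rows <- lapply(seq_len(ncol(expression)), function(j) {
    dat <- cbind(data.frame(.expr = expression[, j],
                            .outcome = records[[outcome_col]]), cov)
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    n_par <- 2L + length(cov_terms)
    if (nrow(dat) <= n_par + 1L)
      stopf("too few complete cases (%d) for %d model parameters",
            nrow(dat), n_par)
    rhs <- paste(cov_terms, collapse = " + ")
    if (orientation == "expression_dependent") {
      f <- stats::as.formula(paste(".expr ~ .outcome +", rhs))
      term <- ".outcome"
    } else {
      f <- stats::as.formula(paste(".outcome ~ .expr +", rhs))
      term <- ".expr"
    }
    r <- ols_term(f, dat, term)
    data.frame(circ_id = colnames(expression)[j], outcome = outcome,
               orientation = orientation, beta = r$beta, se = r$se,
               p = r$p, ci_low = r$ci_low, ci_high = r$ci_high,
               n_used = r$n_used,
               significant_adjusted = r$p < thr$raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni") <- thr
  out
}

# Two-group one-way ANOVA computed directly, so the degenerate all-equal
# case (SSB = SSW = 0) can report F = 0, p = 1 instead of NaN.
anova_two_group <- function(x, g) {
  groups <- split(x, g)
  if (length(groups) != 2L) stopf("exactly two groups expected")
  n <- lengths(groups)
  grand <- mean(x)
  ssb <- sum(n * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df2 <- length(x) - 2L
  if (ssb == 0) return(list(F = 0, p = 1, df1 = 1L, df2 = df2))
  if (ssw == 0) return(list(F = Inf, p = 0, df1 = 1L, df2 = df2))
  Fstat <- (ssb / 1) / (ssw / df2)
  list(F = Fstat, p = stats::pf(Fstat, 1, df2, lower.tail = FALSE),
       df1 = 1L, df2 = df2)
}

#' Early- vs late-passage expression comparison
#'
#' For one cell type, normalizes the Ct matrix ([normalize_qpcr()], with
#' samples = passage x biological replicate) and compares early vs late
#' passage per circRNA by one-way ANOVA (two groups, so F equals the
#' squared pooled t statistic). Medians and interquartile ranges of
#' relative expression per passage group are reported. circRNAs with no
#' detectable Ct in either passage group are marked `expressed = FALSE`
#' and excluded from testing.
#'
#' @param ct_data long data.frame for one cell type with columns
#'   `assay_id`, `passage` (`"early"`/`"late"`), `biological_replicate`,
#'   `technical_replicate`, `ct`.
#' @param cell_type label copied into the result rows.
#' @return data.frame (`SenescenceResult`): `circ_id`, `cell_type`,
#'   `median_early`, `q1_early`, `q3_early`, `median_late`, `q1_late`,
#'   `q3_late`, `p`, `expressed`.
#' @export
senescence_compare <- function(ct_data, cell_type = "cells") {
  assert_columns(ct_data, c("assay_id", "passage", "biological_replicate",
                            "technical_replicate", "ct"), "ct_data")
  if (!all(ct_data$passage %in% c("early", "late")))
    stopf("passage labels must be 'early' or 'late'")
  ct_data$sample_id <- paste(ct_data$passage, ct_data$biological_replicate,
                             sep = ":")
  norm <- suppressWarnings(
    normalize_qpcr(ct_data[, c("assay_id", "sample_id",
                               "technical_replicate", "ct")]))
  expr <- norm$expression
  passage_of <- sub(":.*$", "", colnames(expr))

  rows <- lapply(rownames(expr), function(a) {
    e <- expr[a, passage_of == "early"]
    l <- expr[a, passage_of == "late"]
    e <- e[!is.na(e)]
    l <- l[!is.na(l)]
    expressed <- length(e) >= 2L && length(l) >= 2L
    qs <- function(v) if (length(v) == 0L) rep(NA_real_, 3) else
      stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
    qe <- qs(e)
    ql <- qs(l)
    p <- if (expressed)
      anova_two_group(c(e, l), rep(c("early", "late"),
                                   c(length(e), length(l))))$p
    else NA_real_
    data.frame(circ_id = a, cell_type = cell_type,
               median_early = qe[1], q1_early = qe[2], q3_early = qe[3],
               median_late = ql[1], q1_late = ql[2], q3_late = ql[3],
               p = p, expressed = expressed, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count dysregulated circRNAs across cell types
#'
#' A circRNA counts as expressed when `expressed = TRUE` in at least one
#' cell type, and as dysregulated when additionally `p < alpha` in at
#' least one cell type (distinct-count semantics: significance in several
#' cell types counts once). The fraction is reported as a whole percent
#' (half-up).
#'
#' @param results rbind of [senescence_compare()] outputs across cell
#'   types (or any data.frame with `circ_id`, `cell_type`, `p`,
#'   `expressed`).
#' @param alpha significance level (default 0.05).
#' @return list with `n_dysregulated`, `n_expressed`, `fraction_percent`.
#' @export
count_dysregulated <- function(results, alpha = 0.05) {
  assert_columns(results, c("circ_id", "p", "expressed"), "results")
  results <- unique(results[, c("circ_id",
                                intersect("cell_type", names(results)),
                                "p", "expressed")])
  expressed_ids <- unique(results$circ_id[results$expressed %in% TRUE])
  sig <- results$expressed %in% TRUE & !is.na(results$p) &
    results$p < alpha
  dysreg_ids <- intersect(unique(results$circ_id[sig]), expressed_ids)
  n_exp <- length(expressed_ids)
  n_dys <- length(dysreg_ids)
  list(n_dysregulated = n_dys, n_expressed = n_exp,
       fraction_percent = if (n_exp == 0) NA_real_ else
         round_half_up(100 * n_dys / n_exp))
}

#' Mouse strain-lifespan association
#'
#' Normalizes mouse qPCR panels (technical replicates collapsed by median;
#' delta-Ct of each circRNA assay against the geometric mean of the
#' reference assays, i.e. the arithmetic mean of their Cts; expression
#' 2^-dCt; then per-circRNA scaling to a global geometric mean of 1 across
#' the tissue's samples) and regresses normalized expression on median
#' strain lifespan, per circRNA, within the requested age stratum.
#' circRNAs with no detectable Ct anywhere in the tissue are reported with
#' `detected = FALSE` (the "ND" convention).
#'
#' @param panel long data.frame with columns `strain`, `lifespan_months`,
#'   `age_group` (`"young"`/`"old"`), `tissue`, `animal_id`, `assay_id`,
#'   `technical_replicate`, `ct`.
#' @param tissue tissue to analyse (e.g. `"spleen"`, `"muscle"`).
#' @param stratum `"all"`, `"young"` or `"old"`.
#' @param reference_assays assay ids of the endogenous controls (default
#'   `Pol2ra`, `Trfc`, `Ipo8`).
#' @param alpha family-wise error rate; the Bonferroni family is the set
#'   of tested (detected) circRNAs.
#' @return data.frame: `circ_id`, `tissue`, `stratum`, `detected`, `beta`,
#'   `se`, `p`, `ci_low`, `ci_high`, `n_used`, `significant_adjusted`
#'   (NA columns for not-detected circRNAs).
#' @export
mouse_lifespan_association <- function(panel, tissue,
                                       stratum = c("all", "young", "old"),
                                       reference_assays = c("Pol2ra",
                                                            "Trfc",
                                                            "Ipo8"),
                                       alpha = 0.05) {
  stratum <- match.arg(stratum)
  assert_columns(panel, c("strain", "lifespan_months", "age_group",
                          "tissue", "animal_id", "assay_id",
                          "technical_replicate", "ct"), "panel")
  pt <- panel[panel$tissue == tissue, , drop = FALSE]
  if (nrow(pt) == 0L) stopf("tissue '%s' absent from the panel", tissue)
  circ_assays <- setdiff(unique(pt$assay_id), reference_assays)

  # collapse technical replicates by median per (animal, assay)
  agg <- stats::aggregate(ct ~ animal_id + assay_id, data = pt,
                          FUN = stats::median, na.action = stats::na.omit)
  animals <- unique(pt[, c("animal_id", "strain", "lifespan_months",
                           "age_group")])
  ctm <- matrix(NA_real_, length(unique(agg$assay_id)),
                nrow(animals),
                dimnames = list(unique(agg$assay_id), animals$animal_id))
  ctm[cbind(match(agg$assay_id, rownames(ctm)),
            match(agg$animal_id, colnames(ctm)))] <- agg$ct

  refs <- intersect(reference_assays, rownames(ctm))
  if (length(refs) == 0L) stopf("no reference assays found in the panel")
  ref_mean <- colMeans(ctm[refs, , drop = FALSE], na.rm = TRUE)

  if (length(unique(animals$lifespan_months)) < 2L)
    stopf("need at least 2 distinct lifespan values")

  in_stratum <- if (stratum == "all") rep(TRUE, nrow(animals)) else
    animals$age_group == stratum

  thr_n <- max(1L, sum(vapply(circ_assays, function(a)
    a %in% rownames(ctm) && any(!is.na(ctm[a, ])), TRUE)))
  rows <- lapply(circ_assays, function(a) {
    nd_row <- data.frame(circ_id = a, tissue = tissue, stratum = stratum,
                         detected = FALSE, beta = NA_real_, se = NA_real_,
                         p = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, n_used = 0L,
                         significant_adjusted = NA,
                         stringsAsFactors = FALSE)
    if (!(a %in% rownames(ctm)) || all(is.na(ctm[a, ]))) return(nd_row)
    # delta-Ct then global-mean scaling across the tissue's samples
    expr <- 2^(-(ctm[a, ] - ref_mean))
    expr <- expr / geo_mean(expr)
    dat <- data.frame(expr = expr[in_stratum],
                      lifespan = animals$lifespan_months[in_stratum])
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    if (length(unique(animals$strain[in_stratum])) < 3L)
      stopf("need at least 3 distinct strains in stratum '%s'", stratum)
    r <- ols_term(expr ~ lifespan, dat, "lifespan")
    data.frame(circ_id = a, tissue = tissue, stratum = stratum,
               detected = TRUE, beta = r$beta, se = r$se, p = r$p,
               ci_low = r$ci_low, ci_high = r$ci_high, n_used = r$n_used,
               significant_adjusted = r$p < alpha / thr_n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni") <- bonferroni_threshold(alpha, thr_n)
  out
}
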