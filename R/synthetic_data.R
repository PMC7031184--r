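# Seeded synthetic-data generators with planted ground truth. Each
# generator emulates one input of the pipeline: pooled young/old RNase
# R/mock sequencing libraries, an aging cohort with covariates and
# phenotypes, early/late-passage qPCR plates, and a six-strain mouse
# panel. All randomness flows from a single integer seed; stage seeds are
# derived deterministically (see derive_seed()).

#' Pool simulation configuration
#'
#' Describes the two-pool (young/old) x two-treatment (RNase R/mock)
#' sequencing design. Class sizes default to the planted profile of 184
#' shared, 431 young-only and 1592 old-only circRNAs (2207 total).
#' Back-spliced-junction counts follow a negative binomial with the given
#' mean and dispersion (variance = mu + dispersion * mu^2): pooled
#' junction counts are over-dispersed. RNase R treatment is modeled as two
#' multiplicative factors: canonical (linear) reads retained at
#' `rnase_r_linear_retention` <= 1 and BSJ reads enriched by
#' `rnase_r_circ_enrichment` >= 1.
#'
#' @param n_shared,n_young_only,n_old_only planted class sizes.
#' @param n_circ_total total circRNAs; must equal the class-size sum.
#' @param mean_bsj_reads negative-binomial mean BSJ count in a mock
#'   library for a circRNA present in that pool.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param canonical_mean mean canonical (linear) read count of a host gene
#'   in a mock library.
#' @param rnase_r_linear_retention fraction of canonical reads surviving
#'   RNase R, in [0, 1].
#' @param rnase_r_circ_enrichment BSJ fold-enrichment under RNase R, >= 1.
#' @param fc_sd standard deviation of the planted log2 fold changes of
#'   shared circRNAs (old vs young).
#' @param seed integer RNG seed.
#' @return validated `pool_sim_config` list.
#' @export
pool_sim_config <- function(n_shared = 184, n_young_only = 431,
                            n_old_only = 1592,
                            n_circ_total = n_shared + n_young_only +
                              n_old_only,
                            mean_bsj_reads = 60, dispersion = 0.2,
                            canonical_mean = 400,
                            rnase_r_linear_retention = 0.05,
                            rnase_r_circ_enrichment = 5,
                            fc_sd = 1.5, seed = 1L) {
  cfg <- list(n_shared = n_shared, n_young_only = n_young_only,
              n_old_only = n_old_only, n_circ_total = n_circ_total,
              mean_bsj_reads = mean_bsj_reads, dispersion = dispersion,
              canonical_mean = canonical_mean,
              rnase_r_linear_retention = rnase_r_linear_retention,
              rnase_r_circ_enrichment = rnase_r_circ_enrichment,
              fc_sd = fc_sd, seed = seed)
  for (f in c("n_shared", "n_young_only", "n_old_only", "n_circ_total"))
    assert_scalar_number(cfg[[f]], f, min = 0, integer = TRUE)
  if (cfg$n_shared + cfg$n_young_only + cfg$n_old_only != cfg$n_circ_total)
    stopf("inconsistent class counts: %d + %d + %d != n_circ_total = %d",
          cfg$n_shared, cfg$n_young_only, cfg$n_old_only, cfg$n_circ_total)
  assert_scalar_number(cfg$mean_bsj_reads, "mean_bsj_reads", min = 0)
  assert_scalar_number(cfg$dispersion, "dispersion", min = 1e-9)
  assert_scalar_number(cfg$canonical_mean, "canonical_mean", min = 0)
  assert_scalar_number(cfg$rnase_r_linear_retention,
                       "rnase_r_linear_retention", min = 0, max = 1)
  assert_scalar_number(cfg$rnase_r_circ_enrichment,
                       "rnase_r_circ_enrichment", min = 1)
  assert_scalar_number(cfg$fc_sd, "fc_sd", min = 0)
  assert_scalar_number(cfg$seed, "seed", integer = TRUE)
  structure(cfg, class = "pool_sim_config")
}

rnbinom_mu <- function(n, mu, dispersion) {
  out <- integer(n)
  pos <- mu > 0
  if (any(pos))
    out[pos] <- stats::rnbinom(sum(pos), size = 1 / dispersion,
                               mu = mu[pos])
  out
}

#' Simulate pooled-library junction count tables
#'
#' Generates the four libraries of the pooled design (young/old x RNase
#' R-treated/mock) as one long junction count table, with planted class
#' memberships: a young-only circRNA has expected BSJ count 0 in both old
#' libraries, and vice versa; shared circRNAs carry planted log2 fold
#' changes (old vs young) split symmetrically across the pools.
#'
#' @param config a [pool_sim_config()].
#' @return list with `table` (long junction count table over libraries
#'   `young_treated`, `young_mock`, `old_treated`, `old_mock`) and `truth`
#'   (list: `class_of` named character, `planted_fc` named numeric for
#'   shared circRNAs).
#' @export
simulate_pool_counts <- function(config) {
  if (!inherits(config, "pool_sim_config"))
    config <- do.call(pool_sim_config, as.list(config))
  with_seed(config$seed, {
    n <- config$n_circ_total
    ids <- sprintf("circ%05d", seq_len(n))
    hosts <- sprintf("GENE%05d", seq_len(n))
    cls <- rep(c("shared", "young_only", "old_only"),
               c(config$n_shared, config$n_young_only, config$n_old_only))
    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    start <- sample.int(1e8, n)
    end <- start + sample(200:5000, n, replace = TRUE)

    fc <- stats::rnorm(config$n_shared, 0, config$fc_sd)
    names(fc) <- ids[cls == "shared"]

    mu_young <- mu_old <- numeric(n)
    mu_young[cls == "shared"] <- config$mean_bsj_reads * 2^(-fc / 2)
    mu_old[cls == "shared"] <- config$mean_bsj_reads * 2^(fc / 2)
    mu_young[cls == "young_only"] <- config$mean_bsj_reads
    mu_old[cls == "old_only"] <- config$mean_bsj_reads

    one_lib <- function(lib_id, mu, treated) {
      bsj_mu <- if (treated) mu * config$rnase_r_circ_enrichment else mu
      canon_mu <- if (treated)
        config$canonical_mean * config$rnase_r_linear_retention
      else config$canonical_mean
      data.frame(circ_id = ids, host_gene = hosts, chrom = chrom,
                 junction_start = start, junction_end = end,
                 library_id = lib_id,
                 bsj_reads = rnbinom_mu(n, bsj_mu, config$dispersion),
                 canonical_reads = rnbinom_mu(n, rep(canon_mu, n),
                                              config$dispersion),
                 stringsAsFactors = FALSE)
    }
    table <- rbind(one_lib("young_treated", mu_young, TRUE),
                   one_lib("young_mock", mu_young, FALSE),
                   one_lib("old_treated", mu_old, TRUE),
                   one_lib("old_mock", mu_old, FALSE))
    truth <- list(class_of = stats::setNames(cls, ids), planted_fc = fc)
    list(table = table, truth = truth)
  })
}

#' Cohort simulation configuration
#'
#' Covariate distributions mirror the reference cohort's summary table:
#' ages drawn from its decade-band frequencies (clamped to [30, 94]), BMI
#' and white-cell percentages from clamped normals at the reported
#' means/SDs, categorical covariates at the reported proportions. Parental
#' ages at death are sex-specific normals with a configurable fraction
#' planted below the premature cut-offs. Planted effects enter the
#' expression model as
#' `expr = 1 + confounder loadings + beta * outcome + N(0, noise_sd)`.
#'
#' @param n_participants cohort size (default 306).
#' @param n_circ number of circRNA expression columns (default 15).
#' @param planted_effects named list: circ_id -> list(outcome =
#'   "pls"|"age"|"grip_fu3"|"grip_fu4", beta = numeric). circRNAs without
#'   an entry get beta 0.
#' @param noise_sd residual SD of the expression model (default 0.2
#'   relative-expression units).
#' @param confounder_loadings list of per-covariate slopes entering every
#'   circRNA's expression (defaults: small BMI and neutrophil loadings);
#'   set to `list()` for none.
#' @param premature_fraction fraction of parental deaths planted below the
#'   premature cut-offs (default 0.05).
#' @param parent_missing_fraction fraction of parental ages missing.
#' @param seed integer RNG seed.
#' @return validated `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_participants = 306, n_circ = 15,
                              planted_effects = list(),
                              noise_sd = 0.2,
                              confounder_loadings = list(
                                bmi = 0.01, pct_neutrophils = 0.005),
                              premature_fraction = 0.05,
                              parent_missing_fraction = 0.05,
                              seed = 1L) {
  cfg <- list(n_participants = n_participants, n_circ = n_circ,
              planted_effects = planted_effects, noise_sd = noise_sd,
              confounder_loadings = confounder_loadings,
              premature_fraction = premature_fraction,
              parent_missing_fraction = parent_missing_fraction,
              seed = seed)
  assert_scalar_number(cfg$n_participants, "n_participants", min = 1,
                       integer = TRUE)
  assert_scalar_number(cfg$n_circ, "n_circ", min = 1, integer = TRUE)
  assert_scalar_number(cfg$noise_sd, "noise_sd", min = 0)
  assert_scalar_number(cfg$premature_fraction, "premature_fraction",
                       min = 0, max = 1)
  assert_scalar_number(cfg$parent_missing_fraction,
                       "parent_missing_fraction", min = 0, max = 1)
  assert_scalar_number(cfg$seed, "seed", integer = TRUE)
  for (pe in cfg$planted_effects) {
    if (!all(c("outcome", "beta") %in% names(pe)) ||
        !is.finite(pe$beta))
      stopf("each planted effect needs a finite 'beta' and an 'outcome'")
    if (!pe$outcome %in% c("pls", "age", "grip_fu3", "grip_fu4"))
      stopf("unsupported planted outcome '%s'", pe$outcome)
  }
  # listwise models fit ~13 parameters; require headroom
  if (cfg$n_participants < 30)
    stopf("n_participants = %d too small for the covariate set",
          cfg$n_participants)
  structure(cfg, class = "cohort_sim_config")
}

rnorm_clamped <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate an aging cohort with planted expression effects
#'
#' Draws covariates and phenotypes per [cohort_sim_config()], computes the
#' parental longevity score with [compute_pls()], then builds the
#' expression matrix with planted coefficients. Planted outcome values are
#' centered before entering the expression model (missing outcome values
#' contribute the mean, i.e. zero), so the intercept stays at 1.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `records` (cohort data.frame including `pls`,
#'   `grip_fu3`, `grip_fu4`), `expression` (participants x circRNAs
#'   matrix), and `truth` (the planted effect list, with zero-beta entries
#'   filled in).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_sim_config"))
    config <- do.call(cohort_sim_config, as.list(config))
  with_seed(config$seed, {
    n <- config$n_participants
    # decade-band age frequencies of the reference cohort
    bands <- list(c(30, 39), c(40, 49), c(50, 59), c(60, 69), c(70, 79),
                  c(80, 89), c(90, 94))
    band_p <- c(24, 37, 31, 32, 116, 63, 3) / 306
    bi <- sample.int(length(bands), n, replace = TRUE, prob = band_p)
    age <- vapply(bi, function(i)
      stats::runif(1, bands[[i]][1], bands[[i]][2]), 0)
    age <- round(pmin(pmax(age, 30), 94), 1)

    sex <- sample(SEX_LEVELS, n, replace = TRUE, prob = c(0.467, 0.533))
    site <- sample(SITE_LEVELS, n, replace = TRUE, prob = c(0.477, 0.523))
    education <- sample(EDUCATION_LEVELS, n, replace = TRUE,
                        prob = c(22, 124, 56, 50, 34, 20) / 306)
    smoking <- sample(SMOKING_LEVELS, n, replace = TRUE,
                      prob = c(164, 79, 43, 20) / 306)
    bmi <- round(rnorm_clamped(n, 27.15, 4.35, 15.01, 42.99), 2)
    wbc <- data.frame(
      pct_neutrophils = round(rnorm_clamped(n, 56.59, 8.35, 34.2, 81.2), 1),
      pct_lymphocytes = round(rnorm_clamped(n, 31.69, 7.67, 9.8, 51.2), 1),
      pct_monocytes = round(rnorm_clamped(n, 8.04, 2.20, 3.9, 21.3), 1),
      pct_eosinophils = round(rnorm_clamped(n, 3.18, 2.17, 0.0, 21.5), 1))

    parent_age <- function(mean, cutoff) {
      prem <- stats::runif(n) < config$premature_fraction
      x <- numeric(n)
      x[prem] <- stats::runif(sum(prem), 30, cutoff - 0.5)
      x[!prem] <- pmax(rnorm_clamped(sum(!prem), mean, 11, 35, 105),
                       cutoff)
      x[stats::runif(n) < config$parent_missing_fraction] <- NA
      round(x)
    }
    mother_death_age <- parent_age(74, 49)
    father_death_age <- parent_age(71, 52)

    grip_fu3 <- round(pmax(55 - 0.35 * age + 10 * (sex == "male") +
                             stats::rnorm(n, 0, 7), 2.5), 2)
    grip_fu4 <- round(pmax(grip_fu3 - 1 + stats::rnorm(n, 0, 3), 2.5), 2)

    records <- cbind(
      data.frame(participant_id = sprintf("P%04d", seq_len(n)),
                 age = age, sex = sex, bmi = bmi, education = education,
                 site = site, smoking = smoking,
                 stringsAsFactors = FALSE),
      wbc,
      data.frame(mother_death_age = mother_death_age,
                 father_death_age = father_death_age,
                 grip_fu3 = grip_fu3, grip_fu4 = grip_fu4))
    records$pls <- compute_pls(records)$pls

    circ_ids <- if (length(config$planted_effects) > 0 &&
                    !is.null(names(config$planted_effects))) {
      extra <- config$n_circ - length(config$planted_effects)
      c(names(config$planted_effects),
        if (extra > 0) sprintf("circSIM%02d", seq_len(extra)))
    } else sprintf("circSIM%02d", seq_len(config$n_circ))
    circ_ids <- utils::head(circ_ids, max(config$n_circ,
                                          length(config$planted_effects)))

    base <- rep(1, n)
    for (cv in names(config$confounder_loadings)) {
      v <- records[[cv]]
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      base <- base + config$confounder_loadings[[cv]] * (v - mean(v))
    }
    centered_outcome <- function(outcome) {
      v <- records[[outcome]]
      v <- v - mean(v, na.rm = TRUE)
      v[is.na(v)] <- 0
      v
    }
    expression <- sapply(circ_ids, function(id) {
      pe <- config$planted_effects[[id]]
      signal <- if (is.null(pe)) 0 else
        pe$beta * centered_outcome(pe$outcome)
      base + signal + stats::rnorm(n, 0, config$noise_sd)
    })
    expression <- matrix(expression, nrow = n,
                         dimnames = list(records$participant_id, circ_ids))

    truth <- lapply(stats::setNames(circ_ids, circ_ids), function(id) {
      pe <- config$planted_effects[[id]]
      if (is.null(pe)) list(outcome = NA_character_, beta = 0) else pe
    })
    list(records = records, expression = expression, truth = truth)
  })
}

#' Simulate senescence qPCR plates
#'
#' Ct values for `cell_types` x passage {early, late} x 3 biological x 3
#' technical replicates across the assay panel. Late-passage Ct equals the
#' early-passage baseline minus the planted shift (so a shift of +1
#' doubles late expression and -1 halves it) plus biological and
#' technical noise.
#'
#' @param planted_shifts data.frame with columns `circ_id`, `cell_type`,
#'   `shift` (Ct units); pairs without a row get shift 0.
#' @param assays character vector of assayed circRNA ids (default 15
#'   simulated ids).
#' @param cell_types cell-type labels (default astrocytes,
#'   cardiomyocytes, endothelial, fibroblasts).
#' @param n_bio,n_tech biological/technical replicates (defaults 3, 3).
#' @param baseline_ct mean early-passage Ct (default 26).
#' @param bio_sd,tech_sd replicate noise SDs in Ct units (defaults 0.15,
#'   0.1).
#' @param seed integer RNG seed.
#' @return long data.frame with columns `assay_id`, `cell_type`,
#'   `passage`, `biological_replicate`, `technical_replicate`, `ct`.
#' @export
simulate_senescence_qpcr <- function(planted_shifts = NULL,
                                     assays = sprintf("circSIM%02d", 1:15),
                                     cell_types = c("astrocytes",
                                                    "cardiomyocytes",
                                                    "endothelial",
                                                    "fibroblasts"),
                                     n_bio = 3, n_tech = 3,
                                     baseline_ct = 26, bio_sd = 0.15,
                                     tech_sd = 0.1, seed = 1L) {
  if (!is.null(planted_shifts)) {
    assert_columns(planted_shifts, c("circ_id", "cell_type", "shift"),
                   "planted_shifts")
    if (any(!is.finite(planted_shifts$shift)))
      stopf("planted shifts must be finite")
  }
  with_seed(seed, {
    grid <- expand.grid(assay_id = assays, cell_type = cell_types,
                        passage = c("early", "late"),
                        biological_replicate = seq_len(n_bio),
                        technical_replicate = seq_len(n_tech),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    shift <- rep(0, nrow(grid))
    if (!is.null(planted_shifts)) {
      key <- paste(grid$assay_id, grid$cell_type, sep = "\r")
      pkey <- paste(planted_shifts$circ_id, planted_shifts$cell_type,
                    sep = "\r")
      hit <- match(key, pkey)
      shift[!is.na(hit)] <- planted_shifts$shift[hit[!is.na(hit)]]
    }
    # assay- and cell-type-specific baselines, stable across replicates
    base_key <- unique(paste(grid$assay_id, grid$cell_type, sep = "\r"))
    base_ct <- stats::setNames(
      baseline_ct + stats::rnorm(length(base_key), 0, 0.5), base_key)
    bio_key <- paste(grid$assay_id, grid$cell_type, grid$passage,
                     grid$biological_replicate, sep = "\r")
    ubio <- unique(bio_key)
    bio_noise <- stats::setNames(stats::rnorm(length(ubio), 0, bio_sd),
                                 ubio)
    grid$ct <- base_ct[paste(grid$assay_id, grid$cell_type, sep = "\r")] -
      ifelse(grid$passage == "late", shift, 0) +
      bio_noise[bio_key] + stats::rnorm(nrow(grid), 0, tech_sd)
    rownames(grid) <- NULL
    grid
  })
}

#' Default placeholder strain lifespans
#'
#' Six divergent median strain lifespans (months) for the inbred panel.
#' The values are synthetic placeholders on a realistic scale, not
#' published strain medians; override with measured values where
#' available.
#'
#' @return named numeric vector of lifespans in months.
#' @export
default_strain_lifespans <- function() {
  c("A/J" = 22, "NOD.B10Sn-H2b/J" = 24, "PWD/PhJ" = 26,
    "129S1/SvImJ" = 28, "C57BL/6J" = 30, "WSB/EiJ" = 33)
}

#' Simulate a mouse qPCR panel
#'
#' Per strain x age group {young, old} x tissue {spleen, muscle}:
#' reference-gene Cts (three endogenous-control assays) and circRNA Cts
#' constructed so that reference-normalized expression has expectation
#' `intercept + slope * median strain lifespan`, with slopes planted per
#' (circRNA, tissue, age group). circRNAs can be marked undetected in a
#' tissue, yielding all-NA Cts there (the "ND" convention downstream).
#'
#' @param strain_lifespans named numeric vector strain -> median lifespan
#'   in months (>= 2 distinct strains).
#' @param planted_slopes data.frame with columns `circ_id`, `tissue`,
#'   `age_group` (`"young"`, `"old"` or `"all"`), `slope`; omitted
#'   combinations get slope 0.
#' @param circ_assays assayed circRNAs (default the four conserved ones).
#' @param detected named list tissue -> character vector of detected
#'   circRNAs; default: all four in spleen, `circFoxo3`/`circPlekhm1`
#'   only in muscle.
#' @param n_per_group animals per strain x age group (default 7).
#' @param intercept expected normalized expression at lifespan 0 before
#'   global scaling (default 1).
#' @param ref_ct mean reference-assay Ct (default 22).
#' @param bio_sd,tech_sd biological/technical Ct noise SDs (defaults
#'   0.12, 0.1).
#' @param seed integer RNG seed.
#' @return list with `panel` (long data.frame: `strain`,
#'   `lifespan_months`, `age_group`, `tissue`, `animal_id`, `assay_id`,
#'   `technical_replicate`, `ct`) and `truth` (the resolved slope table).
#' @export
simulate_mouse_panel <- function(strain_lifespans =
                                   default_strain_lifespans(),
                                 planted_slopes = NULL,
                                 circ_assays = c("circFoxo3", "circMib1",
                                                 "circPlekhm1",
                                                 "circXpo7"),
                                 detected = list(
                                   spleen = c("circFoxo3", "circMib1",
                                              "circPlekhm1", "circXpo7"),
                                   muscle = c("circFoxo3",
                                              "circPlekhm1")),
                                 n_per_group = 7, intercept = 1,
                                 ref_ct = 22, bio_sd = 0.12,
                                 tech_sd = 0.1, seed = 1L) {
  if (length(strain_lifespans) < 2L ||
      length(unique(strain_lifespans)) < 2L)
    stopf("need at least 2 strains with distinct lifespans")
  if (is.null(names(strain_lifespans)))
    stopf("'strain_lifespans' must be named by strain")
  if (!is.null(planted_slopes))
    assert_columns(planted_slopes, c("circ_id", "tissue", "age_group",
                                     "slope"), "planted_slopes")
  ref_assays <- c("Pol2ra", "Trfc", "Ipo8")
  tissues <- names(detected)
  with_seed(seed, {
    animals <- expand.grid(strain = names(strain_lifespans),
                           age_group = c("young", "old"),
                           rep = seq_len(n_per_group),
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
    animals$animal_id <- sprintf("m%03d", seq_len(nrow(animals)))
    animals$lifespan_months <- strain_lifespans[animals$strain]

    slope_for <- function(circ, tissue, age_group) {
      if (is.null(planted_slopes)) return(0)
      hit <- planted_slopes$circ_id == circ &
        planted_slopes$tissue == tissue &
        (planted_slopes$age_group == age_group |
           planted_slopes$age_group == "all")
      if (any(hit)) sum(planted_slopes$slope[hit]) else 0
    }

    all_assays <- c(ref_assays, circ_assays)
    # one biological Ct level per (tissue, animal, assay), then three
    # technical replicates around it
    bio <- expand.grid(tissue = tissues, idx = seq_len(nrow(animals)),
                       assay_id = all_assays, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    bio <- bio[order(bio$tissue, bio$idx,
                     match(bio$assay_id, all_assays)), ]
    bio_noise <- stats::rnorm(nrow(bio), 0, bio_sd)

    is_ref <- bio$assay_id %in% ref_assays
    base_ct <- rep(NA_real_, nrow(bio))
    base_ct[is_ref] <- ref_ct + bio_noise[is_ref]
    # per (tissue, animal) mean of the reference-assay biological levels
    grp <- paste(bio$tissue, bio$idx)
    ref_mean <- tapply(base_ct[is_ref], grp[is_ref], mean)

    ag <- animals$age_group[bio$idx]
    ls <- animals$lifespan_months[bio$idx]
    circ_rows <- which(!is_ref)
    for (i in circ_rows) {
      if (bio$assay_id[i] %in% detected[[bio$tissue[i]]]) {
        target <- max(intercept +
                        slope_for(bio$assay_id[i], bio$tissue[i],
                                  ag[i]) * ls[i], 1e-6)
        base_ct[i] <- ref_mean[[grp[i]]] - log2(target) + bio_noise[i]
      }
    }

    panel <- bio[rep(seq_len(nrow(bio)), each = 3), ]
    panel$technical_replicate <- rep(1:3, nrow(bio))
    panel$ct <- rep(base_ct, each = 3) +
      ifelse(is.na(rep(base_ct, each = 3)), NA,
             stats::rnorm(nrow(panel), 0, tech_sd))
    panel$strain <- animals$strain[panel$idx]
    panel$lifespan_months <- animals$lifespan_months[panel$idx]
    panel$age_group <- animals$age_group[panel$idx]
    panel$animal_id <- paste0(animals$animal_id[panel$idx], "_",
                              panel$tissue)
    panel <- panel[, c("strain", "lifespan_months", "age_group",
                       "tissue", "animal_id", "assay_id",
                       "technical_replicate", "ct")]
    rownames(panel) <- NULL
    truth <- expand.grid(circ_id = circ_assays, tissue = tissues,
                         age_group = c("young", "old"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth$slope <- mapply(slope_for, truth$circ_id, truth$tissue,
                          truth$age_group)
    list(panel = panel, truth = truth)
  })
}
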