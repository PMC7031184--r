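# Configuration handling and the end-to-end pipeline driver. A config is
# a plain nested list (JSON on disk); validate_config() fills defaults,
# rejects unknown keys and range errors, and run_pipeline() executes the
# stages in dependency order, writing TSV outputs plus a deterministic
# manifest.

#' Default pipeline configuration
#'
#' All tunables with their defaults. Stage toggles select which parts of
#' the pipeline run; the `simulate` stage feeds every downstream stage
#' unless explicit input paths are given.
#'
#' @return nested list of defaults (a valid configuration).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    stages = list(simulate = TRUE, quantify = TRUE, classify = TRUE,
                  phenotype = TRUE, associate = TRUE, senescence = TRUE,
                  mouse = TRUE),
    quantify = list(min_bsj_reads = 2L, canonical = "per_circ"),
    classify = list(k_per_class = 5L, top_fraction = 0.10),
    associate = list(alpha = 0.05, decimals = 3L),
    pool = list(n_shared = 184L, n_young_only = 431L, n_old_only = 1592L,
                mean_bsj_reads = 60, dispersion = 0.2,
                canonical_mean = 400, rnase_r_linear_retention = 0.05,
                rnase_r_circ_enrichment = 5, fc_sd = 1.5),
    cohort = list(n_participants = 306L, n_circ = 15L, noise_sd = 0.2,
                  premature_fraction = 0.05,
                  parent_missing_fraction = 0.05,
                  planted_pls_beta = -0.065),
    senescence = list(shift_ct = 1, n_shifted = 2),
    mouse = list(n_per_group = 7L, planted_slope = 0.0025,
                 slope_circ = "circPlekhm1", slope_tissue = "spleen",
                 slope_age_group = "young"),
    paths = list(gene_sets = NULL)
  )
}

merge_config <- function(defaults, user, prefix = "", errors) {
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(defaults)) {
      errors$msgs <- c(errors$msgs, sprintf("unknown key '%s'", full))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]])) {
        errors$msgs <- c(errors$msgs,
                         sprintf("'%s' must be a section (object)", full))
      } else {
        defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                        full, errors)
      }
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

check_range <- function(cfg, errors) {
  chk <- function(val, name, min = -Inf, max = Inf, integer = FALSE) {
    ok <- is.numeric(val) && length(val) == 1L && !is.na(val) &&
      val >= min && val <= max && (!integer || val == floor(val))
    if (!ok)
      errors$msgs <- c(errors$msgs,
                       sprintf("'%s' out of range or wrong type", name))
    errors
  }
  errors <- chk(cfg$seed, "seed", integer = TRUE)
  errors <- chk(cfg$quantify$min_bsj_reads, "quantify.min_bsj_reads",
                min = 0, integer = TRUE)
  errors <- chk(cfg$classify$k_per_class, "classify.k_per_class", min = 1,
                integer = TRUE)
  errors <- chk(cfg$classify$top_fraction, "classify.top_fraction",
                min = 1e-9, max = 1)
  errors <- chk(cfg$associate$alpha, "associate.alpha", min = 1e-12,
                max = 1)
  errors <- chk(cfg$associate$decimals, "associate.decimals", min = 0,
                integer = TRUE)
  errors <- chk(cfg$cohort$n_participants, "cohort.n_participants",
                min = 30, integer = TRUE)
  if (!identical(cfg$quantify$canonical, "per_circ") &&
      !identical(cfg$quantify$canonical, "per_gene"))
    errors$msgs <- c(errors$msgs,
                     "'quantify.canonical' must be per_circ or per_gene")
  if (!is.null(cfg$paths$gene_sets) && !file.exists(cfg$paths$gene_sets))
    errors$msgs <- c(errors$msgs,
                     sprintf("'paths.gene_sets' does not exist: %s",
                             cfg$paths$gene_sets))
  errors
}

#' Validate a pipeline configuration
#'
#' Accepts a path to a JSON config file, a list, or NULL (pure defaults).
#' Unknown keys, out-of-range values and missing paths are aggregated
#' into a single error report.
#'
#' @param config NULL, a nested list, or a path to a JSON file. An empty
#'   file or empty list yields the pure defaults.
#' @return a fully-defaulted, range-checked `pipeline_config` list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- if (!nzchar(trimws(txt))) list() else
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stopf("config must be a list or a JSON file")
  errors <- new.env()
  errors$msgs <- character()
  cfg <- merge_config(default_config(), config, "", errors)
  errors <- check_range(cfg, errors)
  if (length(errors$msgs) > 0L)
    stopf("invalid configuration:\n  - %s",
          paste(errors$msgs, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("pipeline_config", "list"))
}

canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)))
      v <- lapply(v[order(names(v))], sort_rec)
    v
  }
  as.character(jsonlite::toJSON(sort_rec(unclass(x)), auto_unbox = TRUE,
                                null = "null", digits = NA))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order (simulate, quantify,
#' classify, phenotype, associate incl. senescence and mouse layers),
#' writing every output table as TSV into `outdir` together with a
#' `manifest.json` recording the config fingerprint, master seed, stage
#' status and per-file row counts. The manifest carries no timestamps, so
#' re-running with the same config reproduces it byte-identically.
#'
#' @param config a `pipeline_config` from [validate_config()] (or
#'   anything it accepts).
#' @param outdir output directory; created if needed.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, outdir = "circage_run") {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = fnv1a32(canonical_json(cfg)),
                   seed = cfg$seed, stages = list(), outputs = list())
  emit <- function(df, name) {
    write_tsv_file(df, file.path(outdir, name))
    manifest$outputs[[name]] <<- list(rows = nrow(df))
  }
  mark <- function(stage, status) manifest$stages[[stage]] <<- status
  finish <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }

  run_stage <- function(stage, fn) {
    if (!isTRUE(cfg$stages[[stage]])) {
      mark(stage, "skipped")
      return(invisible(NULL))
    }
    result <- tryCatch(fn(), error = function(e) e)
    if (inherits(result, "error")) {
      mark(stage, paste0("failed: ", conditionMessage(result)))
      finish()
      stopf("stage '%s' failed: %s", stage, conditionMessage(result))
    }
    mark(stage, "ok")
    result
  }

  env <- new.env()

  run_stage("simulate", function() {
    pool_cfg <- do.call(pool_sim_config,
                        c(cfg$pool, list(seed = derive_seed(cfg$seed, 1))))
    env$pool <- simulate_pool_counts(pool_cfg)
    emit(env$pool$table, "junction_counts.tsv")
    emit(data.frame(circ_id = names(env$pool$truth$class_of),
                    class = unname(env$pool$truth$class_of)),
         "ground_truth_classes.tsv")

    effects <- list()
    if (!is.null(cfg$cohort$planted_pls_beta))
      effects$circSIM01 <- list(outcome = "pls",
                                beta = cfg$cohort$planted_pls_beta)
    cohort_cfg <- cohort_sim_config(
      n_participants = cfg$cohort$n_participants,
      n_circ = cfg$cohort$n_circ,
      planted_effects = effects,
      noise_sd = cfg$cohort$noise_sd,
      premature_fraction = cfg$cohort$premature_fraction,
      parent_missing_fraction = cfg$cohort$parent_missing_fraction,
      seed = derive_seed(cfg$seed, 2))
    env$cohort <- simulate_cohort(cohort_cfg)
    emit(env$cohort$records, "cohort.tsv")
    emit(data.frame(participant_id = rownames(env$cohort$expression),
                    env$cohort$expression, check.names = FALSE),
         "cohort_expression.tsv")

    if (isTRUE(cfg$stages$senescence)) {
      assays <- colnames(env$cohort$expression)
      n_sh <- min(cfg$senescence$n_shifted, length(assays))
      shifts <- data.frame(circ_id = utils::head(assays, n_sh),
                           cell_type = "fibroblasts",
                           shift = cfg$senescence$shift_ct)
      env$sen_ct <- simulate_senescence_qpcr(
        planted_shifts = shifts, assays = assays,
        seed = derive_seed(cfg$seed, 3))
      emit(env$sen_ct, "senescence_ct.tsv")
    }

    if (isTRUE(cfg$stages$mouse)) {
      slopes <- data.frame(circ_id = cfg$mouse$slope_circ,
                           tissue = cfg$mouse$slope_tissue,
                           age_group = cfg$mouse$slope_age_group,
                           slope = cfg$mouse$planted_slope)
      env$mouse <- simulate_mouse_panel(
        planted_slopes = slopes, n_per_group = cfg$mouse$n_per_group,
        seed = derive_seed(cfg$seed, 4))
      emit(env$mouse$panel, "mouse_panel.tsv")
    }
    TRUE
  })

  run_stage("quantify", function() {
    env$bpm_young <- compute_bpm(env$pool$table, "young_treated",
                                 canonical = cfg$quantify$canonical)
    env$bpm_old <- compute_bpm(env$pool$table, "old_treated",
                               canonical = cfg$quantify$canonical)
    emit(env$bpm_young, "bpm_young_treated.tsv")
    emit(env$bpm_old, "bpm_old_treated.tsv")
    env$presence_young <- call_presence(env$bpm_young,
                                        cfg$quantify$min_bsj_reads)
    env$presence_old <- call_presence(env$bpm_old,
                                      cfg$quantify$min_bsj_reads)
    TRUE
  })

  run_stage("classify", function() {
    env$classes <- partition_classes(env$presence_young,
                                     env$presence_old,
                                     env$bpm_young, env$bpm_old)
    emit(as.data.frame(env$classes), "class_table.tsv")
    candidates <- select_candidates(env$classes,
                                    cfg$classify$k_per_class)
    emit(candidates, "candidates.tsv")
    hosts_young <- top_decile_hosts(env$bpm_young,
                                    cfg$classify$top_fraction)
    hosts_old <- top_decile_hosts(env$bpm_old, cfg$classify$top_fraction)
    emit(data.frame(pool = rep(c("young", "old"),
                               c(length(hosts_young),
                                 length(hosts_old))),
                    host_gene = c(hosts_young, hosts_old)),
         "top_decile_hosts.tsv")
    if (!is.null(cfg$paths$gene_sets)) {
      sets <- read_gmt(cfg$paths$gene_sets)
      universe <- unique(c(env$bpm_young$host_gene,
                           env$bpm_old$host_gene))
      enr <- enrich_gene_sets(intersect(hosts_old, universe), sets,
                              universe)
      emit(enr, "enrichment_old.tsv")
    }
    TRUE
  })

  run_stage("phenotype", function() {
    env$pls <- compute_pls(env$cohort$records)
    emit(env$pls, "pls.tsv")
    TRUE
  })

  run_stage("associate", function() {
    assoc <- do.call(rbind, lapply(
      c("age", "pls", "grip_cross_sectional", "grip_longitudinal"),
      function(o) fit_phenotype_association(
        env$cohort$expression, env$cohort$records, outcome = o,
        alpha = cfg$associate$alpha)))
    emit(assoc, "associations.tsv")

    if (isTRUE(cfg$stages$senescence)) {
      sen <- do.call(rbind, lapply(unique(env$sen_ct$cell_type),
                                   function(ctype) {
        senescence_compare(env$sen_ct[env$sen_ct$cell_type == ctype, ],
                           cell_type = ctype)
      }))
      emit(sen, "senescence_results.tsv")
      counts <- count_dysregulated(sen, cfg$associate$alpha)
      manifest$dysregulation <<- counts
    }

    if (isTRUE(cfg$stages$mouse)) {
      combos <- expand.grid(tissue = unique(env$mouse$panel$tissue),
                            stratum = c("all", "young", "old"),
                            stringsAsFactors = FALSE)
      mres <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
        mouse_lifespan_association(env$mouse$panel, combos$tissue[i],
                                   combos$stratum[i],
                                   alpha = cfg$associate$alpha)))
      emit(mres, "mouse_associations.tsv")
    }
    TRUE
  })

  mark("senescence",
       if (isTRUE(cfg$stages$senescence)) "ok" else "skipped")
  mark("mouse", if (isTRUE(cfg$stages$mouse)) "ok" else "skipped")

  finish()
}
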