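# Independent oracles and fixture builders used across the test files.

# Exhaustive-enumeration hypergeometric oracle: probability of observing
# at least / at most k set members when drawing q genes from a universe
# of N genes containing m set members. Enumerates all C(N, q) draws, so
# only usable for tiny N.
hyper_oracle <- function(N, m, q, k) {
  draws <- utils::combn(N, q)
  in_set <- draws <= m  # genes 1..m are the set members
  overlap <- colSums(in_set)
  list(p_enrich = mean(overlap >= k), p_deplete = mean(overlap <= k))
}

# Small junction count table with explicit values for hand oracles.
make_junction_table <- function(j, c, library_id = "lib",
                                genes = paste0("g", seq_along(j))) {
  data.frame(circ_id = paste0("circ", seq_along(j)),
             host_gene = genes,
             chrom = "chr1",
             junction_start = seq_along(j) * 1000L,
             junction_end = seq_along(j) * 1000L + 500L,
             library_id = library_id,
             bsj_reads = j,
             canonical_reads = c,
             stringsAsFactors = FALSE)
}

# Random junction table for property tests.
random_junction_table <- function(n, library_id = "lib") {
  make_junction_table(j = sample(0:500, n, replace = TRUE),
                      c = sample(0:2000, n, replace = TRUE),
                      library_id = library_id)
}

# Minimal cohort record constructor with sensible defaults.
make_cohort_records <- function(n, age = 70, sex = "female",
                                bmi = 27, education = "elementary",
                                site = "Greve", smoking = "none",
                                mother_death_age = NA,
                                father_death_age = NA,
                                grip_fu3 = 30, grip_fu4 = 29,
                                pct_neutrophils = 56,
                                pct_lymphocytes = 31,
                                pct_monocytes = 8,
                                pct_eosinophils = 3) {
  data.frame(participant_id = sprintf("P%03d", seq_len(n)),
             age = rep_len(age, n), sex = rep_len(sex, n),
             bmi = rep_len(bmi, n), education = rep_len(education, n),
             site = rep_len(site, n), smoking = rep_len(smoking, n),
             pct_neutrophils = rep_len(pct_neutrophils, n),
             pct_lymphocytes = rep_len(pct_lymphocytes, n),
             pct_monocytes = rep_len(pct_monocytes, n),
             pct_eosinophils = rep_len(pct_eosinophils, n),
             mother_death_age = rep_len(mother_death_age, n),
             father_death_age = rep_len(father_death_age, n),
             grip_fu3 = rep_len(grip_fu3, n),
             grip_fu4 = rep_len(grip_fu4, n),
             stringsAsFactors = FALSE)
}

# Cohort records with variation in every covariate, so regression
# designs are full rank. Uses the current RNG stream.
make_varying_records <- function(n) {
  make_cohort_records(
    n,
    age = runif(n, 40, 90),
    sex = sample(c("male", "female"), n, replace = TRUE),
    bmi = runif(n, 18, 38),
    education = sample(c("none", "elementary", "secondary",
                         "high school", "professional school",
                         "university"), n, replace = TRUE),
    site = sample(c("Greve", "Bagno"), n, replace = TRUE),
    smoking = sample(c("none", "<20", "20-39", "40+"), n,
                     replace = TRUE),
    pct_neutrophils = runif(n, 40, 75),
    pct_lymphocytes = runif(n, 15, 45),
    pct_monocytes = runif(n, 4, 12),
    pct_eosinophils = runif(n, 0, 8),
    grip_fu3 = runif(n, 10, 60),
    grip_fu4 = runif(n, 10, 60))
}

# Long-format Ct data from an assays x samples matrix, one technical
# replicate per cell.
ct_long <- function(ct_matrix) {
  df <- expand.grid(assay_id = rownames(ct_matrix),
                    sample_id = colnames(ct_matrix),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$technical_replicate <- 1L
  df$ct <- ct_matrix[cbind(df$assay_id, df$sample_id)]
  df
}

# The published early/late passage significance table used as a worked
# example for dysregulation counting: per (circRNA, cell type) p-values
# for the 12 expressed circRNAs; circBCL11B, circDEF6 and circITGAX were
# not expressed in any of the four cell types.
table5_fixture <- function() {
  path <- system.file("extdata", "senescence_pvalues.tsv",
                      package = "circage")
  read.delim(path, stringsAsFactors = FALSE)
}
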