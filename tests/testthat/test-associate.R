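test_that("qPCR normalization identities hold", {
  # flat matrix: every relative expression is 1
  flat <- matrix(25, 3, 4, dimnames = list(paste0("a", 1:3),
                                           paste0("s", 1:4)))
  norm <- normalize_qpcr(ct_long(flat))
  expect_equal(unname(norm$expression), matrix(1, 3, 4))
  # per-assay geometric mean across samples is exactly 1
  set.seed(5)
  m <- matrix(rnorm(20, 26, 2), 4, 5,
              dimnames = list(paste0("a", 1:4), paste0("s", 1:5)))
  norm2 <- normalize_qpcr(ct_long(m))
  gm <- apply(norm2$expression, 1, function(x) exp(mean(log(x))))
  expect_equal(unname(gm), rep(1, 4), tolerance = 1e-10)
})

test_that("2x2 normalization matches a spreadsheet-style hand oracle", {
  # one cell lowered by 1 cycle
  m <- matrix(c(25, 25, 25, 24), 2, 2,
              dimnames = list(c("a1", "a2"), c("s1", "s2")))
  norm <- normalize_qpcr(ct_long(m))
  # hand evaluation of steps 1-4:
  sample_means <- colMeans(m)                    # 25, 24.5
  dct <- sweep(m, 2, sample_means)               # 0 0 / .5 -.5
  e <- 2^(-dct)
  e <- sweep(e, 1, apply(e, 1, function(x) exp(mean(log(x)))), "/")
  expect_equal(norm$expression, e, tolerance = 1e-12)
  # the 1-cycle drop splits across the per-sample mean: dCt = (0, -0.5),
  # then the geometric-mean scaling centres the pair at 2^(+-0.25)
  expect_equal(unname(norm$expression["a2", ]), c(2^-0.25, 2^0.25),
               tolerance = 1e-12)
})

test_that("normalization is invariant to sample order and collapses
           technical replicates by median", {
  set.seed(6)
  m <- matrix(rnorm(12, 26, 1), 3, 4,
              dimnames = list(paste0("a", 1:3), paste0("s", 1:4)))
  long <- ct_long(m)
  perm <- long[sample(nrow(long)), ]
  n1 <- normalize_qpcr(long)
  n2 <- normalize_qpcr(perm)
  expect_equal(n1$expression[rownames(n2$expression),
                             colnames(n2$expression)],
               n2$expression, tolerance = 1e-12)
  # technical replicates: median of {24, 25, 40} is 25
  reps <- rbind(
    data.frame(assay_id = "a1", sample_id = "s1",
               technical_replicate = 1:3, ct = c(24, 25, 40)),
    data.frame(assay_id = "a1", sample_id = "s2",
               technical_replicate = 1, ct = 26),
    data.frame(assay_id = "a2", sample_id = c("s1", "s2"),
               technical_replicate = 1, ct = c(30, 30)))
  n3 <- normalize_qpcr(reps)
  expect_equal(n3$ct_median["a1", "s1"], 25)
})

test_that("normalization drops empty samples and flags sparse assays", {
  m <- matrix(c(25, 26, NA, NA, 24, NA, 26, NA), 2, 4,
              dimnames = list(c("a1", "a2"),
                              c("s1", "s2", "s3", "s4")))
  # s2 has no signal at all; a2 is present only in s1 (1 of 3 retained)
  expect_warning(expect_warning(norm <- normalize_qpcr(ct_long(m)),
                                "dropping sample"), "50%")
  expect_equal(norm$dropped_samples, "s2")
  expect_equal(norm$flagged_assays, "a2")
  expect_error(normalize_qpcr(ct_long(m[1, , drop = FALSE])),
               "at least 2 assays")
  bad <- ct_long(m)
  bad$ct[1] <- 60
  expect_error(normalize_qpcr(bad), "\\(0, 50\\]")
})

test_that("bonferroni_threshold reports rounded values, flags on raw", {
  expect_equal(bonferroni_threshold(0.05, 15)$reported, 0.003)
  expect_equal(bonferroni_threshold(0.05, 4)$reported, 0.013)
  expect_equal(bonferroni_threshold(0.05, 1)$reported, 0.05)
  expect_equal(bonferroni_threshold(0.05, 15)$raw, 0.05 / 15)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})

test_that("noise-free synthetic outcome recovers the coefficient exactly", {
  set.seed(8)
  rec <- make_varying_records(60)
  expr <- rnorm(60, 1, 0.3)
  rec$grip_fu3 <- 0.5 * expr + 0.2 * rec$bmi + 0.1 * rec$age +
    2 * (rec$sex == "male")
  # lm warns about the essentially perfect fit; that is the point here
  res <- suppressWarnings(
    fit_phenotype_association(expr, rec, "grip_cross_sectional"))
  expect_equal(res$beta, 0.5, tolerance = 1e-10)
  expect_equal(res$orientation, "outcome_dependent")
})

test_that("association matches a brute-force normal-equations solution", {
  set.seed(9)
  rec <- make_varying_records(50)
  rec$pls <- rnorm(50)
  expr <- 1 - 0.06 * rec$pls + rnorm(50, 0, 0.2)
  res <- fit_phenotype_association(expr, rec, "pls")
  expect_equal(res$orientation, "expression_dependent")

  cov <- build_covariates(rec, model = "pls")
  X <- cbind(1, rec$pls, as.matrix(cov))
  beta_hat <- solve(t(X) %*% X, t(X) %*% expr)
  resid <- expr - X %*% beta_hat
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * solve(t(X) %*% X)[2, 2])
  expect_equal(res$beta, beta_hat[2], tolerance = 1e-8)
  expect_equal(res$se, se, tolerance = 1e-8)
  tcrit <- qt(0.975, df)
  expect_equal(res$ci_low, beta_hat[2] - tcrit * se, tolerance = 1e-8)
  expect_equal(res$ci_high, beta_hat[2] + tcrit * se, tolerance = 1e-8)
})

test_that("listwise deletion and significance flags are consistent", {
  set.seed(10)
  rec <- make_varying_records(60)
  rec$pls <- rnorm(60)
  rec$bmi[1:5] <- NA
  expr <- matrix(rnorm(180, 1, 0.2), 60, 3,
                 dimnames = list(NULL, paste0("c", 1:3)))
  res <- fit_phenotype_association(expr, rec, "pls")
  expect_true(all(res$n_used == 55))
  thr <- attr(res, "bonferroni")
  expect_equal(res$significant_adjusted, res$p < thr$raw)
  expect_true(all(res$ci_low <= res$beta & res$beta <= res$ci_high))
  # collinear covariates are named
  rec2 <- make_varying_records(40)
  rec2$pls <- rnorm(40)
  rec2$pct_lymphocytes <- rec2$pct_neutrophils
  expect_error(
    fit_phenotype_association(rnorm(40), rec2, "pls"),
    "collinear")
})

test_that("two-group ANOVA equals the pooled t-test (t^2 = F)", {
  set.seed(12)
  for (i in 1:100) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    x <- rnorm(n1 + n2)
    g <- rep(c("a", "b"), c(n1, n2))
    a <- circage:::anova_two_group(x, g)
    tt <- t.test(x ~ g, var.equal = TRUE)
    expect_equal(a$p, tt$p.value, tolerance = 1e-12)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("senescence_compare handles degenerate and missing groups", {
  # identical values in both groups: F = 0, p = 1
  ct <- expand.grid(assay_id = c("a1", "a2"), passage = c("early", "late"),
                    biological_replicate = 1:3, technical_replicate = 1,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ct$ct <- 25
  res <- senescence_compare(ct, "fibroblasts")
  expect_equal(res$p, c(1, 1))
  expect_equal(res$median_early, res$median_late)
  # an assay with no late-passage signal is marked not expressed
  ct2 <- ct
  ct2$ct[ct2$assay_id == "a1" & ct2$passage == "late"] <- NA
  ct2 <- rbind(ct2, within(ct, assay_id <- "a3"))
  res2 <- senescence_compare(ct2, "fibroblasts")
  expect_false(res2$expressed[res2$circ_id == "a1"])
  expect_true(is.na(res2$p[res2$circ_id == "a1"]))
})

test_that("a planted -1 Ct late shift is detected with high power", {
  shifts <- data.frame(circ_id = "circSIM01", cell_type = "fibroblasts",
                       shift = -1)
  hits <- 0L
  for (r in 1:100) {
    ct <- simulate_senescence_qpcr(shifts, cell_types = "fibroblasts",
                                   seed = 5000 + r)
    res <- senescence_compare(ct, "fibroblasts")
    hits <- hits + (res$p[res$circ_id == "circSIM01"] < 0.05)
  }
  expect_gt(hits, 90)
})

test_that("count_dysregulated uses distinct-count semantics", {
  res <- data.frame(circ_id = c("c1", "c1", "c2", "c3"),
                    cell_type = c("f", "a", "f", "f"),
                    p = c(0.01, 0.02, 0.9, NA),
                    expressed = c(TRUE, TRUE, TRUE, FALSE))
  out <- count_dysregulated(res)
  expect_equal(out$n_expressed, 2)
  expect_equal(out$n_dysregulated, 1)   # c1 counted once
  expect_equal(out$fraction_percent, 50)
  # all p = 1: nothing dysregulated
  res$p <- 1
  expect_equal(count_dysregulated(res)$n_dysregulated, 0)
  # invariant to row order and duplicated rows
  res2 <- data.frame(circ_id = c("c1", "c2"), cell_type = "f",
                     p = c(0.01, 0.5), expressed = TRUE)
  shuffled <- rbind(res2[2:1, ], res2)
  expect_equal(count_dysregulated(shuffled),
               count_dysregulated(res2))
})

test_that("mouse association reports ND and validates inputs", {
  sim <- simulate_mouse_panel(seed = 31)
  res <- mouse_lifespan_association(sim$panel, "muscle", "all")
  nd <- res[res$circ_id %in% c("circMib1", "circXpo7"), ]
  expect_true(all(!nd$detected))
  expect_true(all(is.na(nd$beta)))
  det <- res[res$detected, ]
  expect_true(all(is.finite(det$beta)))
  expect_true(all(det$ci_low <= det$beta & det$beta <= det$ci_high))
  expect_error(mouse_lifespan_association(sim$panel, "kidney"),
               "absent")
  expect_error(
    simulate_mouse_panel(strain_lifespans = c(X = 20), seed = 1),
    "at least 2 strains")
})
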