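make_class_table <- function(circ_id, class, bpm_young, bpm_old,
                             D_young = 1e6, D_old = 1e6) {
  out <- data.frame(circ_id = circ_id, host_gene = paste0("g", circ_id),
                    class = class, bpm_young = bpm_young,
                    bpm_old = bpm_old, stringsAsFactors = FALSE)
  attr(out, "D_young") <- D_young
  attr(out, "D_old") <- D_old
  class(out) <- c("circ_class_table", "data.frame")
  out
}

test_that("partition_classes assigns each circRNA to exactly one class", {
  tab <- rbind(make_junction_table(j = c(10, 10, 0), c = c(5, 5, 5),
                                   library_id = "yt"),
               make_junction_table(j = c(0, 10, 10), c = c(5, 5, 5),
                                   library_id = "ot"))
  py <- compute_bpm(tab, "yt")
  po <- compute_bpm(tab, "ot")
  cl <- partition_classes(call_presence(py), call_presence(po), py, po)
  expect_equal(cl$class[match(c("circ1", "circ2", "circ3"), cl$circ_id)],
               c("young_only", "shared", "old_only"))
  # partition completeness
  expect_equal(sum(attr(cl, "class_counts")),
               length(union(call_presence(py), call_presence(po))))
  # identical presence sets mean everything is shared
  cl2 <- partition_classes(call_presence(py), call_presence(py), py, po)
  expect_true(all(cl2$class == "shared"))
  expect_warning(partition_classes(character(), character(), py, po),
                 "empty")
})

test_that("rank_shared_differential orders by |log2 fold change|", {
  ct <- make_class_table(c("a", "b", "c"), "shared",
                         bpm_young = c(10, 20, 50),
                         bpm_old = c(80, 40, 50))
  ranked <- rank_shared_differential(ct, eps = 1e-9)
  # |fc| = 3, 1, ~0
  expect_equal(ranked$circ_id, c("a", "b", "c"))
  expect_equal(ranked$log2_fc[1:2], c(3, 1), tolerance = 1e-6)
  # equal bpm ranks last with fc 0
  expect_equal(ranked$log2_fc[3], 0, tolerance = 1e-6)
  # swapping pools negates fold changes but preserves the ranking
  swapped <- make_class_table(c("a", "b", "c"), "shared",
                              bpm_young = c(80, 40, 50),
                              bpm_old = c(10, 20, 50))
  r2 <- rank_shared_differential(swapped, eps = 1e-9)
  expect_equal(r2$circ_id, ranked$circ_id)
  expect_equal(r2$log2_fc, -ranked$log2_fc, tolerance = 1e-6)
})

test_that("fold-change pseudocount derives from the smaller library", {
  ct <- make_class_table("a", "shared", bpm_young = 0, bpm_old = 100,
                         D_young = 2e6, D_old = 1e6)
  ranked <- rank_shared_differential(ct)
  # eps = 1e6 / min(D) = 1; log2((100 + 1) / 1)
  expect_equal(attr(ranked, "eps"), 1)
  expect_equal(ranked$log2_fc, log2(101))
})

test_that("select_candidates takes top-k per class in documented order", {
  ct <- make_class_table(
    sprintf("c%02d", 1:9),
    rep(c("young_only", "old_only", "shared"), each = 3),
    bpm_young = c(30, 10, 20, 0, 0, 0, 10, 10, 45),
    bpm_old = c(0, 0, 0, 5, 25, 15, 80, 11, 50))
  sel <- select_candidates(ct, 2)
  expect_equal(nrow(sel), 6)
  expect_equal(sel$class, rep(c("young_only", "old_only", "shared"),
                              each = 2))
  expect_equal(sel$circ_id[1:2], c("c01", "c03"))  # by bpm_young
  expect_equal(sel$circ_id[3:4], c("c05", "c06"))  # by bpm_old
  expect_equal(sel$circ_id[5], "c07")              # biggest |fc|
  # k larger than every class takes all, warning once per short class
  expect_warning(expect_warning(expect_warning(
    all_sel <- select_candidates(ct, 5),
    "taking all"), "taking all"), "taking all")
  expect_equal(nrow(all_sel), 9)
  expect_error(select_candidates(ct, 0), "k_per_class")
  # single-member classes select that member
  ct1 <- make_class_table(c("y", "o", "s"),
                          c("young_only", "old_only", "shared"),
                          bpm_young = c(5, 0, 9),
                          bpm_old = c(0, 7, 2))
  expect_equal(select_candidates(ct1, 1)$circ_id, c("y", "o", "s"))
})

test_that("top_decile_hosts applies the ceiling rule and deduplicates", {
  prof <- make_junction_table(j = 20:1, c = rep(0, 20))
  p <- compute_bpm(prof, "lib")
  expect_length(top_decile_hosts(p), 2)          # ceil(2.0)
  p15 <- compute_bpm(make_junction_table(j = 15:1, c = rep(0, 15)), "lib")
  expect_length(top_decile_hosts(p15), 2)        # ceil(1.5)
  # two top circRNAs sharing a host collapse to one gene
  shared_host <- make_junction_table(j = c(100, 90, 1, 1, 1, 1, 1, 1, 1,
                                           1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                                           1),
                                     c = rep(0, 20),
                                     genes = c("gX", "gX",
                                               paste0("g", 3:20)))
  ph <- compute_bpm(shared_host, "lib")
  expect_equal(top_decile_hosts(ph), "gX")
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # worked example: N=10, m=5, q=3, k=3
  res <- enrich_gene_sets(paste0("g", 1:3),
                          list(s = paste0("g", 1:5)), paste0("g", 1:10))
  expect_equal(res$p_enrich, 10 / 120)
  # random tiny instances against the enumeration oracle
  set.seed(11)
  for (i in 1:30) {
    N <- sample(4:12, 1)
    m <- sample(1:(N - 1), 1)
    q <- sample(1:(N - 1), 1)
    universe <- paste0("g", 1:N)
    set_genes <- paste0("g", 1:m)
    query <- sample(universe, q)
    res <- enrich_gene_sets(query, list(s = set_genes), universe)
    oracle <- hyper_oracle(N, m, q, res$k)
    expect_equal(res$p_enrich, oracle$p_enrich, tolerance = 1e-12)
    expect_equal(res$p_deplete, oracle$p_deplete, tolerance = 1e-12)
    expect_equal(res$p_two_sided,
                 min(1, 2 * min(oracle$p_enrich, oracle$p_deplete)),
                 tolerance = 1e-12)
  }
})

test_that("enrichment degenerate cases and Holm adjustment behave", {
  universe <- paste0("g", 1:10)
  sets <- list(a = paste0("g", 1:4), b = paste0("g", 3:9),
               c = paste0("g", 10))
  # query = universe: k = m, p_two_sided capped at 1
  res <- enrich_gene_sets(universe, sets, universe)
  expect_true(all(res$k == res$m))
  expect_true(all(res$p_two_sided <= 1))
  # single set: Holm is identity
  one <- enrich_gene_sets(paste0("g", 1:3), sets["a"], universe)
  expect_equal(one$p_adjusted, one$p_two_sided)
  # Holm monotonicity in raw p order
  res2 <- enrich_gene_sets(paste0("g", c(1, 2, 10)), sets, universe)
  ord <- order(res2$p_two_sided)
  expect_true(all(diff(res2$p_adjusted[ord]) >= -1e-15))
  expect_true(all(res2$p_adjusted >= res2$p_two_sided))
  # query outside the universe is rejected with the offender named
  expect_error(enrich_gene_sets(c("g1", "gZ"), sets, universe), "gZ")
})

test_that("GMT round trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tfirst pathway\tg1\tg2\tg3",
               "setB\tsecond pathway\tg2\tg9"), path)
  sets <- read_gmt(path)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setB, c("g2", "g9"))
  writeLines("broken\tonly-two-fields", path)
  expect_error(read_gmt(path), "malformed")
})
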