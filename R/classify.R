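# Age-class partitioning of circRNAs, differential ranking, qPCR candidate
# selection, top-decile host-gene extraction, and gene-set
# over-representation.

#' Partition circRNAs into age classes
#'
#' Each circRNA in the union of the young- and old-pool presence sets is
#' assigned exactly one class: `young_only`, `old_only` or `shared`.
#'
#' @param presence_young,presence_old character vectors of present
#'   `circ_id`s from [call_presence()] on each pool's treated library.
#' @param profile_young,profile_old `bpm_profile`s for the two treated
#'   libraries, used to attach bpm values (0 where a circRNA is absent
#'   from a library's profile).
#' @return data.frame (`circ_class_table`) with columns `circ_id`,
#'   `host_gene`, `class`, `bpm_young`, `bpm_old`; attributes `D_young`,
#'   `D_old` carry the two library denominators (used downstream for the
#'   fold-change pseudocount) and `class_counts` the per-class tally.
#' @export
partition_classes <- function(presence_young, presence_old,
                              profile_young, profile_old) {
  all_ids <- union(presence_young, presence_old)
  if (length(all_ids) == 0L) {
    warnf("both presence sets are empty; returning an empty class table")
    out <- data.frame(circ_id = character(), host_gene = character(),
                      class = character(), bpm_young = numeric(),
                      bpm_old = numeric(), stringsAsFactors = FALSE)
  } else {
    cls <- ifelse(all_ids %in% presence_young & all_ids %in% presence_old,
                  "shared",
                  ifelse(all_ids %in% presence_young, "young_only",
                         "old_only"))
    lookup <- function(profile, ids, col) {
      idx <- match(ids, profile$circ_id)
      val <- profile[[col]][idx]
      val[is.na(idx)] <- if (col == "bpm") 0 else NA
      val
    }
    host <- lookup(profile_young, all_ids, "host_gene")
    host[is.na(host)] <- lookup(profile_old, all_ids[is.na(host)],
                                "host_gene")
    out <- data.frame(circ_id = all_ids,
                      host_gene = host,
                      class = cls,
                      bpm_young = lookup(profile_young, all_ids, "bpm"),
                      bpm_old = lookup(profile_old, all_ids, "bpm"),
                      stringsAsFactors = FALSE)
    out$bpm_young[is.na(out$bpm_young)] <- 0
    out$bpm_old[is.na(out$bpm_old)] <- 0
  }
  attr(out, "D_young") <- attr(profile_young, "denominator")
  attr(out, "D_old") <- attr(profile_old, "denominator")
  attr(out, "class_counts") <- c(
    young_only = sum(out$class == "young_only"),
    old_only = sum(out$class == "old_only"),
    shared = sum(out$class == "shared"))
  class(out) <- c("circ_class_table", "data.frame")
  out
}

#' Rank shared circRNAs by differential expression
#'
#' For circRNAs present in both pools, computes
#' `log2_fc = log2((bpm_old + eps) / (bpm_young + eps))` and ranks by
#' decreasing `|log2_fc|`. The pseudocount `eps` is the bpm equivalent of a
#' single read in the smaller library (`1e6 / min(D_young, D_old)`), so a
#' shared circRNA scraping the presence threshold cannot produce an
#' unbounded fold change. Ties are broken by larger
#' `max(bpm_young, bpm_old)`, then lexical `circ_id`.
#'
#' @param class_table a `circ_class_table` from [partition_classes()].
#' @param eps pseudocount on the bpm scale; default derived from the
#'   library denominators as above.
#' @return the shared rows with a `log2_fc` column, ordered by rank.
#' @export
rank_shared_differential <- function(class_table, eps = NULL) {
  shared <- class_table[class_table$class == "shared", , drop = FALSE]
  if (nrow(shared) == 0L)
    stopf("no shared circRNAs to rank")
  if (is.null(eps)) {
    Dm <- min(attr(class_table, "D_young"), attr(class_table, "D_old"))
    eps <- if (is.null(Dm) || !is.finite(Dm)) 1 else 1e6 / Dm
  }
  shared$log2_fc <- log2((shared$bpm_old + eps) / (shared$bpm_young + eps))
  ord <- order(-abs(shared$log2_fc),
               -pmax(shared$bpm_young, shared$bpm_old),
               shared$circ_id)
  shared <- shared[ord, , drop = FALSE]
  rownames(shared) <- NULL
  attr(shared, "eps") <- eps
  shared
}

#' Select qPCR candidate circRNAs
#'
#' Takes the top `k_per_class` circRNAs from each age class: by bpm within
#' each exclusive class (in its own pool) and by the differential ranking
#' of [rank_shared_differential()] among shared circRNAs. Output order is
#' young_only, old_only, shared. The default of 5 per class yields the
#' 15-candidate panel used for qPCR follow-up.
#'
#' @param class_table a `circ_class_table`.
#' @param k_per_class candidates per class (default 5). If a class has
#'   fewer members, all are taken with a warning.
#' @return data.frame of selected rows with a `log2_fc` column (NA for
#'   exclusives) in selection order.
#' @export
select_candidates <- function(class_table, k_per_class = 5) {
  assert_scalar_number(k_per_class, "k_per_class", min = 1, integer = TRUE)
  take <- function(rows, ord, cls) {
    rows <- rows[ord, , drop = FALSE]
    if (nrow(rows) < k_per_class)
      warnf("class '%s' has only %d member(s); taking all", cls, nrow(rows))
    utils::head(rows, k_per_class)
  }
  yo <- class_table[class_table$class == "young_only", , drop = FALSE]
  yo <- take(yo, order(-yo$bpm_young, yo$circ_id), "young_only")
  yo$log2_fc <- NA_real_
  ol <- class_table[class_table$class == "old_only", , drop = FALSE]
  ol <- take(ol, order(-ol$bpm_old, ol$circ_id), "old_only")
  ol$log2_fc <- NA_real_
  sh <- if (any(class_table$class == "shared")) {
    ranked <- rank_shared_differential(class_table)
    if (nrow(ranked) < k_per_class)
      warnf("class 'shared' has only %d member(s); taking all",
            nrow(ranked))
    utils::head(ranked, k_per_class)
  } else {
    warnf("class 'shared' has only 0 member(s); taking all")
    cbind(class_table[0, , drop = FALSE], log2_fc = numeric())
  }
  out <- rbind(yo, ol, sh)
  rownames(out) <- NULL
  out
}

#' Host genes of the top-decile circRNAs
#'
#' Sorts a pool's circRNAs by bpm (descending) and returns the
#' deduplicated host genes of the top `ceil(top_fraction * n)` circRNAs,
#' preserving abundance rank order. Ceiling is used so a non-empty profile
#' always yields at least one gene.
#'
#' @param profile a `bpm_profile` for one pool's treated library.
#' @param top_fraction fraction of circRNAs to take (default 0.10).
#' @return character vector of host genes in rank order.
#' @export
top_decile_hosts <- function(profile, top_fraction = 0.10) {
  assert_scalar_number(top_fraction, "top_fraction", min = 0, max = 1)
  if (nrow(profile) == 0L) stopf("empty bpm profile")
  ord <- order(-profile$bpm, profile$circ_id)
  n_take <- ceiling(top_fraction * nrow(profile))
  top <- profile[utils::head(ord, n_take), , drop = FALSE]
  unique(top$host_gene)
}

#' Gene-set over-representation by two-sided hypergeometric test
#'
#' For each gene set, tests whether the query gene list is enriched or
#' depleted relative to a hypergeometric draw of `q = |query|` genes from a
#' universe of `N` genes of which `m` belong to the set:
#' `p_enrich = P(X >= k)`, `p_deplete = P(X <= k)`,
#' `p_two_sided = min(1, 2 min(p_enrich, p_deplete))`, then Holm's
#' step-down Bonferroni adjustment across the sets.
#'
#' @param query character vector of query genes; must be a subset of
#'   `universe`.
#' @param gene_sets named list of character vectors (set_id -> genes); each
#'   set is intersected with the universe before testing.
#' @param universe character vector of background genes. Typically all
#'   genes hosting any detected circRNA.
#' @return data.frame with one row per set: `set_id`, `k`, `q`, `m`, `N`,
#'   `p_enrich`, `p_deplete`, `p_two_sided`, `p_adjusted`,
#'   `leading_genes` (comma-separated overlap), sorted by `p_adjusted`
#'   then raw `p_two_sided`.
#' @export
enrich_gene_sets <- function(query, gene_sets, universe) {
  query <- unique(query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L)
    stopf("query gene(s) outside the universe: %s",
          paste(outside, collapse = ", "))
  if (length(gene_sets) == 0L) stopf("no gene sets supplied")
  if (is.null(names(gene_sets)) || any(names(gene_sets) == ""))
    stopf("'gene_sets' must be a named list")
  N <- length(universe)
  q <- length(query)
  rows <- lapply(names(gene_sets), function(id) {
    set_genes <- intersect(unique(gene_sets[[id]]), universe)
    m <- length(set_genes)
    overlap <- intersect(query, set_genes)
    k <- length(overlap)
    p_enrich <- stats::phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    p_deplete <- stats::phyper(k, m, N - m, q, lower.tail = TRUE)
    data.frame(set_id = id, k = k, q = q, m = m, N = N,
               p_enrich = p_enrich, p_deplete = p_deplete,
               p_two_sided = min(1, 2 * min(p_enrich, p_deplete)),
               leading_genes = paste(sort(overlap), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_two_sided, method = "holm")
  res <- res[order(res$p_adjusted, res$p_two_sided, res$set_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read gene sets in GMT format
#'
#' Each line: set_id TAB description TAB gene1 TAB gene2 ...
#'
#' @param path GMT file path.
#' @return named list of character gene vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad))
    stopf("malformed GMT line(s): %s",
          paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- vapply(parts, `[[`, "", 2L)
  sets
}
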