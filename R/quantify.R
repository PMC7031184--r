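# Abundance statistics for circRNA profiles: bpm, RPKM per exon,
# presence calling, and read-depth bar scaling for junction schematics.

#' Back-spliced reads per million (bpm)
#'
#' Computes the bpm abundance statistic for every circRNA observed in one
#' sequencing library. For circRNA i with back-spliced-junction (BSJ) read
#' count \eqn{j_i} and host-gene canonical read count \eqn{c_i}, over the
#' \eqn{n} circRNAs detected in the library,
#' \deqn{bpm_i = \frac{j_i}{\sum_{a=1}^n j_a + \sum_{b=1}^n c_b} \times 10^6.}
#' The denominator mixes all BSJ reads with the canonical reads of the host
#' genes, so bpm expresses circular abundance relative to the combined
#' circular + linear read mass of the circRNA-producing loci.
#'
#' The canonical term is, by default, summed once per circRNA (so a gene
#' hosting two circRNAs contributes its canonical count twice, following the
#' summation bounds literally). `canonical = "per_gene"` sums each host
#' gene's canonical count once instead.
#'
#' @param table junction count table: data.frame with columns `circ_id`,
#'   `host_gene`, `library_id`, `bsj_reads`, `canonical_reads` (and
#'   optionally `chrom`, `junction_start`, `junction_end`).
#' @param library_id library to quantify; must appear in `table$library_id`.
#' @param canonical `"per_circ"` (default, literal summation) or
#'   `"per_gene"` (each host gene counted once in the denominator).
#' @return A `bpm_profile`: data.frame with columns `circ_id`, `host_gene`,
#'   `bsj_reads`, `canonical_reads`, `bpm`, with attributes `denominator`
#'   (the library denominator D) and `library_id`.
#' @examples
#' tab <- data.frame(circ_id = c("c1", "c2"), host_gene = c("g1", "g2"),
#'                   library_id = "lib", bsj_reads = c(5L, 15L),
#'                   canonical_reads = c(80L, 100L))
#' compute_bpm(tab, "lib")  # D = 200, bpm = 25000, 75000
#' @export
compute_bpm <- function(table, library_id,
                        canonical = c("per_circ", "per_gene")) {
  canonical <- match.arg(canonical)
  assert_columns(table, c("circ_id", "host_gene", "library_id",
                          "bsj_reads", "canonical_reads"), "table")
  lib <- table[table$library_id == library_id, , drop = FALSE]
  if (nrow(lib) == 0L)
    stopf("library '%s' not present in the junction count table", library_id)
  if (anyDuplicated(lib$circ_id))
    stopf("duplicate circ_id rows for library '%s'", library_id)
  if (any(is.na(lib$bsj_reads)) || any(lib$bsj_reads < 0) ||
      any(is.na(lib$canonical_reads)) || any(lib$canonical_reads < 0))
    stopf("negative or missing read counts in library '%s'", library_id)

  canon_sum <- if (canonical == "per_circ") {
    sum(lib$canonical_reads)
  } else {
    # one canonical count per distinct host gene
    sum(lib$canonical_reads[!duplicated(lib$host_gene)])
  }
  D <- sum(lib$bsj_reads) + canon_sum
  if (D == 0)
    stopf("library '%s' has denominator D = 0 (no reads)", library_id)

  out <- data.frame(circ_id = lib$circ_id,
                    host_gene = lib$host_gene,
                    bsj_reads = lib$bsj_reads,
                    canonical_reads = lib$canonical_reads,
                    bpm = lib$bsj_reads / D * 1e6,
                    stringsAsFactors = FALSE)
  attr(out, "denominator") <- D
  attr(out, "library_id") <- library_id
  class(out) <- c("bpm_profile", "data.frame")
  out
}

#' RPKM per exon
#'
#' Reads per kilobase per million mapped reads for each exon:
#' `reads / ((exon_length/1e3) * (total_mapped_reads/1e6))`.
#'
#' @param table data.frame with columns `gene`, `exon`, `reads`,
#'   `exon_length`, and `library_id` if `total_mapped_reads` is per-library.
#' @param total_mapped_reads positive scalar: total mapped reads in the
#'   library.
#' @return input data.frame with an `rpkm` column appended.
#' @export
compute_rpkm <- function(table, total_mapped_reads) {
  assert_columns(table, c("gene", "exon", "reads", "exon_length"), "table")
  assert_scalar_number(total_mapped_reads, "total_mapped_reads",
                       min = 1)
  if (any(table$exon_length <= 0))
    stopf("exon_length must be positive for every exon")
  if (any(table$reads < 0))
    stopf("negative read counts")
  table$rpkm <- table$reads /
    ((table$exon_length / 1e3) * (total_mapped_reads / 1e6))
  table
}

#' Presence calling in an RNase R-treated pool
#'
#' A circRNA is called present in a pool when its BSJ read count in the
#' RNase R-treated library reaches `min_bsj_reads`. The mock library never
#' contributes: RNase R removes linear competitors, so the treated library
#' is the circRNA-enriched evidence. The default threshold of 2 reads
#' discards single chimeric reads, a common mapping artifact.
#'
#' @param profile a `bpm_profile` computed on the treated library.
#' @param min_bsj_reads minimum BSJ reads (inclusive) to call presence.
#' @return character vector of present `circ_id`s.
#' @export
call_presence <- function(profile, min_bsj_reads = 2) {
  if (!inherits(profile, "bpm_profile"))
    stopf("'profile' must be a bpm_profile from compute_bpm()")
  assert_scalar_number(min_bsj_reads, "min_bsj_reads", min = 0,
                       integer = TRUE)
  profile$circ_id[profile$bsj_reads >= min_bsj_reads]
}

#' Scale junction read depths to 1-10 bars
#'
#' Linear interpolation of read depths onto integer bar counts for junction
#' schematics: the lowest-depth junction gets 1 bar and the highest 10,
#' `bars = round(1 + 9 (d - d_min) / (d_max - d_min))` with round-half-up.
#' When every depth is equal, each junction is simultaneously the minimum
#' and the maximum; the maximum branch wins and all junctions get 10 bars.
#'
#' @param depths positive numeric vector of junction read depths.
#' @return integer vector of bar counts in `[1, 10]`, monotone in depth.
#' @export
scale_junction_depth <- function(depths) {
  if (length(depths) == 0L) stopf("'depths' must contain at least one value")
  if (any(is.na(depths)) || any(depths <= 0))
    stopf("'depths' must be positive and non-missing")
  dmin <- min(depths)
  dmax <- max(depths)
  if (dmax == dmin) return(rep(10L, length(depths)))
  as.integer(round_half_up(1 + 9 * (depths - dmin) / (dmax - dmin)))
}

#' Export junction coordinates as BED
#'
#' Writes a 6-column BED (0-based half-open) with `name = circ_id` and
#' `score = bsj_reads`; strand is reported as `.` since junction
#' coordinates are stored genome-oriented with start < end.
#'
#' @param table junction count table with coordinate columns.
#' @param path output file path.
#' @param library_id restrict to one library (default: first in the table).
#' @return the path, invisibly.
#' @export
export_junctions_bed <- function(table, path,
                                 library_id = table$library_id[1]) {
  assert_columns(table, c("circ_id", "chrom", "junction_start",
                          "junction_end", "library_id", "bsj_reads"),
                 "table")
  lib <- table[table$library_id == library_id, , drop = FALSE]
  bed <- data.frame(chrom = lib$chrom,
                    start = lib$junction_start,
                    end = lib$junction_end,
                    name = lib$circ_id,
                    score = lib$bsj_reads,
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
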