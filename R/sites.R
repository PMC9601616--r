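# Site classification (SNP / indel / monomorphic) and per-marker
# variability statistics.

#' Classify alignment columns as SNP, indel, or monomorphic sites
#'
#' A column containing a gap in any row is an indel site. A column in which
#' at least two distinct unambiguous nucleotides (A/C/G/T) occur is a SNP
#' site; ambiguity codes and N never create polymorphism. With
#' `count_gap_snps = TRUE` (default) a gap-containing column whose gap-free
#' rows are still polymorphic is counted in both tallies, matching the
#' additive definition of the variable-site percentage (SNP sites + indel
#' sites over alignment length); with `FALSE` indel classification takes
#' strict precedence. Columns in neither set are monomorphic.
#'
#' @param alignment A [marker_alignment()] with at least 2 samples.
#' @param count_gap_snps Count nucleotide polymorphism inside gap columns
#'   as SNPs too? Default `TRUE`.
#' @return A list of class `site_classification`: `n_sites`, and 1-based
#'   column index vectors `snp_sites`, `indel_sites`, `monomorphic_sites`.
#' @export
classify_sites <- function(alignment, count_gap_snps = TRUE) {
  mat <- alignment$seq
  if (nrow(mat) < 2) {
    abort("site classification needs at least 2 samples",
          class = "barcodegap_insufficient_data_error")
  }
  gap_col <- colSums(mat == "-") > 0
  n_bases <- (colSums(mat == "A") > 0) + (colSums(mat == "C") > 0) +
    (colSums(mat == "G") > 0) + (colSums(mat == "T") > 0)
  snp_col <- n_bases >= 2
  if (!count_gap_snps) snp_col <- snp_col & !gap_col
  structure(
    list(
      n_sites = ncol(mat),
      snp_sites = which(snp_col),
      indel_sites = which(gap_col),
      monomorphic_sites = which(!snp_col & !gap_col)
    ),
    class = "site_classification"
  )
}

#' @export
print.site_classification <- function(x, ...) {
  cat("<site_classification> ", x$n_sites, " sites: ",
      length(x$snp_sites), " SNP, ", length(x$indel_sites), " indel, ",
      length(x$monomorphic_sites), " monomorphic\n", sep = "")
  invisible(x)
}

#' SNP and variable-site percentages from integer counts
#'
#' `pct_snp = 100 * n_snps / length_bp` and
#' `pct_variable = 100 * (n_snps + n_indels) / length_bp`, both rounded
#' half-up to two decimals. The denominators are the aligned marker length.
#'
#' @param n_snps Number of SNP sites.
#' @param n_indels Number of insertion/deletion sites.
#' @param length_bp Aligned length in base pairs.
#' @return Tibble with `pct_snp` and `pct_variable`.
#' @export
#' @examples
#' site_percentages(125, 78, 452) # 27.65 and 44.91
site_percentages <- function(n_snps, n_indels, length_bp) {
  tibble(
    pct_snp = round_half_up(100 * n_snps / length_bp, 2),
    pct_variable = round_half_up(100 * (n_snps + n_indels) / length_bp, 2)
  )
}

#' Marker variability summary row
#'
#' The per-marker summary used to compare candidate barcodes: aligned
#' length, SNP and indel site counts with their percentages, and the mean
#' intra- and interspecific pairwise distances (unweighted means over the
#' pooled conspecific and heterospecific pair lists).
#'
#' @param alignment A [marker_alignment()].
#' @param dist Optional precomputed [distance_matrix()] on the same
#'   alignment (default: K2P, computed here).
#' @param partition Optional precomputed [partition_by_species()].
#' @param count_gap_snps Passed to [classify_sites()].
#' @param ... Passed to [distance_matrix()] when it is computed here.
#' @return One-row tibble: `marker`, `length_bp`, `n_snps`, `pct_snp`,
#'   `n_indels`, `pct_variable`, `mean_intra`, `mean_inter`.
#' @export
variability_stats <- function(alignment, dist = NULL, partition = NULL,
                              count_gap_snps = TRUE, ...) {
  sites <- classify_sites(alignment, count_gap_snps = count_gap_snps)
  if (is.null(dist)) dist <- distance_matrix(alignment, model = "k2p", ...)
  if (is.null(partition)) partition <- partition_by_species(dist, alignment$species)
  n_snps <- length(sites$snp_sites)
  n_indels <- length(sites$indel_sites)
  pct <- site_percentages(n_snps, n_indels, sites$n_sites)
  tibble(
    marker = alignment$marker,
    length_bp = sites$n_sites,
    n_snps = n_snps,
    pct_snp = pct$pct_snp,
    n_indels = n_indels,
    pct_variable = pct$pct_variable,
    mean_intra = if (length(partition$pooled_intra)) mean(partition$pooled_intra) else NA_real_,
    mean_inter = if (length(partition$pooled_inter)) mean(partition$pooled_inter) else NA_real_
  )
}
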