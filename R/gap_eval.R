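# PWG-distance barcoding-gap test, discrimination-rate statistic, and
# intra/inter divergence histograms.

#' Per-species barcoding-gap (PWG-distance) test
#'
#' A species passes when its minimum interspecific distance is strictly
#' larger than its maximum intraspecific distance. Singleton species have
#' no intraspecific pairs; under the default policy their maximum
#' intraspecific distance is taken as 0 (so they pass whenever their
#' minimum interspecific distance is positive), under `"exclude"` they are
#' dropped from the denominator.
#'
#' @param partition A [partition_by_species()] result.
#' @param species Species label present in the partition; `NULL` (default)
#'   evaluates every species.
#' @param singleton_policy `"count_success_if_positive_inter"` (default) or
#'   `"exclude"`.
#' @param intra_partition Optional second partition from which the
#'   intraspecific side is taken (the mixed literal mode that measures the
#'   intra side under the p-distance model and the inter side under K2P).
#' @return Tibble with one row per species evaluated: `species`,
#'   `n_individuals`, `max_intra`, `min_inter`, `success`. Excluded
#'   singletons carry `success = NA`.
#' @export
pwg_species_test <- function(partition, species = NULL,
                             singleton_policy = c("count_success_if_positive_inter",
                                                  "exclude"),
                             intra_partition = NULL) {
  singleton_policy <- match.arg(singleton_policy)
  per <- partition$per_species
  if (!is.null(intra_partition)) {
    ip <- intra_partition$per_species
    if (!identical(ip$species, per$species)) {
      abort("intra_partition must cover the same species in the same order")
    }
    per$intra <- ip$intra
  }
  if (!is.null(species)) {
    if (!species %in% per$species) {
      abort(paste0("species not in partition: ", species),
            class = "barcodegap_evaluation_error")
    }
    per <- per[per$species == species, ]
  }
  if (any(lengths(per$inter) == 0)) {
    abort("species with no heterospecific comparisons",
          class = "barcodegap_evaluation_error")
  }
  max_intra <- vapply(per$intra, function(v) if (length(v)) max(v) else NA_real_,
                      numeric(1))
  min_inter <- vapply(per$inter, min, numeric(1))
  singleton <- per$n_individuals == 1
  success <- min_inter > ifelse(singleton, 0, max_intra)
  if (singleton_policy == "exclude") success[singleton] <- NA
  tibble(
    species = per$species,
    n_individuals = per$n_individuals,
    max_intra = max_intra,
    min_inter = min_inter,
    success = success
  )
}

#' Discrimination rate from per-species gap records
#'
#' Counts successes over evaluated species (records with `success = NA`,
#' i.e. excluded singletons, do not enter either count) and attaches the
#' percentage rate rounded half-up to two decimals.
#'
#' @param records Tibble from [pwg_species_test()] (or any tibble with a
#'   logical `success` column).
#' @param marker_set Marker-set label for the result row.
#' @param model Distance model label (`"k2p"` or `"p_distance"`).
#' @param method Method label, default `"pwg_distance"`.
#' @return One-row tibble: `marker_set`, `method`, `model`, `n_success`,
#'   `n_species`, `rate_pct`.
#' @export
pwg_discrimination_rate <- function(records, marker_set = "", model = "k2p",
                                    method = "pwg_distance") {
  keep <- !is.na(records$success)
  if (!any(keep)) {
    abort("no species left to evaluate", class = "barcodegap_evaluation_error")
  }
  n_success <- sum(records$success[keep])
  n_species <- sum(keep)
  tibble(
    marker_set = marker_set, method = method, model = model,
    n_success = n_success, n_species = n_species,
    rate_pct = discrimination_rate_pct(n_success, n_species)
  )
}

#' Barcoding-gap histogram of pairwise divergences
#'
#' Bins the pooled intra- and interspecific distances into shared half-open
#' bins `[lo, hi)` of width `bin_width` covering `[0, max distance]`. When
#' the pooled distributions overlap (pooled maximum intraspecific exceeds
#' pooled minimum interspecific distance) the overlap interval is recorded.
#'
#' @param partition A [partition_by_species()] result with at least one
#'   pairwise distance.
#' @param bin_width Bin width in substitutions/site (default 0.005).
#' @return A tibble of class `divergence_histogram` with columns `bin_low`,
#'   `bin_high`, `intra_count`, `inter_count`; attributes `overlap_range`
#'   (numeric length 2 or `NULL`) and `bin_width`.
#' @export
divergence_histogram <- function(partition, bin_width = 0.005) {
  if (bin_width <= 0) abort("bin_width must be positive")
  intra <- partition$pooled_intra
  inter <- partition$pooled_inter
  if (length(intra) + length(inter) == 0) {
    abort("empty distance partition", class = "barcodegap_evaluation_error")
  }
  dmax <- max(c(intra, inter))
  n_bins <- max(1L, as.integer(floor(dmax / bin_width + 1e-12)) + 1L)
  edges <- bin_width * (0:n_bins)
  bin_of <- function(x) pmin(floor(x / bin_width) + 1L, n_bins)
  out <- tibble(
    bin_low = edges[-(n_bins + 1)],
    bin_high = edges[-1],
    intra_count = tabulate(bin_of(intra), nbins = n_bins),
    inter_count = tabulate(bin_of(inter), nbins = n_bins)
  )
  overlap <- NULL
  if (length(intra) && length(inter) && max(intra) > min(inter)) {
    overlap <- c(min(inter), max(intra))
  }
  structure(out, overlap_range = overlap, bin_width = bin_width,
            class = c("divergence_histogram", class(out)))
}

#' Overlap interval of a divergence histogram
#' @param x A [divergence_histogram()].
#' @return Numeric `c(low, high)` or `NULL` when the pooled distributions
#'   do not overlap.
#' @export
overlap_range <- function(x) attr(x, "overlap_range")
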