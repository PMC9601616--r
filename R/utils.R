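# Shared helpers: rounding, seed-stream derivation, id checks.

#' Round half away from zero
#'
#' Reported percentages in this package use conventional "half-up" rounding
#' (0.005 rounds to 0.01), not the round-half-even rule of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(44.444, 88.888, 63.035), 2)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage discrimination-rate statistic
#'
#' The identification rate: successfully identified species over species
#' evaluated, as a percentage rounded half-up to two decimals.
#'
#' @param n_success Number of successfully identified species.
#' @param n_species Number of species evaluated (positive).
#' @return Numeric percentage.
#' @export
#' @examples
#' discrimination_rate_pct(38, 45) # 84.44
#' discrimination_rate_pct(40, 45) # 88.89
discrimination_rate_pct <- function(n_success, n_species) {
  stopifnot(all(n_species > 0), all(n_success >= 0), all(n_success <= n_species))
  round_half_up(100 * n_success / n_species, 2)
}

# Deterministic sub-seed derivation. Every random stage draws its own seed
# from (seed, stream, index) so that, e.g., bootstrap replicate r depends
# only on (seed, r) regardless of how many replicates were redrawn before it.
# Kept strictly below 2^31 - 1 (R integer seeds are 32-bit).
derive_seed <- function(seed, stream, index = 0) {
  m <- 2147483629
  s <- (as.numeric(seed) %% m)
  v <- (s * 48271 + as.numeric(stream) * 2654435 + as.numeric(index) * 97 + 12345) %% m
  as.integer(v + 1)
}

check_newick_safe <- function(labels) {
  bad <- grepl("[][(),:;'\" \t]", labels)
  if (any(bad)) {
    abort(paste0(
      "sample/species ids must not contain Newick metacharacters or spaces: ",
      paste(head(labels[bad], 3), collapse = ", ")
    ), class = "barcodegap_id_error")
  }
  invisible(labels)
}

fmt_len <- function(x) sprintf("%.10g", x)
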