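# Build a distance_partition directly so the gap criterion can be probed
# at exact values.
fake_partition <- function(per) {
  structure(list(
    per_species = per,
    pooled_intra = unlist(per$intra),
    pooled_inter = unlist(per$inter) / 2,  # pooling not used by the test
    model = "k2p"
  ), class = "distance_partition")
}

test_that("the PWG criterion is a strict per-species inequality", {
  per <- tibble::tibble(
    species = c("ok", "fail", "tie"),
    n_individuals = c(3L, 3L, 3L),
    intra = list(c(0.001, 0.002), c(0.02, 0.05), c(0.03)),
    inter = list(c(0.05, 0.06), c(0.01, 0.2), c(0.03, 0.2))
  )
  rec <- pwg_species_test(fake_partition(per))
  expect_equal(rec$success, c(TRUE, FALSE, FALSE))
  expect_equal(rec$max_intra, c(0.002, 0.05, 0.03))
  expect_equal(rec$min_inter, c(0.05, 0.01, 0.03))

  one <- pwg_species_test(fake_partition(per), species = "tie")
  expect_false(one$success)
  expect_error(pwg_species_test(fake_partition(per), species = "absent"),
               class = "barcodegap_evaluation_error")
})

test_that("singleton species follow the chosen policy", {
  per <- tibble::tibble(
    species = c("solo", "pair"),
    n_individuals = c(1L, 2L),
    intra = list(numeric(0), c(0.01)),
    inter = list(c(0.04), c(0.04, 0.05))
  )
  count <- pwg_species_test(fake_partition(per))
  expect_true(count$success[count$species == "solo"])
  expect_true(is.na(count$max_intra[count$species == "solo"]))
  drop <- pwg_species_test(fake_partition(per), singleton_policy = "exclude")
  expect_true(is.na(drop$success[drop$species == "solo"]))
  rate <- pwg_discrimination_rate(drop, "m")
  expect_equal(rate$n_species, 1)

  # singleton with zero minimum inter distance is not a success
  per0 <- tibble::tibble(species = c("solo", "twin"),
                         n_individuals = c(1L, 1L),
                         intra = list(numeric(0), numeric(0)),
                         inter = list(c(0), c(0)))
  rec0 <- pwg_species_test(fake_partition(per0))
  expect_false(any(rec0$success))
})

test_that("the rate statistic reproduces the half-up percentage", {
  rec <- function(n_succ, n_sp) {
    tibble::tibble(success = c(rep(TRUE, n_succ), rep(FALSE, n_sp - n_succ)))
  }
  expect_equal(pwg_discrimination_rate(rec(0, 45), "m")$rate_pct, 0)
  expect_equal(pwg_discrimination_rate(rec(20, 45), "m")$rate_pct, 44.44)
  expect_equal(pwg_discrimination_rate(rec(40, 45), "m")$rate_pct, 88.89)
  expect_error(pwg_discrimination_rate(tibble::tibble(success = NA), "m"),
               class = "barcodegap_evaluation_error")
})

test_that("divergence histograms conserve counts and report overlap", {
  part <- structure(list(
    per_species = NULL,
    pooled_intra = c(0.001, 0.004, 0.008),
    pooled_inter = c(0.051, 0.07, 0.22),
    model = "k2p"
  ), class = "distance_partition")
  h <- divergence_histogram(part, bin_width = 0.005)
  expect_equal(sum(h$intra_count), 3)
  expect_equal(sum(h$inter_count), 3)
  expect_null(overlap_range(h))
  expect_equal(h$bin_low[1], 0)
  expect_true(all(abs(h$bin_high - h$bin_low - 0.005) < 1e-12))
  # values sit in half-open bins [lo, hi)
  expect_equal(h$intra_count[1], 2)  # 0.001, 0.004
  expect_equal(h$intra_count[2], 1)  # 0.008

  part2 <- structure(list(
    pooled_intra = c(0.01, 0.08), pooled_inter = c(0.05, 0.2)
  ), class = "distance_partition")
  h2 <- divergence_histogram(part2, 0.01)
  expect_equal(overlap_range(h2), c(0.05, 0.08))

  expect_error(divergence_histogram(part, bin_width = 0), "positive")
})

test_that("inflating intra distances never raises the PWG rate", {
  sim <- simulate_dataset(simulation_config(n_species = 8,
                                            individuals_per_species = 3,
                                            markers = default_markers()[1:2, ],
                                            seed = 4))
  part <- partition_by_species(
    distance_matrix(concatenate_markers(sim$alignments), "k2p"))
  rate_at <- function(f) {
    p <- part
    p$per_species$intra <- lapply(p$per_species$intra, function(v) v * f)
    pwg_discrimination_rate(pwg_species_test(p), "m")$rate_pct
  }
  factors <- c(1, 2, 5, 10, 30, 100)
  rates <- vapply(factors, rate_at, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("PWG rate ignores sample relabeling and marker order", {
  sim <- simulate_dataset(simulation_config(n_species = 6,
                                            individuals_per_species = 3,
                                            seed = 12))
  rate_of <- function(alns) {
    cc <- concatenate_markers(alns)
    pwg_discrimination_rate(
      pwg_species_test(partition_by_species(distance_matrix(cc, "k2p"))),
      "m")$rate_pct
  }
  base <- rate_of(sim$alignments)
  expect_equal(rate_of(rev(sim$alignments)), base)
  # rename every sample consistently
  renamed <- lapply(sim$alignments, function(a) {
    ids <- paste0("Z", sample_ids(a))
    marker_alignment(`rownames<-`(a$seq, ids),
                     make_meta(ids, unname(a$species)), a$marker)
  })
  expect_equal(rate_of(renamed), base)
})
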