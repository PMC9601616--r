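test_that("p-distance applies pairwise deletion", {
  expect_equal(p_distance_pair("ACGT", "ACGA"),
               tibble::tibble(p = 0.25, n_comparable = 4L))
  expect_equal(p_distance_pair("AC-T", "ACGT"),
               tibble::tibble(p = 0, n_comparable = 3L))
  long <- strrep("ACGT", 113)  # 452-mer
  expect_equal(p_distance_pair(long, long)$p, 0)
  # N and ambiguity codes are excluded like gaps
  expect_equal(p_distance_pair("ANRT", "ACGT")$n_comparable, 2L)
  expect_error(p_distance_pair("--", "AC"),
               class = "barcodegap_undefined_distance_error")
  expect_error(p_distance_pair("ACG", "ACGT"))
})

test_that("K2P distance matches its closed form and counts", {
  same <- k2p_distance_pair("ACGT", "ACGT")
  expect_equal(same$d, 0)
  expect_equal(same$P, 0)
  expect_equal(same$Q, 0)

  # one transition among 4 sites: P = 0.25, Q = 0
  one_ts <- k2p_distance_pair("ACGT", "GCGT")
  expect_equal(one_ts$P, 0.25)
  expect_equal(one_ts$Q, 0)
  expect_equal(one_ts$d, -0.5 * log(0.5), tolerance = 1e-12)

  # P = 0.1, Q = 0.05 realised as exact counts over 100 sites
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("G", 10), rep("C", 5), rep("A", 85)), collapse = "")
  pq <- k2p_distance_pair(a, b)
  expect_equal(pq$P, 0.1)
  expect_equal(pq$Q, 0.05)
  expect_equal(pq$d, 0.170181, tolerance = 1e-6)
  expect_equal(pq$d, -0.5 * log(0.75) - 0.25 * log(0.9), tolerance = 1e-12)

  # saturation: error by default, capped when asked
  sat_a <- paste(rep("A", 10), collapse = "")
  sat_b <- paste(rep("G", 10), collapse = "")
  expect_error(k2p_distance_pair(sat_a, sat_b),
               class = "barcodegap_saturation_error")
  expect_equal(k2p_distance_pair(sat_a, sat_b, saturation = "cap", d_max = 3)$d, 3)
})

test_that("distance matrices are symmetric, zero-diagonal, model-consistent", {
  aln <- random_alignment(8, 200, seed = 11, gap_frac = 0.03)
  for (model in c("k2p", "p_distance")) {
    dm <- distance_matrix(aln, model)
    expect_equal(dm$d, t(dm$d))
    expect_equal(unname(diag(dm$d)), rep(0, 8))
    expect_true(all(is.finite(dm$d)) && all(dm$d >= 0))
    expect_equal(dm$comparable, t(dm$comparable))
    expect_true(all(dm$comparable[upper.tri(dm$comparable)] > 0))
  }
  # matrix path agrees with the pair functions
  dm <- distance_matrix(aln, "k2p")
  dp <- distance_matrix(aln, "p_distance")
  for (j in 2:4) {
    pair_k <- k2p_distance_pair(aln$seq[1, ], aln$seq[j, ])
    pair_p <- p_distance_pair(aln$seq[1, ], aln$seq[j, ])
    expect_equal(dm$d[1, j], pair_k$d)
    expect_equal(dp$d[1, j], pair_p$p)
    expect_equal(dm$comparable[1, j], pair_p$n_comparable)
  }
  two <- marker_alignment(c(x = "ACGT", y = "ACGT"),
                          make_meta(c("x", "y"), c("s", "s")))
  expect_equal(unname(distance_matrix(two)$d), matrix(0, 2, 2))
})

test_that("K2P correction dominates p-distance, equal only at zero", {
  for (seed in 1:5) {
    aln <- random_alignment(6, 300, seed = seed, gap_frac = 0.02)
    dk <- distance_matrix(aln, "k2p")$d
    dp <- distance_matrix(aln, "p_distance")$d
    ut <- upper.tri(dk)
    expect_true(all(dk[ut] >= dp[ut] - 1e-12))
    nz <- ut & dp > 0
    expect_true(all(dk[nz] > dp[nz]))
    expect_true(all(dk[ut & dp == 0] == 0))
  }
})

test_that("distances agree with ape's K80 and raw models (independent check)", {
  aln <- random_alignment(7, 400, seed = 21)
  bin <- ape::as.DNAbin(aln$seq)
  ref_k <- as.matrix(ape::dist.dna(bin, model = "K80",
                                   pairwise.deletion = TRUE))
  ref_p <- as.matrix(ape::dist.dna(bin, model = "raw",
                                   pairwise.deletion = TRUE))
  ids <- sample_ids(aln)
  expect_equal(distance_matrix(aln, "k2p")$d, ref_k[ids, ids],
               tolerance = 1e-12)
  expect_equal(distance_matrix(aln, "p_distance")$d, ref_p[ids, ids],
               tolerance = 1e-12)
})

test_that("gap-free concatenation p-distance is the site-weighted mean", {
  set.seed(5)
  for (i in 1:5) {
    la <- sample(50:150, 1); lb <- sample(50:150, 1)
    a <- random_alignment(5, la, seed = 100 + i, marker = "A")
    b <- random_alignment(5, lb, seed = 200 + i, marker = "B")
    cc <- concatenate_markers(list(a, b))
    dc <- distance_matrix(cc, "p_distance")$d
    da <- distance_matrix(a, "p_distance")$d
    db <- distance_matrix(b, "p_distance")$d
    expect_equal(dc, (la * da + lb * db) / (la + lb), tolerance = 1e-12)
  }
})

test_that("K2P estimate converges to the generating divergence", {
  # single long pair at true divergence 0.1 (kappa 2)
  anc <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE), collapse = "")
  child <- evolve_k2p(anc, 0.1, kappa = 2, seed = 99)
  est <- k2p_distance_pair(anc, child)$d
  expect_lt(abs(est - 0.1), 0.01)
  # error shrinks with length (1e3 vs 1e5, averaged over replicates)
  err_at <- function(L, n_rep) {
    mean(vapply(seq_len(n_rep), function(r) {
      set.seed(1000 + r)
      a <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      b <- evolve_k2p(a, 0.1, kappa = 2)
      abs(k2p_distance_pair(a, b)$d - 0.1)
    }, numeric(1)))
  }
  expect_lt(err_at(1e5, 3), err_at(1e3, 3))
})

test_that("species partition has the right pair combinatorics", {
  aln <- small_alignment()  # 2 species x 2 individuals
  part <- partition_by_species(distance_matrix(aln))
  expect_length(part$pooled_intra, 2)
  expect_length(part$pooled_inter, 4)
  expect_equal(length(part$pooled_intra) + length(part$pooled_inter),
               4 * 3 / 2)
  per <- part$per_species
  expect_equal(lengths(per$intra), c(1L, 1L), ignore_attr = TRUE)
  expect_equal(lengths(per$inter), c(4L, 4L), ignore_attr = TRUE)

  # single species, 3 individuals: all intra
  meta3 <- make_meta(c("x1", "x2", "x3"), rep("X", 3))
  one_sp <- marker_alignment(c(x1 = "ACGTAA", x2 = "ACGTAT", x3 = "ACGAAT"),
                             meta3, "m")
  p1 <- partition_by_species(distance_matrix(one_sp))
  expect_length(p1$pooled_intra, 3)
  expect_length(p1$pooled_inter, 0)

  # singleton species has an empty intra list
  meta_s <- make_meta(c("x1", "x2", "y1"), c("X", "X", "Y"))
  mix <- marker_alignment(c(x1 = "ACGTAA", x2 = "ACGTAT", y1 = "TTTTTT"),
                          meta_s, "m")
  ps <- partition_by_species(distance_matrix(mix, saturation = "cap"))
  expect_equal(lengths(ps$per_species$intra[ps$per_species$species == "Y"]), 0,
               ignore_attr = TRUE)

  unl <- distance_matrix(small_alignment())
  expect_error(partition_by_species(unl, c(a1 = "A", a2 = "A", b1 = "B")),
               class = "barcodegap_metadata_error")
})

test_that("distance matrices round-trip through TSV and PHYLIP", {
  dm <- distance_matrix(random_alignment(5, 80, seed = 3))
  tsv <- tempfile(fileext = ".tsv")
  write_dist_tsv(dm, tsv)
  got <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(as.matrix(got[, -1]), dm$d, ignore_attr = TRUE)
  phy <- tempfile(fileext = ".phy")
  write_dist_phylip(dm, phy)
  back <- read_dist_phylip(phy)
  expect_equal(back, dm$d, tolerance = 1e-7)
})
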