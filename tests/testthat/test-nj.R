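test_that("three taxa give the closed-form star", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
})

test_that("the four-taxon additive example is recovered exactly", {
  # unrooted tree: A-u = 1, B-u = 2, u-v = 1, C-v = 3, D-v = 4
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(labs, labs))
  # four-point condition: AB|CD is the additive split
  expect_true(d["A", "B"] + d["C", "D"] < d["A", "C"] + d["B", "D"])
  tr <- neighbor_joining(d)
  bip <- tree_bipartitions(tr)
  sides <- lapply(bip$tips, identity)
  expect_true(any(vapply(sides, function(s) setequal(s, c("A", "B")) ||
                           setequal(s, c("C", "D")), logical(1))))
  # path lengths reproduce the input exactly
  expect_equal(ape::cophenetic.phylo(tr)[labs, labs], d, tolerance = 1e-12)
  # internal edge has length 1
  internal <- tr$edge[, 2] > ape::Ntip(tr)
  expect_equal(tr$edge.length[internal], 1, tolerance = 1e-12)
})

test_that("NJ is consistent on random additive matrices", {
  for (seed in 1:10) {
    n <- sample(5:12, 1)
    fix <- random_additive(n, seed)
    tr <- neighbor_joining(fix$d)
    expect_equal(phangorn::RF.dist(ape::unroot(fix$tree), tr), 0)
    ids <- rownames(fix$d)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[ids, ids] - fix$d)), 1e-9)
  }
})

test_that("NJ topology agrees with ape's implementation on noisy matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    fix <- random_additive(8, seed + 50)
    noisy <- fix$d + matrix(runif(64, 0, 0.01), 8, 8)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    mine <- neighbor_joining(noisy)
    theirs <- ape::nj(as.dist(noisy))
    expect_equal(phangorn::RF.dist(mine, ape::unroot(theirs)), 0)
  }
})

test_that("NJ rejects degenerate inputs", {
  d2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(d2), class = "barcodegap_size_error")
  d3 <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(d3), class = "barcodegap_input_error")
})

test_that("an n-tip binary unrooted tree has n-3 internal bipartitions", {
  for (seed in 1:5) {
    n <- sample(5:15, 1)
    fix <- random_additive(n, seed + 400)
    tr <- neighbor_joining(fix$d)
    expect_equal(length(attr(tr, "clusters")), n - 3)
    expect_equal(nrow(tree_bipartitions(tr)), n - 3)
  }
})

test_that("bootstrap supports are deterministic and sane", {
  aln <- random_alignment(6, 150, seed = 31, n_species = 3)
  b1 <- bootstrap_supports(aln, "k2p", n_replicates = 25, seed = 5)
  b2 <- bootstrap_supports(aln, "k2p", n_replicates = 25, seed = 5)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  expect_identical(attr(b1, "support_table"), attr(b2, "support_table"))
  s <- attr(b1, "support_table")$support
  expect_true(all(s >= 0 & s <= 100))

  # a single replicate can only give 0 or 100
  b_one <- bootstrap_supports(aln, "k2p", n_replicates = 1, seed = 2)
  expect_true(all(attr(b_one, "support_table")$support %in% c(0, 100)))
})

test_that("clearly separated clusters get near-certain support", {
  # two 2-taxon clusters separated by many substitutions over a long
  # alignment: the AB|CD split should appear in nearly every resample
  set.seed(7)
  base <- sample(c("A", "C", "G", "T"), 800, replace = TRUE)
  mut <- function(x, k, offset) {
    idx <- seq(offset, offset + k - 1)
    x[idx] <- chartr("ACGT", "GTAC", x[idx])
    x
  }
  far <- mut(base, 200, 1)
  seqs <- rbind(A = base, B = mut(base, 3, 500),
                C = far, D = mut(far, 3, 600))
  aln <- marker_alignment(seqs, make_meta(rownames(seqs),
                                          c("x", "x", "y", "y")), "m")
  bt <- bootstrap_supports(aln, "k2p", n_replicates = 100, seed = 3)
  expect_true(all(attr(bt, "support_table")$support >= 95))
})

test_that("bootstrap supports are invariant to tip order", {
  aln <- random_alignment(6, 200, seed = 41, n_species = 3)
  perm <- c(4, 2, 6, 1, 3, 5)
  aln_p <- marker_alignment(aln$seq[perm, ],
                            make_meta(sample_ids(aln)[perm],
                                      unname(aln$species[perm])),
                            aln$marker)
  b <- bootstrap_supports(aln, "k2p", n_replicates = 50, seed = 9)
  bp <- bootstrap_supports(aln_p, "k2p", n_replicates = 50, seed = 9)
  # same splits by label, same support values attached (sides canonicalised
  # to the half not containing the alphabetically first tip)
  key <- function(tree) {
    tips <- sort(tree$tip.label)
    bip <- tree_bipartitions(tree)
    nm <- vapply(bip$tips, function(s) {
      if (tips[1] %in% s) s <- setdiff(tips, s)
      paste(sort(s), collapse = ",")
    }, character(1))
    sup <- bip$support
    names(sup) <- nm
    sup[order(names(sup))]
  }
  expect_equal(key(b), key(bp))
})

test_that("Newick I/O round-trips topology, lengths and supports", {
  fix <- random_additive(7, 77)
  aln <- random_alignment(7, 150, seed = 78, n_species = 3)
  bt <- bootstrap_supports(aln, "k2p", n_replicates = 20, seed = 1)
  path <- tempfile(fileext = ".nwk")
  write_newick(bt, path)
  back <- read_newick(path)
  expect_equal(phangorn::RF.dist(bt, back), 0)
  o1 <- tree_bipartitions(bt); o2 <- tree_bipartitions(back)
  ord <- function(b) order(vapply(b$tips, paste, character(1), collapse = ","))
  expect_equal(o1$support[ord(o1)], o2$support[ord(o2)])
  expect_equal(sort(bt$edge.length), sort(back$edge.length),
               tolerance = 1e-9)

  parsed <- read_newick(textConnection("(A:1,B:2,(C:3,D:4)95:1);"))
  pb <- tree_bipartitions(parsed)
  expect_equal(nrow(pb), 1)
  expect_equal(pb$support, 95)
  expect_setequal(pb$tips[[1]], c("C", "D"))

  bad <- tempfile(fileext = ".nwk")
  writeLines("(A:1,B:2", bad)
  expect_error(read_newick(bad), class = "barcodegap_parse_error")
})
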