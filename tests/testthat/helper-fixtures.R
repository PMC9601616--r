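# Shared fixtures: all synthetic, built in code at test time.

make_meta <- function(ids, species) {
  tibble::tibble(sample_id = ids, species = species)
}

# 4 samples, 2 species, 10 aligned sites
small_alignment <- function() {
  seqs <- c(a1 = "ACGTACGTAC", a2 = "ACGTACGAAC",
            b1 = "ACGAACGTTC", b2 = "ACGAACGTTA")
  marker_alignment(seqs, make_meta(names(seqs), c("A", "A", "B", "B")), "m1")
}

# related sequences (common ancestor, modest divergence) so K2P never
# saturates
random_alignment <- function(n, L, seed, n_species = 2, gap_frac = 0,
                             marker = "rand") {
  set.seed(seed)
  anc <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  mat <- do.call(rbind, lapply(seq_len(n), function(i) {
    strsplit(evolve_k2p(anc, runif(1, 0.02, 0.15), kappa = 2), "")[[1]]
  }))
  if (gap_frac > 0) {
    mat[matrix(runif(n * L) < gap_frac, nrow = n)] <- "-"
  }
  ids <- sprintf("s%02d", seq_len(n))
  rownames(mat) <- ids
  sp <- sprintf("sp%d", rep_len(seq_len(n_species), n))
  marker_alignment(mat, make_meta(ids, sp), marker)
}

# random rooted tree with uniform branch lengths and its additive
# path-length matrix
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.05, 1))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

write_temp_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  lines <- character(2 * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  lines[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(lines, path)
  path
}

# independent monophyly oracle: root outside the subset and compare the
# MRCA clade's tip set (handles the trivial subsets directly)
mono_oracle <- function(tree, subset) {
  tips <- tree$tip.label
  if (length(subset) <= 1 || length(subset) >= length(tips) - 1) return(TRUE)
  out <- setdiff(tips, subset)[1]
  rooted <- ape::root(tree, outgroup = out, resolve.root = TRUE)
  mrca <- ape::getMRCA(rooted, subset)
  clade <- ape::extract.clade(rooted, mrca)$tip.label
  setequal(clade, subset)
}
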