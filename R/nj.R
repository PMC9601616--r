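# Neighbor-joining tree construction, nonparametric bootstrap supports,
# bipartition utilities and Newick I/O.

# Run the NJ kernel and return merges plus the tip-index cluster created at
# each merge (these clusters are exactly the internal-edge bipartitions of
# the resulting unrooted tree, one side each).
nj_core <- function(d) {
  n <- nrow(d)
  res <- nj_cpp(d)
  n_merge <- nrow(res$merges)
  members <- vector("list", n + n_merge)
  for (i in seq_len(n)) members[[i]] <- i
  if (n_merge > 0) {
    for (s in seq_len(n_merge)) {
      a <- res$merges[s, 1]; b <- res$merges[s, 2]; u <- res$merges[s, 3]
      members[[u]] <- sort(c(members[[a]], members[[b]]))
    }
  }
  clusters <- if (n_merge > 0) members[n + seq_len(n_merge)] else list()
  list(n = n, merges = res$merges, lengths = res$lengths,
       final_ids = res$final_ids, final_lengths = res$final_lengths,
       members = members, clusters = clusters)
}

# Canonical bipartition key: the side not containing tip 1, as a string of
# sorted tip indices. Equal splits compare equal regardless of which side
# was stored.
bipartition_key <- function(tip_idx, n) {
  if (1L %in% tip_idx) tip_idx <- setdiff(seq_len(n), tip_idx)
  paste(tip_idx, collapse = " ")
}

# Assemble Newick from an nj_core result; internal_labels is a character
# vector aligned with core$clusters ("" = no label).
nj_newick <- function(core, labels, internal_labels = NULL) {
  n <- core$n
  n_merge <- nrow(core$merges)
  if (is.null(internal_labels)) internal_labels <- rep("", max(n_merge, 0))
  str <- vector("character", n + n_merge)
  str[seq_len(n)] <- labels
  if (n_merge > 0) {
    for (s in seq_len(n_merge)) {
      a <- core$merges[s, 1]; b <- core$merges[s, 2]; u <- core$merges[s, 3]
      str[u] <- paste0("(", str[a], ":", fmt_len(core$lengths[s, 1]), ",",
                       str[b], ":", fmt_len(core$lengths[s, 2]), ")",
                       internal_labels[s])
    }
  }
  paste0("(",
         paste0(str[core$final_ids], ":",
                vapply(core$final_lengths, fmt_len, character(1)),
                collapse = ","),
         ");")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: repeatedly joins the pair minimising
#' the rate-corrected criterion `Q_ij = (N-2) d_ij - r_i - r_j`, computes
#' the two branch lengths to the new node, reduces the matrix, and stops
#' when three nodes remain (resolved as the central trifurcation of the
#' unrooted tree). Ties in Q are broken by the first (row, column) pair in
#' the current matrix ordering; negative branch lengths are clamped to zero
#' with the deficit moved to the sister edge. NJ is consistent: on an
#' additive matrix it recovers the generating topology and path lengths
#' exactly.
#'
#' @param dist A [distance_matrix()] result, or a square symmetric numeric
#'   matrix with dimnames.
#' @return An unrooted `phylo` tree (class from \pkg{ape}) with branch
#'   lengths; tips are the matrix sample ids.
#' @export
neighbor_joining <- function(dist) {
  d <- if (inherits(dist, "pairwise_dist")) dist$d else as.matrix(dist)
  if (nrow(d) < 3) {
    abort("neighbor joining needs at least 3 samples", class = "barcodegap_size_error")
  }
  if (!all(is.finite(d))) {
    abort("distance matrix contains non-finite entries", class = "barcodegap_input_error")
  }
  labels <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  check_newick_safe(labels)
  core <- nj_core(d)
  tree <- ape::read.tree(text = nj_newick(core, labels))
  attr(tree, "clusters") <- core$clusters
  tree
}

#' Nonparametric bootstrap supports on the NJ tree
#'
#' Builds the reference NJ tree from the full alignment, then for each
#' replicate resamples alignment columns with replacement, recomputes the
#' distance matrix and NJ tree, and scores every internal edge of the
#' reference tree by the percentage of replicate trees containing the same
#' bipartition. Replicates whose resample leaves a pair with no comparable
#' sites or a saturated K2P distance are redrawn (the count is recorded);
#' more than `10 * n_replicates` total draws aborts.
#'
#' Replicate `r`'s resample depends only on `(seed, r)` (and the redraw
#' attempt number), so runs with the same seed are bit-identical.
#'
#' @param alignment A [marker_alignment()].
#' @param model `"k2p"` (default) or `"p_distance"`.
#' @param n_replicates Number of bootstrap replicates (>= 1; 1000 for
#'   publication-grade supports).
#' @param seed Integer seed driving the column-resampling streams.
#' @return The reference NJ `phylo` with `node.label` holding supports in
#'   percent (the central node has none), plus attributes `support_table`
#'   (tibble: cluster key, support) and `n_redraws`.
#' @export
bootstrap_supports <- function(alignment, model = c("k2p", "p_distance"),
                               n_replicates = 1000, seed = 1) {
  model <- match.arg(model)
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  ids <- sample_ids(alignment)
  check_newick_safe(ids)
  n <- length(ids)
  if (n < 3) abort("bootstrap needs at least 3 samples", class = "barcodegap_size_error")
  L <- alignment_length(alignment)
  codes <- encode_alignment(alignment)
  # pay the O(n^2 L) site scan once; replicates only sum weights over each
  # pair's sparse mismatch/missing site lists
  site_idx <- pair_site_index_cpp(codes)

  dist_from_weights <- function(w) {
    cnt <- pair_counts_indexed_cpp(site_idx, w)
    comp <- cnt$comparable
    off <- upper.tri(comp)
    if (any(comp[off] <= 0)) return(NULL)
    P <- cnt$transitions / comp
    Q <- cnt$transversions / comp
    diag(P) <- 0; diag(Q) <- 0
    if (model == "p_distance") return(P + Q)
    arg1 <- 1 - 2 * P - Q
    arg2 <- 1 - 2 * Q
    if (any((arg1 <= 0 | arg2 <= 0)[off])) return(NULL)
    d <- -0.5 * log(arg1) - 0.25 * log(arg2)
    diag(d) <- 0
    d
  }

  d_ref <- dist_from_weights(rep(1, L))
  if (is.null(d_ref)) {
    abort("reference distance matrix undefined (saturation or no comparable sites)",
          class = "barcodegap_saturation_error")
  }
  dimnames(d_ref) <- list(ids, ids)
  core <- nj_core(d_ref)
  ref_keys <- vapply(core$clusters, bipartition_key, character(1), n = n)
  counts <- setNames(rep(0L, length(ref_keys)), ref_keys)

  n_redraws <- 0L
  max_draws <- 10 * n_replicates
  total_draws <- 0L
  for (r in seq_len(n_replicates)) {
    attempt <- 0L
    repeat {
      total_draws <- total_draws + 1L
      if (total_draws > max_draws) {
        abort("bootstrap resampling failed repeatedly (persistent saturation)",
              class = "barcodegap_bootstrap_error")
      }
      set.seed(derive_seed(seed, r, attempt))
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      d_rep <- dist_from_weights(as.numeric(w))
      if (!is.null(d_rep)) break
      attempt <- attempt + 1L
      n_redraws <- n_redraws + 1L
    }
    rep_core <- nj_core(d_rep)
    rep_keys <- vapply(rep_core$clusters, bipartition_key, character(1), n = n)
    hit <- ref_keys %in% rep_keys
    counts[hit] <- counts[hit] + 1L
  }

  supports <- 100 * counts / n_replicates
  tree <- ape::read.tree(text = nj_newick(core, ids, fmt_len(supports)))
  attr(tree, "clusters") <- core$clusters
  attr(tree, "support_table") <- tibble(cluster = unname(ref_keys),
                                        support = unname(supports))
  attr(tree, "n_redraws") <- n_redraws
  tree
}

#' Bipartitions of an unrooted tree
#'
#' One row per internal edge: the tip labels on the side of the edge away
#' from the storage root, with that edge's support label (if any).
#'
#' @param tree A `phylo` object.
#' @return Tibble with columns `node` (internal node number), `tips`
#'   (list-column of sorted tip labels), `support` (numeric or NA).
#' @export
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  members <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) members[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    members[[p]] <- c(members[[p]], members[[ch]])
  }
  internal <- setdiff(n + seq_len(tree$Nnode), root)
  sup <- rep(NA_real_, length(internal))
  if (!is.null(tree$node.label)) {
    raw <- tree$node.label[internal - n]
    sup <- suppressWarnings(as.numeric(raw))
  }
  tibble(
    node = internal,
    tips = lapply(members[internal], function(ix) sort(tree$tip.label[ix])),
    support = sup
  )
}

#' Write / read trees in Newick format
#'
#' Thin wrappers over \pkg{ape}'s Newick I/O: branch lengths are written
#' with 10 significant digits and bootstrap supports travel as internal
#' node labels, so a write/read round trip preserves the bipartition set,
#' branch lengths and supports.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()`
#'   returns a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) abort(paste0("malformed Newick in ", path, ": ",
                                                    conditionMessage(e)),
                                             class = "barcodegap_parse_error"))
  if (is.null(tree)) {
    abort(paste0("malformed Newick in ", path), class = "barcodegap_parse_error")
  }
  tree
}
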