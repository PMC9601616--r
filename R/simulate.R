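# Multilocus sequence simulator with known species structure: a species
# tree, two-parameter (K80) substitution along its branches, per-marker
# rate multipliers, random-depth within-species divergence, and optional
# single-column lineage deletions.

#' Simulation configuration
#'
#' Parameters of the synthetic multilocus barcode generator. Defaults are
#' the package's reference study design: 20 species of 5 individuals, four
#' markers of 500 bp whose rate multipliers mimic a variable ITS-like
#' marker down to a conserved RPB2-like one, species-tree height 0.10
#' substitutions/site, individual (within-species) branches of 0.002, and
#' transition/transversion rate ratio 2 with no indels.
#'
#' @param n_species Number of species (>= 2).
#' @param individuals_per_species Single integer or per-species vector.
#' @param markers Data frame with columns `name`, `length_bp`,
#'   `rate_multiplier`.
#' @param interspecific_depth Species-tree root height in expected
#'   substitutions/site (every tip is this far from the root).
#' @param intraspecific_depth Within-species divergence scale: each
#'   individual's lineage attaches to its species' ancestral lineage at a
#'   height drawn uniformly on `[0, intraspecific_depth]` (the individual's
#'   branch equals its attachment height, keeping tips contemporaneous).
#'   Conspecific pairwise divergence is then about `2 * max(u_i, u_j)`,
#'   i.e. of order `intraspecific_depth`. When this scale approaches the
#'   species-split heights, individuals attach above their species' origin
#'   and the species signal degrades, emulating unsorted ancestral
#'   polymorphism or introgressed individuals.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param indel_rate Per-column probability of a single-column deletion
#'   event on a random species-tree lineage.
#' @param label_swap_fraction Fraction of individuals whose species label
#'   is reassigned at random (a contamination negative control; default 0).
#' @param seed Integer seed; all randomness derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_species = 20,
                              individuals_per_species = 5,
                              markers = default_markers(),
                              interspecific_depth = 0.10,
                              intraspecific_depth = 0.002,
                              kappa = 2,
                              indel_rate = 0,
                              label_swap_fraction = 0,
                              seed = 1) {
  markers <- as_tibble(markers)
  stopifnot(
    n_species >= 2,
    all(c("name", "length_bp", "rate_multiplier") %in% names(markers)),
    all(markers$length_bp >= 1), all(markers$rate_multiplier > 0),
    interspecific_depth >= 0, intraspecific_depth >= 0, kappa > 0,
    indel_rate >= 0, indel_rate <= 1,
    label_swap_fraction >= 0, label_swap_fraction <= 1
  )
  k <- rep_len(individuals_per_species, n_species)
  stopifnot(all(k >= 1))
  structure(
    list(n_species = as.integer(n_species),
         individuals_per_species = as.integer(k),
         markers = markers,
         interspecific_depth = interspecific_depth,
         intraspecific_depth = intraspecific_depth,
         kappa = kappa, indel_rate = indel_rate,
         label_swap_fraction = label_swap_fraction,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @rdname simulation_config
#' @export
default_markers <- function() {
  tibble(name = c("ITS", "EF1a", "RPB1", "RPB2"),
         length_bp = 500L,
         rate_multiplier = c(1.5, 1.0, 0.9, 0.6))
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> ", x$n_species, " species, ",
      sum(x$individuals_per_species), " individuals, ",
      nrow(x$markers), " markers; inter ", x$interspecific_depth,
      ", intra ", x$intraspecific_depth, ", kappa ", x$kappa,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate an ultrametric species tree
#'
#' Topology by uniformly random sequential pair joins; the n-1 join events
#' sit at equally spaced heights `depth * i / (n-1)`, so the tree is
#' ultrametric with every root-to-tip path equal to `depth` and the two
#' closest species separated by `2 * depth / (n-1)`. This models a set of
#' recognised, mutually divergent species (a stylised radiation) rather
#' than a population sample.
#'
#' @param n_species Number of species (>= 2).
#' @param depth Root height in expected substitutions/site.
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @param labels Optional tip labels (default `sp01`, `sp02`, ...).
#' @return A `phylo` species tree.
#' @export
simulate_species_tree <- function(n_species, depth, seed = NULL, labels = NULL) {
  stopifnot(n_species >= 2, depth >= 0)
  if (!is.null(seed)) set.seed(seed)
  labels <- labels %||% sprintf("sp%02d", seq_len(n_species))
  check_newick_safe(labels)
  str <- labels
  height <- rep(0, n_species)
  active <- seq_len(n_species)
  for (i in seq_len(n_species - 1)) {
    h <- depth * i / (n_species - 1)
    pick <- sort(sample(seq_along(active), 2))
    a <- active[pick[1]]; b <- active[pick[2]]
    str[a] <- paste0("(", str[a], ":", fmt_len(h - height[a]), ",",
                     str[b], ":", fmt_len(h - height[b]), ")")
    height[a] <- h
    active <- active[-pick[2]]
  }
  ape::read.tree(text = paste0(str[active[1]], ";"))
}

# K80 per-site substitution probabilities after branch length t (expected
# substitutions/site), rate ratio kappa. alpha + 2 beta = 1 normalises the
# total rate so t is in substitutions/site.
k80_site_probs <- function(t, kappa) {
  alpha <- kappa / (kappa + 2)
  beta <- 1 / (kappa + 2)
  p_tv <- 0.25 - 0.25 * exp(-4 * beta * t)          # each of 2 transversions
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  c(ts = p_ts, tv = p_tv)
}

#' Evolve a sequence under the two-parameter substitution model
#'
#' Each site mutates independently using the closed-form K80 site
#' substitution probabilities for the branch length (expected
#' substitutions/site; transitions at `kappa` times the rate of each
#' transversion). Gap or ambiguous positions are carried through
#' unchanged.
#'
#' @param parent_seq Parent sequence (string or character vector).
#' @param branch_length Branch length >= 0 in expected substitutions/site.
#' @param kappa Transition/transversion rate ratio.
#' @param seed Optional seed (`NULL`: current RNG state).
#' @return Child sequence as a single string.
#' @export
evolve_k2p <- function(parent_seq, branch_length, kappa = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codes <- encode_chars(as_char_seq(parent_seq))
  child <- evolve_codes(codes, branch_length, kappa)
  chars <- as_char_seq(parent_seq)
  chars[child >= 0] <- names(CODE_MAP)[child[child >= 0] + 1]
  paste(chars, collapse = "")
}

evolve_codes <- function(codes, branch_length, kappa) {
  stopifnot(branch_length >= 0)
  if (branch_length == 0) return(codes)
  pr <- k80_site_probs(branch_length, kappa)
  L <- length(codes)
  u <- runif(L)
  ok <- codes >= 0
  out <- codes
  # transition partner = code xor 2; the two transversion partners = xor 1, xor 3
  mut1 <- ok & u < pr["ts"]
  mut2 <- ok & u >= pr["ts"] & u < pr["ts"] + pr["tv"]
  mut3 <- ok & u >= pr["ts"] + pr["tv"] & u < pr["ts"] + 2 * pr["tv"]
  out[mut1] <- bitwXor(codes[mut1], 2L)
  out[mut2] <- bitwXor(codes[mut2], 1L)
  out[mut3] <- bitwXor(codes[mut3], 3L)
  out
}

#' Simulate a multilocus barcode data set with known species structure
#'
#' Draws a species tree and one attachment height per individual (uniform
#' on `[0, intraspecific_depth]`, shared across markers), grafts each
#' individual onto its species' ancestral lineage at that height, and per
#' marker evolves a uniform-random ancestral sequence down this genealogy
#' with branch lengths scaled by the marker's rate multiplier.
#' Single-column deletions are applied on random species-tree lineages at
#' `indel_rate`. All randomness flows from `config$seed` via fixed
#' per-marker streams.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_dataset`: list with `alignments` (named list of
#'   [marker_alignment()]), `species` (truth metadata tibble),
#'   `species_tree` (`phylo`), `realized_stats` (per-marker mean intra and
#'   inter K2P divergence), and the `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_sp <- config$n_species
  k <- config$individuals_per_species
  sp_labels <- sprintf("sp%02d", seq_len(n_sp))
  tree <- simulate_species_tree(n_sp, config$interspecific_depth,
                                seed = derive_seed(config$seed, 1),
                                labels = sp_labels)
  ids <- unlist(lapply(seq_len(n_sp), function(s) {
    sprintf("%s_i%02d", sp_labels[s], seq_len(k[s]))
  }))
  species_of <- rep(sp_labels, k)
  meta <- tibble(sample_id = ids, species = species_of)

  if (config$label_swap_fraction > 0) {
    set.seed(derive_seed(config$seed, 9))
    n_swap <- floor(config$label_swap_fraction * length(ids))
    if (n_swap > 0) {
      swap <- sample(seq_along(ids), n_swap)
      meta$species[swap] <- sample(sp_labels, n_swap, replace = TRUE)
    }
  }

  # species-tree traversal order (parent before child)
  pre <- ape::reorder.phylo(tree, "cladewise")
  n_nodes <- n_sp + tree$Nnode
  root <- n_sp + 1L
  depth <- config$interspecific_depth

  # node heights above the present (tree is ultrametric with root = depth)
  from_root <- ape::node.depth.edgelength(tree)
  heights <- max(from_root) - from_root
  heights[abs(heights) < 1e-12] <- 0
  parent_of <- integer(n_nodes)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]

  # one attachment height per individual, shared across markers: the whole
  # multilocus genotype descends from one point on the species' lineage
  set.seed(derive_seed(config$seed, 4))
  u_attach <- runif(length(ids), 0, config$intraspecific_depth)
  if (depth > 0) u_attach <- pmin(u_attach, depth * (1 - 1e-9)) else u_attach[] <- 0

  # per-edge attachment lists: individual idx attaches to the edge of its
  # species' root-to-tip path spanning its height
  edge_attach <- vector("list", n_nodes)  # indexed by child node of the edge
  for (i in seq_along(ids)) {
    tip <- match(species_of[i], tree$tip.label)
    node <- tip
    # climb to the path edge whose span [height(node), height(parent))
    # contains the attachment height
    while (node != root) {
      hp <- heights[parent_of[node]]
      if (u_attach[i] < hp || hp <= heights[node]) break
      node <- parent_of[node]
    }
    edge_attach[[node]] <- c(edge_attach[[node]], i)
  }

  alignments <- list()
  for (m in seq_len(nrow(config$markers))) {
    mk <- config$markers[m, ]
    set.seed(derive_seed(config$seed, 2, m))
    L <- mk$length_bp
    mult <- mk$rate_multiplier
    node_seq <- vector("list", n_nodes)
    node_seq[[root]] <- sample(0:3, L, replace = TRUE)
    rows <- matrix(NA_integer_, nrow = length(ids), ncol = L,
                   dimnames = list(ids, NULL))
    evolve_edge <- function(ch) {
      par <- parent_of[ch]
      cur <- node_seq[[par]]
      cur_h <- heights[par]
      att <- edge_attach[[ch]]
      if (length(att)) att <- att[order(u_attach[att], decreasing = TRUE)]
      for (i in att) {
        u <- u_attach[i]
        cur <- evolve_codes(cur, (cur_h - u) * mult, config$kappa)
        rows[ids[i], ] <<- evolve_codes(cur, u * mult, config$kappa)
        cur_h <- u
      }
      node_seq[[ch]] <<- evolve_codes(cur, (cur_h - heights[ch]) * mult,
                                      config$kappa)
    }
    for (e in seq_len(nrow(pre$edge))) evolve_edge(pre$edge[e, 2])
    chars <- matrix(names(CODE_MAP)[rows + 1], nrow = nrow(rows),
                    dimnames = dimnames(rows))
    if (config$indel_rate > 0) {
      del_cols <- which(runif(L) < config$indel_rate)
      for (col in del_cols) {
        edge <- sample(nrow(tree$edge), 1)
        desc <- descendant_tips(tree, tree$edge[edge, 2])
        affected <- species_of %in% tree$tip.label[desc]
        chars[affected, col] <- "-"
      }
    }
    alignments[[mk$name]] <- marker_alignment(chars, meta, marker = mk$name)
  }

  realized <- dplyr::bind_rows(lapply(alignments, function(a) {
    part <- partition_by_species(distance_matrix(a, model = "k2p"))
    tibble(marker = a$marker,
           mean_intra = if (length(part$pooled_intra)) mean(part$pooled_intra) else NA_real_,
           mean_inter = mean(part$pooled_inter))
  }))

  structure(
    list(alignments = alignments, species = meta, species_tree = tree,
         realized_stats = realized, config = config),
    class = "simulated_dataset"
  )
}

descendant_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  po <- ape::reorder.phylo(tree, "postorder")
  members <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) members[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    members[[p]] <- c(members[[p]], members[[ch]])
  }
  members[[node]]
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset> ", x$config$n_species, " species, ",
      nrow(x$species), " individuals, markers: ",
      paste(names(x$alignments), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a simulated data set to disk
#'
#' Emits one aligned FASTA per marker, the metadata TSV, the true species
#' tree in Newick, and a YAML echo of the configuration.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in sim$alignments) {
    write_alignment_fasta(a, file.path(dir, paste0(a$marker, ".fasta")))
  }
  readr::write_tsv(sim$species, file.path(dir, "metadata.tsv"), progress = FALSE)
  write_newick(sim$species_tree, file.path(dir, "species_tree.nwk"))
  cfg <- sim$config
  cfg_list <- list(
    n_species = cfg$n_species,
    individuals_per_species = cfg$individuals_per_species,
    markers = lapply(seq_len(nrow(cfg$markers)), function(i) as.list(cfg$markers[i, ])),
    interspecific_depth = cfg$interspecific_depth,
    intraspecific_depth = cfg$intraspecific_depth,
    kappa = cfg$kappa, indel_rate = cfg$indel_rate,
    label_swap_fraction = cfg$label_swap_fraction, seed = cfg$seed
  )
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  invisible(dir)
}
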