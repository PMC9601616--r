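# Tree-based species discrimination: bootstrap-supported monophyly.

#' Is a set of tips monophyletic on an unrooted tree?
#'
#' On an unrooted tree a tip subset is monophyletic when some edge's
#' bipartition has one side exactly equal to the subset. Singleton subsets
#' (and the pendant-edge cases: the full tip set or all-but-one tip) are
#' monophyletic by convention with undefined support.
#'
#' @param tree A `phylo` object (optionally with bootstrap supports as
#'   internal node labels).
#' @param tip_subset Character vector of tip labels (non-empty, all present
#'   in the tree).
#' @return One-row tibble: `is_monophyletic` (logical), `support_pct`
#'   (numeric, `NA` when the subtending edge carries no support or the
#'   subset is trivial).
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((a1:1,a2:1)90:1,(b1:1,b2:1)80:1,c1:1);")
#' is_species_monophyletic(tr, c("a1", "a2"))
is_species_monophyletic <- function(tree, tip_subset) {
  tips <- tree$tip.label
  unknown <- setdiff(tip_subset, tips)
  if (length(tip_subset) == 0 || length(unknown) > 0) {
    abort(paste0("unknown tip label(s): ", paste(head(unknown, 5), collapse = ", ")),
          class = "barcodegap_input_error")
  }
  k <- length(unique(tip_subset))
  n <- length(tips)
  if (k == 1 || k >= n - 1) {
    return(tibble(is_monophyletic = TRUE, support_pct = NA_real_))
  }
  want <- sort(unique(tip_subset))
  comp <- sort(setdiff(tips, want))
  bip <- tree_bipartitions(tree)
  for (i in seq_len(nrow(bip))) {
    side <- bip$tips[[i]]
    if (length(side) == k && identical(side, want)) {
      return(tibble(is_monophyletic = TRUE, support_pct = bip$support[i]))
    }
    if (length(side) == n - k && identical(side, comp)) {
      return(tibble(is_monophyletic = TRUE, support_pct = bip$support[i]))
    }
  }
  tibble(is_monophyletic = FALSE, support_pct = NA_real_)
}

#' Per-species monophyly records on a tree
#'
#' @param tree A `phylo` whose tips are sample ids.
#' @param species Data frame (`sample_id`, `species`) or named character
#'   vector labelling every tip.
#' @param support_threshold Minimum bootstrap support (percent, strict
#'   inequality) for a multi-individual species to count as identified.
#' @param singleton_policy Count singleton species as successes
#'   (`"count"`, default) or drop them (`"exclude"`).
#' @return Tibble: `species`, `n_individuals`, `is_monophyletic`,
#'   `support_pct`, `success`. When a species is monophyletic but its edge
#'   has no support annotation, success falls back to topology alone with
#'   one warning.
#' @export
monophyly_records <- function(tree, species, support_threshold = 50,
                              singleton_policy = c("count", "exclude")) {
  singleton_policy <- match.arg(singleton_policy)
  sp <- species
  if (is.data.frame(sp)) sp <- setNames(sp$species, sp$sample_id)
  tips <- tree$tip.label
  unlabeled <- setdiff(tips, names(sp))
  if (length(unlabeled) > 0) {
    abort(paste0("tree tip(s) missing from metadata: ",
                 paste(head(unlabeled, 5), collapse = ", ")),
          class = "barcodegap_input_error")
  }
  sp <- sp[tips]
  warned <- FALSE
  rows <- lapply(unique(sp), function(s) {
    members <- tips[sp == s]
    mono <- is_species_monophyletic(tree, members)
    n_ind <- length(members)
    if (n_ind == 1) {
      success <- if (singleton_policy == "count") TRUE else NA
    } else if (!mono$is_monophyletic) {
      success <- FALSE
    } else if (is.na(mono$support_pct)) {
      if (!warned) {
        warn("monophyletic species without support annotation: scoring on topology alone")
        warned <<- TRUE
      }
      success <- TRUE
    } else {
      success <- mono$support_pct > support_threshold
    }
    tibble(species = s, n_individuals = n_ind,
           is_monophyletic = mono$is_monophyletic,
           support_pct = mono$support_pct, success = success)
  })
  dplyr::bind_rows(rows)
}

#' Tree-method species discrimination rate
#'
#' One monophyly record per species; a multi-individual species is
#' successfully identified when it is monophyletic with bootstrap support
#' strictly above the threshold (default >50), singletons per policy. The
#' rate is successes over species evaluated, as a half-up two-decimal
#' percentage.
#'
#' @inheritParams monophyly_records
#' @param marker_set,model Labels for the result row.
#' @return One-row tibble as in [pwg_discrimination_rate()] with
#'   `method = "nj_tree"`, carrying the per-species records in attribute
#'   `records`.
#' @export
tree_discrimination_rate <- function(tree, species, support_threshold = 50,
                                     marker_set = "", model = "k2p",
                                     singleton_policy = c("count", "exclude")) {
  records <- monophyly_records(tree, species, support_threshold = support_threshold,
                               singleton_policy = singleton_policy)
  out <- pwg_discrimination_rate(records, marker_set = marker_set, model = model,
                                 method = "nj_tree")
  attr(out, "records") <- records
  out
}
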