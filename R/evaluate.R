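# Full evaluation sweep over every marker set x method x model, and the
# table renderer / verifier for its outputs.

#' Run the full barcode evaluation sweep
#'
#' For every non-empty subset of the marker catalog: concatenates the
#' member alignments, computes the pairwise distance matrix under each
#' requested model, evaluates the PWG-distance barcoding-gap criterion per
#' species, builds the NJ tree with bootstrap supports and scores
#' bootstrap-supported species monophyly, and collects one discrimination
#' row per (marker set, method, model). Per-marker variability statistics
#' and barcoding-gap histograms are computed alongside. A failure in one
#' marker set is recorded and the sweep continues. Fully deterministic
#' given `seed`.
#'
#' @param alignments Named list of [marker_alignment()] objects (the marker
#'   catalog, in order).
#' @param models Distance models to evaluate (`"k2p"`, `"p_distance"`).
#' @param methods Methods to evaluate (`"pwg_distance"`, `"nj_tree"`).
#' @param n_bootstrap Bootstrap replicates for tree supports (default
#'   1000).
#' @param support_threshold Bootstrap support (percent) a species clade
#'   must strictly exceed (default 50).
#' @param singleton_policy Singleton species handling, `"count"` or
#'   `"exclude"` (applies to both methods).
#' @param missing_policy Concatenation policy, see
#'   [concatenate_markers()].
#' @param bin_width Histogram bin width; `NULL` disables histograms.
#' @param pwg_mixed Use the mixed literal criterion (intra side under
#'   p-distance, inter side under K2P) for the PWG method's K2P rows.
#' @param saturation K2P saturation handling for full matrices (see
#'   [distance_matrix()]).
#' @param seed Integer seed for all bootstrap streams.
#' @return A `barcode_evaluation` object: list with tibbles `rates`,
#'   `variability`, `gap_records`, `monophyly`, named lists `trees`
#'   (`phylo` per "set|model") and `histograms`, a tibble `errors`, and
#'   the echoed `config`.
#' @export
run_evaluation <- function(alignments,
                           models = c("k2p", "p_distance"),
                           methods = c("pwg_distance", "nj_tree"),
                           n_bootstrap = 1000,
                           support_threshold = 50,
                           singleton_policy = c("count", "exclude"),
                           missing_policy = "intersect",
                           bin_width = 0.005,
                           pwg_mixed = FALSE,
                           saturation = "error",
                           seed = 1) {
  singleton_policy <- match.arg(singleton_policy)
  models <- match.arg(models, c("k2p", "p_distance"), several.ok = TRUE)
  methods <- match.arg(methods, c("pwg_distance", "nj_tree"), several.ok = TRUE)
  stopifnot(length(alignments) >= 1, n_bootstrap >= 1)
  catalog <- vapply(alignments, function(a) a$marker, character(1))
  names(alignments) <- catalog
  sets <- enumerate_marker_sets(catalog)
  pwg_policy <- if (singleton_policy == "count")
    "count_success_if_positive_inter" else "exclude"

  rates <- list(); gap_records <- list(); mono_records <- list()
  trees <- list(); histograms <- list(); errors <- list()
  set_idx <- 0L

  for (set_name in names(sets)) {
    set_idx <- set_idx + 1L
    stage <- "concatenate"
    res <- tryCatch({
      concat <- concatenate_markers(alignments, sets[[set_name]],
                                    missing_policy = missing_policy)
      meta <- tibble(sample_id = sample_ids(concat),
                     species = unname(concat$species))
      for (mi in seq_along(models)) {
        model <- models[mi]
        stage <- paste0("distance/", model)
        dmat <- distance_matrix(concat, model = model, saturation = saturation)
        part <- partition_by_species(dmat)
        if ("pwg_distance" %in% methods) {
          stage <- paste0("pwg/", model)
          intra_part <- NULL
          if (pwg_mixed && model == "k2p") {
            dp <- distance_matrix(concat, model = "p_distance")
            intra_part <- partition_by_species(dp)
          }
          rec <- pwg_species_test(part, singleton_policy = pwg_policy,
                                  intra_partition = intra_part)
          gap_records[[paste0(set_name, "|", model)]] <-
            dplyr::mutate(rec, marker_set = set_name, model = model,
                          .before = 1)
          rates[[length(rates) + 1L]] <-
            pwg_discrimination_rate(rec, marker_set = set_name, model = model)
        }
        if ("nj_tree" %in% methods) {
          stage <- paste0("nj_tree/", model)
          tree <- bootstrap_supports(concat, model = model,
                                     n_replicates = n_bootstrap,
                                     seed = derive_seed(seed, 3,
                                                        set_idx * 10 + mi))
          trees[[paste0(set_name, "|", model)]] <- tree
          rate <- tree_discrimination_rate(tree, meta,
                                           support_threshold = support_threshold,
                                           marker_set = set_name, model = model,
                                           singleton_policy = singleton_policy)
          mono_records[[paste0(set_name, "|", model)]] <-
            dplyr::mutate(attr(rate, "records"), marker_set = set_name,
                          model = model, .before = 1)
          attr(rate, "records") <- NULL
          rates[[length(rates) + 1L]] <- rate
        }
        if (model == "k2p" && !is.null(bin_width)) {
          stage <- "histogram"
          histograms[[set_name]] <- divergence_histogram(part, bin_width)
        }
      }
      NULL
    }, error = function(e) {
      tibble(marker_set = set_name, stage = stage,
             message = conditionMessage(e))
    })
    if (!is.null(res)) errors[[length(errors) + 1L]] <- res
  }

  stage <- "variability"
  variability <- dplyr::bind_rows(lapply(alignments, function(a) {
    tryCatch(variability_stats(a, saturation = "cap"),
             error = function(e) tibble(marker = a$marker))
  }))

  structure(
    list(
      rates = dplyr::bind_rows(rates),
      variability = variability,
      gap_records = dplyr::bind_rows(gap_records),
      monophyly = dplyr::bind_rows(mono_records),
      trees = trees,
      histograms = histograms,
      errors = dplyr::bind_rows(errors),
      config = list(markers = unname(catalog), models = models,
                    methods = methods, n_bootstrap = n_bootstrap,
                    support_threshold = support_threshold,
                    singleton_policy = singleton_policy,
                    missing_policy = missing_policy,
                    bin_width = bin_width, pwg_mixed = pwg_mixed,
                    saturation = saturation, seed = seed)
    ),
    class = "barcode_evaluation"
  )
}

#' @export
print.barcode_evaluation <- function(x, ...) {
  cat("<barcode_evaluation> ", nrow(x$rates), " rate rows over ",
      length(unique(x$rates$marker_set)), " marker sets; ",
      nrow(x$errors), " failures\n", sep = "")
  if (nrow(x$rates)) print(x$rates, n = 10)
  invisible(x)
}

#' @rdname run_evaluation
#' @param x A `barcode_evaluation`.
#' @param ... Unused.
#' @return For `tidy()`: the long discrimination-rate tibble. For
#'   `glance()`: a one-row summary (grid size, failure count, best rate
#'   per method).
#' @method tidy barcode_evaluation
#' @export
tidy.barcode_evaluation <- function(x, ...) x$rates

#' @rdname run_evaluation
#' @method glance barcode_evaluation
#' @export
glance.barcode_evaluation <- function(x, ...) {
  best <- dplyr::slice_max(dplyr::group_by(x$rates, .data$method),
                           .data$rate_pct, n = 1, with_ties = FALSE)
  tibble(
    n_marker_sets = length(unique(x$rates$marker_set)),
    n_rows = nrow(x$rates),
    n_failures = nrow(x$errors),
    best_pwg_rate = if ("pwg_distance" %in% best$method)
      best$rate_pct[best$method == "pwg_distance"] else NA_real_,
    best_tree_rate = if ("nj_tree" %in% best$method)
      best$rate_pct[best$method == "nj_tree"] else NA_real_
  )
}

#' Write the evaluation's output tables
#'
#' Emits `variability.tsv` (per single marker), `rates.tsv` (long),
#' `rates_wide.tsv` (marker set x method/model grid), `metadata.tsv`,
#' per-set `histograms/*.tsv`, `trees/*.nwk`, `gap_records/*.tsv`,
#' `monophyly/*.tsv` and a `manifest.yaml` echoing the configuration and
#' seed. Reruns with the same inputs and seed are byte-identical.
#'
#' @param eval A [run_evaluation()] result.
#' @param output_dir Output directory (created if needed).
#' @param metadata Optional metadata tibble to persist alongside.
#' @return `output_dir`, invisibly.
#' @export
render_tables <- function(eval, output_dir, metadata = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, ...) readr::write_tsv(df, file.path(output_dir, ...),
                                          progress = FALSE)
  w(eval$variability, "variability.tsv")
  w(eval$rates, "rates.tsv")
  wide <- tidyr::pivot_wider(
    eval$rates,
    id_cols = "marker_set",
    names_from = c("method", "model"),
    values_from = "rate_pct"
  )
  w(wide, "rates_wide.tsv")
  if (!is.null(metadata)) w(metadata, "metadata.tsv")
  if (length(eval$histograms)) {
    dir.create(file.path(output_dir, "histograms"), showWarnings = FALSE)
    for (nm in names(eval$histograms)) {
      w(as_tibble(eval$histograms[[nm]]), "histograms", paste0(nm, ".tsv"))
    }
  }
  if (length(eval$trees)) {
    dir.create(file.path(output_dir, "trees"), showWarnings = FALSE)
    for (nm in names(eval$trees)) {
      write_newick(eval$trees[[nm]],
                   file.path(output_dir, "trees",
                             paste0(gsub("\\|", "_", nm), ".nwk")))
    }
  }
  if (nrow(eval$gap_records)) {
    dir.create(file.path(output_dir, "gap_records"), showWarnings = FALSE)
    for (grp in split(eval$gap_records,
                      paste0(eval$gap_records$marker_set, "_",
                             eval$gap_records$model))) {
      w(grp, "gap_records",
        paste0(grp$marker_set[1], "_", grp$model[1], ".tsv"))
    }
  }
  if (nrow(eval$monophyly)) {
    dir.create(file.path(output_dir, "monophyly"), showWarnings = FALSE)
    for (grp in split(eval$monophyly,
                      paste0(eval$monophyly$marker_set, "_",
                             eval$monophyly$model))) {
      w(grp, "monophyly",
        paste0(grp$marker_set[1], "_", grp$model[1], ".tsv"))
    }
  }
  manifest <- c(eval$config,
                list(package = "barcodegap",
                     version = as.character(utils::packageVersion("barcodegap"))))
  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  invisible(output_dir)
}

#' Verify rendered tables against their own records
#'
#' Self-consistency check on a [render_tables()] directory: every
#' discrimination row in `rates.tsv` is recomputed from the persisted
#' per-species records — PWG rows from `gap_records/`, tree rows by
#' re-scoring monophyly on the persisted `trees/*.nwk` against
#' `metadata.tsv` with the manifest's support threshold.
#'
#' @param output_dir A directory written by [render_tables()].
#' @return Tibble with one row per rate row: `marker_set`, `method`,
#'   `model`, `stored`, `recomputed`, `ok`. All `ok` must be `TRUE` for a
#'   consistent run.
#' @export
verify_tables <- function(output_dir) {
  rates <- readr::read_tsv(file.path(output_dir, "rates.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  manifest <- yaml::read_yaml(file.path(output_dir, "manifest.yaml"))
  meta_path <- file.path(output_dir, "metadata.tsv")
  meta <- if (file.exists(meta_path)) read_species_map(meta_path) else NULL
  rows <- lapply(seq_len(nrow(rates)), function(i) {
    r <- rates[i, ]
    recomputed <- NA_real_
    if (r$method == "pwg_distance") {
      gp <- file.path(output_dir, "gap_records",
                      paste0(r$marker_set, "_", r$model, ".tsv"))
      rec <- readr::read_tsv(gp, show_col_types = FALSE, progress = FALSE)
      keep <- !is.na(rec$success)
      recomputed <- discrimination_rate_pct(sum(rec$success[keep]), sum(keep))
    } else if (r$method == "nj_tree" && !is.null(meta)) {
      tp <- file.path(output_dir, "trees",
                      paste0(r$marker_set, "_", r$model, ".nwk"))
      tree <- read_newick(tp)
      rr <- suppressWarnings(tree_discrimination_rate(
        tree, meta,
        support_threshold = manifest$support_threshold,
        marker_set = r$marker_set, model = r$model,
        singleton_policy = manifest$singleton_policy))
      recomputed <- rr$rate_pct
    }
    tibble(marker_set = r$marker_set, method = r$method, model = r$model,
           stored = r$rate_pct, recomputed = recomputed,
           ok = isTRUE(all.equal(r$rate_pct, recomputed)))
  })
  dplyr::bind_rows(rows)
}
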