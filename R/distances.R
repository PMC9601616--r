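# Pairwise p and Kimura 2-parameter distances with pairwise deletion,
# full distance matrices, and intra/inter species partitioning.

CODE_MAP <- c(A = 0L, C = 1L, G = 2L, T = 3L)

encode_chars <- function(chars) {
  out <- unname(CODE_MAP[chars])
  out[is.na(out)] <- -1L
  out
}

# L x n integer code matrix (sites in rows) for the C++ kernel
encode_alignment <- function(alignment) {
  mat <- alignment$seq
  codes <- matrix(encode_chars(as.vector(t(mat))),
                  nrow = ncol(mat), ncol = nrow(mat))
  colnames(codes) <- rownames(mat)
  codes
}

as_char_seq <- function(x) {
  if (length(x) == 1 && nchar(x) > 1) x <- strsplit(x, "")[[1]]
  toupper(x)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Sites where either sequence has a gap, `N`, or an ambiguity code are
#' excluded (pairwise deletion); `p` is the proportion of mismatches among
#' the remaining comparable sites.
#'
#' @param seq_a,seq_b Aligned sequences of equal length (strings or
#'   character vectors).
#' @return One-row tibble: `p`, `n_comparable`.
#' @export
#' @examples
#' p_distance_pair("ACGT", "ACGA") # p = 0.25 over 4 sites
p_distance_pair <- function(seq_a, seq_b) {
  a <- encode_chars(as_char_seq(seq_a))
  b <- encode_chars(as_char_seq(seq_b))
  if (length(a) != length(b)) abort("sequences must have equal aligned length")
  ok <- a >= 0 & b >= 0
  n <- sum(ok)
  if (n == 0) {
    abort("no comparable sites between the two sequences",
          class = "barcodegap_undefined_distance_error")
  }
  tibble(p = sum(a[ok] != b[ok]) / n, n_comparable = n)
}

k2p_from_PQ <- function(P, Q, saturation = c("error", "cap"), d_max = 5) {
  saturation <- match.arg(saturation)
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  bad <- arg1 <= 0 | arg2 <= 0
  d <- rep(NA_real_, length(P))
  d[!bad] <- -0.5 * log(arg1[!bad]) - 0.25 * log(arg2[!bad])
  if (any(bad)) {
    if (saturation == "error") {
      abort("K2P distance undefined (substitution saturation): 1-2P-Q or 1-2Q <= 0",
            class = "barcodegap_saturation_error")
    }
    d[bad] <- d_max
  }
  d
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' With `P` and `Q` the transition (A<->G, C<->T) and transversion
#' proportions among comparable sites (pairwise deletion, as in
#' [p_distance_pair()]), the distance is
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#' When the logarithm arguments are non-positive the pair is saturated:
#' by default this errors, or with `saturation = "cap"` the distance is
#' capped at `d_max`.
#'
#' @inheritParams p_distance_pair
#' @param saturation `"error"` (default) or `"cap"`.
#' @param d_max Cap value used when `saturation = "cap"`.
#' @return One-row tibble: `d`, `P`, `Q`, `n_comparable`.
#' @export
#' @examples
#' k2p_distance_pair("ACGT", "GCGT") # one transition: d = -log(0.5)/2
k2p_distance_pair <- function(seq_a, seq_b, saturation = c("error", "cap"),
                              d_max = 5) {
  a <- encode_chars(as_char_seq(seq_a))
  b <- encode_chars(as_char_seq(seq_b))
  if (length(a) != length(b)) abort("sequences must have equal aligned length")
  ok <- a >= 0 & b >= 0
  n <- sum(ok)
  if (n == 0) {
    abort("no comparable sites between the two sequences",
          class = "barcodegap_undefined_distance_error")
  }
  diff <- a[ok] != b[ok]
  ts <- sum(diff & bitwXor(a[ok], b[ok]) == 2L)
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  tibble(d = k2p_from_PQ(P, Q, saturation = saturation, d_max = d_max),
         P = P, Q = Q, n_comparable = n)
}

#' Pairwise distance matrix of an alignment
#'
#' Computes all n(n-1)/2 pairwise distances under the chosen model with
#' pairwise deletion of gaps, `N` and ambiguity codes. K2P saturation and
#' pairs with zero comparable sites are reported with the offending pair
#' identified (or capped, for K2P, with `saturation = "cap"`).
#'
#' @param alignment A [marker_alignment()] with >= 2 samples.
#' @param model `"k2p"` (default) or `"p_distance"`.
#' @param saturation,d_max See [k2p_distance_pair()].
#' @param site_weights Optional per-site non-negative weights (used by the
#'   bootstrap to resample columns without copying the alignment).
#' @return A `pairwise_dist` object: list with `model`, `sample_ids`,
#'   `species`, square matrices `d` and `comparable`, and for K2P also
#'   `P` and `Q`.
#' @export
distance_matrix <- function(alignment, model = c("k2p", "p_distance"),
                            saturation = c("error", "cap"), d_max = 5,
                            site_weights = NULL) {
  model <- match.arg(model)
  saturation <- match.arg(saturation)
  if (nrow(alignment$seq) < 2) abort("need at least 2 samples")
  codes <- encode_alignment(alignment)
  w <- site_weights %||% rep(1, nrow(codes))
  if (length(w) != nrow(codes)) abort("site_weights length must equal alignment length")
  cnt <- pair_counts_cpp(codes, as.numeric(w))
  n <- ncol(codes)
  ids <- colnames(codes)
  comp <- cnt$comparable
  off <- upper.tri(comp)
  if (any(comp[off] <= 0)) {
    idx <- which(comp <= 0 & off, arr.ind = TRUE)[1, ]
    abort(paste0("no comparable sites for pair ", ids[idx[1]], " / ", ids[idx[2]]),
          class = "barcodegap_undefined_distance_error")
  }
  P <- cnt$transitions / comp
  Q <- cnt$transversions / comp
  diag(P) <- 0; diag(Q) <- 0
  if (model == "p_distance") {
    d <- P + Q
  } else {
    arg1 <- 1 - 2 * P - Q
    arg2 <- 1 - 2 * Q
    bad <- (arg1 <= 0 | arg2 <= 0) & off
    if (any(bad)) {
      if (saturation == "error") {
        idx <- which(bad, arr.ind = TRUE)[1, ]
        abort(paste0("K2P saturation for pair ", ids[idx[1]], " / ", ids[idx[2]]),
              class = "barcodegap_saturation_error")
      }
    }
    d <- -0.5 * log(pmax(arg1, .Machine$double.xmin)) -
      0.25 * log(pmax(arg2, .Machine$double.xmin))
    d[bad | t(bad)] <- d_max
    diag(d) <- 0
  }
  dimnames(d) <- list(ids, ids)
  out <- list(model = model, sample_ids = ids, species = alignment$species,
              d = d, comparable = comp)
  if (model == "k2p") { out$P <- P; out$Q <- Q }
  structure(out, class = "pairwise_dist")
}

#' @export
print.pairwise_dist <- function(x, ...) {
  cat("<pairwise_dist> ", length(x$sample_ids), " samples, model ", x$model,
      ", mean distance ", signif(mean(x$d[upper.tri(x$d)]), 4), "\n", sep = "")
  invisible(x)
}

#' @rdname distance_matrix
#' @param x A `pairwise_dist` object.
#' @param ... Unused.
#' @return For `tidy()`: a long tibble with one row per unordered pair
#'   (`sample_a`, `sample_b`, `distance`, `n_comparable`, `same_species`).
#' @method tidy pairwise_dist
#' @export
tidy.pairwise_dist <- function(x, ...) {
  ut <- which(upper.tri(x$d), arr.ind = TRUE)
  sp <- x$species
  out <- tibble(
    sample_a = x$sample_ids[ut[, 1]],
    sample_b = x$sample_ids[ut[, 2]],
    distance = x$d[ut],
    n_comparable = x$comparable[ut]
  )
  if (!is.null(sp) && length(sp) > 0) {
    out$same_species <- sp[out$sample_a] == sp[out$sample_b]
  }
  out
}

#' Split pairwise distances into intra- and interspecific sets
#'
#' For each species, collects the distances among its own individuals
#' (intra) and from its individuals to every heterospecific sample (inter).
#' The pooled lists contain every unordered pair exactly once; per-species
#' inter lists necessarily share elements between the two species of a
#' pair.
#'
#' @param dist A [distance_matrix()] result.
#' @param species Named character vector (sample id -> species label) or a
#'   data frame with `sample_id` and `species`; defaults to the labels
#'   carried by the distance matrix.
#' @return A `distance_partition`: list with `per_species` tibble
#'   (`species`, `n_individuals`, list-columns `intra`, `inter`),
#'   `pooled_intra`, `pooled_inter`.
#' @export
partition_by_species <- function(dist, species = NULL) {
  sp <- species %||% dist$species
  if (is.data.frame(sp)) sp <- setNames(sp$species, sp$sample_id)
  sp <- sp[dist$sample_ids]
  if (anyNA(sp)) {
    abort(paste0("unlabeled sample(s): ",
                 paste(head(dist$sample_ids[is.na(sp)], 5), collapse = ", ")),
          class = "barcodegap_metadata_error")
  }
  d <- dist$d
  same <- outer(sp, sp, "==")
  ut <- upper.tri(d)
  per <- lapply(unique(sp), function(s) {
    idx <- which(sp == s)
    intra <- if (length(idx) >= 2) d[idx, idx][upper.tri(diag(length(idx)))] else numeric(0)
    inter <- as.vector(d[idx, sp != s, drop = FALSE])
    tibble(species = s, n_individuals = length(idx),
           intra = list(unname(intra)), inter = list(unname(inter)))
  })
  structure(
    list(
      per_species = dplyr::bind_rows(per),
      pooled_intra = unname(d[ut & same]),
      pooled_inter = unname(d[ut & !same]),
      model = dist$model
    ),
    class = "distance_partition"
  )
}

#' @export
print.distance_partition <- function(x, ...) {
  cat("<distance_partition> ", nrow(x$per_species), " species, ",
      length(x$pooled_intra), " intraspecific and ",
      length(x$pooled_inter), " interspecific pairs\n", sep = "")
  invisible(x)
}

#' Write / read a square distance matrix
#'
#' `write_dist_tsv()` writes a square TSV with sample ids as header row and
#' first column; `write_dist_phylip()` writes PHYLIP square format and
#' `read_dist_phylip()` reads it back.
#'
#' @param dist A `pairwise_dist` (or plain square matrix for the writers).
#' @param path File path.
#' @return The path (writers) or a numeric matrix (reader), invisibly for
#'   writers.
#' @export
write_dist_tsv <- function(dist, path) {
  d <- if (inherits(dist, "pairwise_dist")) dist$d else dist
  df <- as.data.frame(d)
  df <- cbind(sample_id = rownames(d), df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
write_dist_phylip <- function(dist, path) {
  d <- if (inherits(dist, "pairwise_dist")) dist$d else dist
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(c(sprintf("%-10s", rownames(d)[i]),
                       sprintf("%.8f", d[i, ])), collapse = "  ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "[ \t]+")
  ids <- vapply(parts, `[`, character(1), 1)
  d <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  dimnames(d) <- list(ids, ids)
  d
}
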