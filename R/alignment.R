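# Aligned marker containers, FASTA/metadata I/O, concatenation, marker sets.

DNA_ALPHABET <- c("A", "C", "G", "T",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V",
                  "N", "-")

new_marker_alignment <- function(marker, seq, species, offsets) {
  structure(
    list(marker = marker, seq = seq, species = species, offsets = offsets),
    class = "marker_alignment"
  )
}

#' Construct an aligned marker data set
#'
#' Bundles one marker's aligned sequences with its sample-to-species
#' metadata. Sequences are normalised to upper case and validated against
#' the IUPAC DNA alphabet plus `-` for alignment gaps; all rows must have
#' identical (aligned) length and every sample id must carry a species
#' label.
#'
#' @param seqs Named character vector of aligned sequences (names are
#'   sample ids), or a character matrix of single characters with rownames.
#' @param species A data frame with columns `sample_id` and `species`
#'   covering every sequence id.
#' @param marker Marker name (e.g. `"ITS"`).
#' @return A `marker_alignment` object.
#' @export
#' @examples
#' meta <- tibble::tibble(sample_id = c("s1", "s2"), species = c("A", "A"))
#' marker_alignment(c(s1 = "ACGT", s2 = "AC-T"), meta, "ITS")
marker_alignment <- function(seqs, species, marker = "marker") {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
      abort("sequences must be named by sample id", class = "barcodegap_metadata_error")
    }
    nc <- unique(nchar(seqs))
    if (length(nc) != 1) {
      abort(
        paste0("sequences are not aligned: lengths ", paste(sort(nc), collapse = ", ")),
        class = "barcodegap_alignment_error"
      )
    }
    mat <- do.call(rbind, strsplit(unname(as.character(seqs)), ""))
    rownames(mat) <- names(seqs)
  }
  mat[] <- toupper(mat)
  ids <- rownames(mat)
  if (is.null(ids) || anyDuplicated(ids)) {
    abort("sample ids must be present and unique", class = "barcodegap_metadata_error")
  }
  bad <- setdiff(unique(as.vector(mat)), DNA_ALPHABET)
  if (length(bad) > 0) {
    abort(
      paste0("illegal character(s) in alignment: ", paste(bad, collapse = " ")),
      class = "barcodegap_alphabet_error"
    )
  }
  species <- as_tibble(species)
  if (!all(c("sample_id", "species") %in% names(species))) {
    abort("metadata must have columns sample_id and species",
          class = "barcodegap_metadata_error")
  }
  missing_ids <- setdiff(ids, species$sample_id)
  if (length(missing_ids) > 0) {
    abort(
      paste0("sample id(s) absent from metadata: ",
             paste(head(missing_ids, 5), collapse = ", ")),
      class = "barcodegap_metadata_error"
    )
  }
  sp <- setNames(species$species, species$sample_id)[ids]
  offsets <- tibble(marker = marker, start = 1L, end = ncol(mat))
  new_marker_alignment(marker, mat, sp, offsets)
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat("<marker_alignment> ", x$marker, ": ", nrow(x$seq), " samples x ",
      ncol(x$seq), " aligned sites, ", length(unique(x$species)),
      " species\n", sep = "")
  invisible(x)
}

#' @export
dim.marker_alignment <- function(x) dim(x$seq)

#' Number of aligned columns
#' @param x A `marker_alignment`.
#' @return Integer alignment length.
#' @export
alignment_length <- function(x) ncol(x$seq)

#' Sample ids of an alignment
#' @param x A `marker_alignment`.
#' @return Character vector of sample ids, in alignment order.
#' @export
sample_ids <- function(x) rownames(x$seq)

#' Read a species metadata table
#'
#' Two-column tab-separated file with a header line `sample_id<TAB>species`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample_id` and `species`.
#' @export
read_species_map <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (!all(c("sample_id", "species") %in% names(meta))) {
    abort("metadata TSV must have header columns sample_id and species",
          class = "barcodegap_metadata_error")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicated sample_id in metadata", class = "barcodegap_metadata_error")
  }
  meta[, c("sample_id", "species")]
}

#' Species tally of a metadata table
#' @param species Data frame with `sample_id` and `species` columns.
#' @return Tibble with one row per species and its individual count.
#' @export
species_counts <- function(species) {
  dplyr::count(as_tibble(species), .data$species, name = "n_individuals")
}

#' Read one marker's aligned FASTA
#'
#' Records must all have the same aligned length; ids are matched to the
#' metadata by exact string equality. Lower-case bases are normalised to
#' upper case.
#'
#' @param path FASTA file of aligned sequences (`-` for gaps).
#' @param marker_name Marker name to attach.
#' @param metadata Data frame with `sample_id` and `species` columns.
#' @return A [marker_alignment()].
#' @export
read_alignment_fasta <- function(path, marker_name, metadata) {
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0) {
    abort("empty FASTA file", class = "barcodegap_alignment_error")
  }
  lens <- lengths(recs)
  if (length(unique(lens)) != 1) {
    abort(
      paste0("FASTA records have unequal lengths (", min(lens), "-", max(lens),
             "); input must be aligned"),
      class = "barcodegap_alignment_error"
    )
  }
  mat <- toupper(do.call(rbind, as.character(recs)))
  rownames(mat) <- names(recs)
  marker_alignment(mat, metadata, marker = marker_name)
}

#' Write an alignment back to FASTA
#' @param x A `marker_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(x, path) {
  seqs <- apply(x$seq, 1, paste, collapse = "")
  lines <- character(2 * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  lines[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(lines, path)
  invisible(path)
}

#' Marker block offsets of a (concatenated) alignment
#' @param x A `marker_alignment`.
#' @return Tibble `marker`, `start`, `end` (1-based inclusive columns).
#' @export
marker_offsets <- function(x) x$offsets

#' Write the marker partition table
#' @param x A `marker_alignment`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_partition_table <- function(x, path) {
  readr::write_tsv(x$offsets, path, progress = FALSE)
  invisible(path)
}

#' Concatenate marker alignments
#'
#' Joins per-marker alignments column-wise into one supermatrix, recording
#' each marker's column block. Under `intersect` (the default) only samples
#' present in every selected marker are kept; under `pad_with_gaps` the
#' union of samples is kept and a sample's missing markers are filled with
#' gap columns.
#'
#' @param alignments List of `marker_alignment` objects (named or carrying
#'   their own marker names).
#' @param markers Character vector selecting and ordering markers; default
#'   all, in catalog (input) order.
#' @param missing_policy `"intersect"` or `"pad_with_gaps"`.
#' @return A `marker_alignment` whose length is the sum of member lengths.
#' @export
concatenate_markers <- function(alignments, markers = NULL,
                                missing_policy = c("intersect", "pad_with_gaps")) {
  missing_policy <- match.arg(missing_policy)
  if (length(alignments) == 0) abort("need at least one alignment")
  nm <- vapply(alignments, function(a) a$marker, character(1))
  names(alignments) <- nm
  markers <- markers %||% nm
  missing_m <- setdiff(markers, nm)
  if (length(missing_m) > 0) {
    abort(paste0("unknown marker(s): ", paste(missing_m, collapse = ", ")))
  }
  alignments <- alignments[markers]

  # species labels must agree across markers for shared ids
  sp_all <- list()
  for (a in alignments) {
    for (id in names(a$species)) {
      prev <- sp_all[[id]]
      if (!is.null(prev) && prev != a$species[[id]]) {
        abort(paste0("conflicting species label for sample ", id),
              class = "barcodegap_metadata_error")
      }
      sp_all[[id]] <- a$species[[id]]
    }
  }

  id_sets <- lapply(alignments, function(a) rownames(a$seq))
  if (missing_policy == "intersect") {
    keep <- Reduce(intersect, id_sets)
    if (length(keep) == 0) {
      abort("no sample is present in all selected markers",
            class = "barcodegap_empty_result_error")
    }
  } else {
    keep <- Reduce(union, id_sets)
  }

  blocks <- lapply(alignments, function(a) {
    L <- ncol(a$seq)
    block <- matrix("-", nrow = length(keep), ncol = L,
                    dimnames = list(keep, NULL))
    present <- intersect(keep, rownames(a$seq))
    block[present, ] <- a$seq[present, , drop = FALSE]
    block
  })
  mat <- do.call(cbind, blocks)
  lens <- vapply(alignments, function(a) ncol(a$seq), integer(1))
  ends <- cumsum(lens)
  offsets <- tibble(marker = markers,
                    start = as.integer(ends - lens + 1L),
                    end = as.integer(ends))
  meta <- tibble(sample_id = keep,
                 species = unlist(sp_all[keep], use.names = FALSE))
  out <- marker_alignment(mat, meta, marker = paste(markers, collapse = "+"))
  out$offsets <- offsets
  out
}

#' Enumerate all single and combined marker sets
#'
#' All non-empty subsets of the marker catalog, singletons first, then
#' pairs, triples, and so on; within a size, subsets follow catalog order.
#' Four markers give the 4 single + 11 combined sets (15 total).
#'
#' @param catalog Character vector of unique marker names.
#' @return Named list of character vectors; names join members with `+`.
#' @export
#' @examples
#' length(enumerate_marker_sets(c("ITS", "EF1a", "RPB1", "RPB2"))) # 15
enumerate_marker_sets <- function(catalog) {
  if (length(catalog) == 0 || anyDuplicated(catalog)) {
    abort("marker catalog must be non-empty and unique")
  }
  sets <- list()
  for (k in seq_along(catalog)) {
    sets <- c(sets, combn(catalog, k, simplify = FALSE))
  }
  names(sets) <- vapply(sets, paste, character(1), collapse = "+")
  sets
}
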