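#' Catalog of KRAB domain occurrences
#'
#' A catalog is a plain tibble, one row per domain occurrence, with columns
#' `id` (unique), `species` (non-empty), `subgroup` (one of
#' `r paste0('\x60', KRAB_SUBGROUPS, '\x60', collapse = ", ")`), and
#' `alignment` (the domain sequence gapped onto the [krab_frame()] columns).
#' A degapped `sequence` column is derived on validation. Optional
#' `evalue_<model>` columns carry externally computed E-values.
#'
#' @param x A data frame with at least `id`, `species`, `subgroup` and one of
#'   `alignment` or `sequence`.
#' @return A validated catalog tibble (with `sequence` filled in).
#' @export
as_catalog <- function(x) {
  x <- as_tibble(x)
  need <- c("id", "species", "subgroup")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("catalog lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "krabstrat_catalog_error")
  }
  if (!any(c("alignment", "sequence") %in% names(x))) {
    abort("catalog needs an 'alignment' or 'sequence' column",
          class = "krabstrat_catalog_error")
  }
  if (anyDuplicated(x$id)) {
    abort(sprintf("duplicate catalog id: '%s'", x$id[duplicated(x$id)][1]),
          class = "krabstrat_catalog_error")
  }
  if (any(!nzchar(x$species) | is.na(x$species))) {
    abort("species strings must be non-empty", class = "krabstrat_catalog_error")
  }
  bad <- setdiff(unique(x$subgroup), KRAB_SUBGROUPS)
  if (length(bad) > 0) {
    abort(sprintf("unknown subgroup label '%s'", bad[1]),
          class = "krabstrat_catalog_error")
  }
  if ("alignment" %in% names(x)) {
    x$alignment <- vapply(x$alignment, normalize_residues, "", USE.NAMES = FALSE)
    x$sequence <- gsub("-", "", x$alignment, fixed = TRUE)
  } else {
    x$sequence <- vapply(x$sequence, normalize_residues, "",
                         allow_gap = FALSE, USE.NAMES = FALSE)
  }
  x
}

#' Subgroup labels used for stratification
#' @export
KRAB_SUBGROUPS <- c("PRDM9_ortho", "SSX_ortho", "lcha_ZNF", "hs_mKRAB", "unknown")

#' Read / write a catalog TSV
#'
#' Tab-separated, UTF-8, with header; `.` and `-` are both accepted as gap
#' characters on read, `-` is written.
#'
#' @param path File path.
#' @return `read_catalog()` returns a validated catalog tibble.
#' @export
read_catalog <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  ev <- grep("^evalue_", names(x), value = TRUE)
  for (col in ev) x[[col]] <- as.numeric(x[[col]])
  as_catalog(x)
}

#' @param catalog A catalog tibble.
#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(as_catalog(catalog), path, progress = FALSE)
  invisible(path)
}

#' Convert a catalog row to a krab_sequence
#'
#' @param catalog A catalog tibble.
#' @param id Row id.
#' @return A [krab_sequence()]; coordinates are derived from the `alignment`
#'   column when present.
#' @export
catalog_sequence <- function(catalog, id) {
  row <- catalog[catalog$id == id, ]
  if (nrow(row) != 1) {
    abort(sprintf("id '%s' not found in catalog", id),
          class = "krabstrat_catalog_error")
  }
  if ("alignment" %in% names(row) && !is.na(row$alignment)) {
    map_alignment_to_coordinates(row$alignment, krab_frame()$coord,
                                 source_id = row$id, species = row$species)
  } else {
    krab_sequence(row$sequence, source_id = row$id, species = row$species)
  }
}

#' Read sequences and alignments in standard formats
#'
#' Thin wrappers over Biostrings readers, returning named character vectors
#' so downstream functions stay format-agnostic. `read_alignment()` handles
#' ClustalW `.aln` and Stockholm files, `read_fasta()` plain FASTA.
#'
#' @param path File path.
#' @param format For `read_alignment()`: `"clustal"` or `"stockholm"`
#'   (guessed from the extension by default).
#' @return Named character vector of (aligned) sequences.
#' @export
read_alignment <- function(path, format = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required to read alignment files")
  }
  if (is.null(format)) {
    format <- if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE)) {
      "stockholm"
    } else {
      "clustal"
    }
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  out <- as.character(aln)
  vapply(out, normalize_residues, "", USE.NAMES = TRUE)
}

#' @rdname read_alignment
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required to read FASTA files")
  }
  x <- Biostrings::readAAStringSet(path)
  setNames(vapply(as.character(x), normalize_residues, "", USE.NAMES = FALSE),
           names(x))
}

#' @param sequences Named character vector.
#' @rdname read_alignment
#' @export
write_fasta <- function(sequences, path) {
  nm <- names(sequences)
  if (is.null(nm)) nm <- paste0("seq", seq_along(sequences))
  writeLines(as.vector(rbind(paste0(">", nm), unname(sequences))), path)
  invisible(path)
}
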