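#' The KRAB coordinate frame
#'
#' KRAB residues are addressed per subdomain, 1-based: positions `A1`--`A42`
#' for KRAB-A and `B1`--`B35` for KRAB-B, with all A positions preceding all
#' B positions. Ancestral (aKRAB) sequences leave `A32` unoccupied: the
#' alignment gap there is treated like a coordinate so that numbering stays
#' comparable with modern (mKRAB) domains.
#'
#' @return A tibble with one row per frame position: `coord` (e.g. `"A32"`),
#'   `subdomain`, `position`, and `rank` (total order over the frame).
#' @export
#' @examples
#' krab_frame()
krab_frame <- function() {
  tibble(
    subdomain = c(rep("A", 42L), rep("B", 35L)),
    position  = c(seq_len(42L), seq_len(35L))
  ) %>%
    mutate(coord = paste0(.data$subdomain, .data$position),
           rank  = dplyr::row_number()) %>%
    select("coord", "subdomain", "position", "rank")
}

#' Parse KRAB coordinate labels
#'
#' @param x Character vector of labels such as `"A32"` or `"B14"`.
#' @return A tibble with columns `coord`, `subdomain`, `position`, `rank`.
#' @export
parse_krab_coord <- function(x) {
  m <- regmatches(x, regexec("^([AB])([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    abort(sprintf("malformed KRAB coordinate: '%s'", x[bad][1]),
          class = "krabstrat_coord_error")
  }
  subdomain <- vapply(m, `[`, "", 2L)
  position <- as.integer(vapply(m, `[`, "", 3L))
  limit <- ifelse(subdomain == "A", 42L, 35L)
  if (any(position < 1L | position > limit)) {
    i <- which(position < 1L | position > limit)[1]
    abort(sprintf("KRAB coordinate out of range: '%s' (A spans 1..42, B 1..35)",
                  x[i]),
          class = "krabstrat_coord_error")
  }
  tibble(coord = x, subdomain = subdomain, position = position,
         rank = ifelse(subdomain == "A", position, 42L + position))
}

#' Construct a KRAB-annotated sequence
#'
#' A `krab_sequence` couples an ungapped residue string with an injective,
#' order-preserving map from KRAB coordinates to residue indices. Unmapped
#' coordinates (typically `A32` in aKRAB) simply have no row in `coords`.
#'
#' @param residues Ungapped amino-acid string.
#' @param coords Tibble with columns `coord` and `res_index` (1-based index
#'   into `residues`), or `NULL` for an unannotated sequence.
#' @param source_id,species Optional provenance labels.
#' @return A `krab_sequence` object.
#' @export
krab_sequence <- function(residues, coords = NULL, source_id = "", species = "") {
  residues <- normalize_residues(residues, allow_gap = FALSE)
  if (is.null(coords)) {
    coords <- tibble(coord = character(), res_index = integer())
  }
  coords <- as_tibble(coords)[, c("coord", "res_index")]
  coords$res_index <- as.integer(coords$res_index)
  parsed <- parse_krab_coord(coords$coord)
  coords <- coords %>%
    mutate(rank = parsed$rank) %>%
    arrange(.data$rank)
  if (anyDuplicated(coords$coord) || anyDuplicated(coords$res_index)) {
    abort("coordinate map must be injective", class = "krabstrat_coord_error")
  }
  if (nrow(coords) > 0 &&
      (any(coords$res_index < 1L) || any(coords$res_index > nchar(residues)))) {
    abort("coordinate map points outside the residue string",
          class = "krabstrat_coord_error")
  }
  if (is.unsorted(coords$res_index, strictly = TRUE)) {
    abort("mapped residue indices must increase with coordinate order",
          class = "krabstrat_coord_error")
  }
  structure(
    list(residues = residues, coords = select(coords, "coord", "res_index"),
         source_id = source_id, species = species),
    class = "krab_sequence"
  )
}

#' @export
print.krab_sequence <- function(x, ...) {
  cat(sprintf("<krab_sequence> %s%s, %d aa, %d mapped coordinates\n",
              x$source_id,
              if (nzchar(x$species)) paste0(" [", x$species, "]") else "",
              nchar(x$residues), nrow(x$coords)))
  cat(" ", x$residues, "\n")
  invisible(x)
}

#' @export
as.character.krab_sequence <- function(x, ...) x$residues

#' Residues at KRAB coordinates
#'
#' @param seq A [krab_sequence()].
#' @param coords Character vector of coordinate labels.
#' @return Character vector of single residues; `NA` where unmapped.
#' @export
residue_at <- function(seq, coords) {
  stopifnot(inherits(seq, "krab_sequence"))
  idx <- seq$coords$res_index[match(coords, seq$coords$coord)]
  out <- rep(NA_character_, length(coords))
  ok <- !is.na(idx)
  if (any(ok)) out[ok] <- substring(seq$residues, idx[ok], idx[ok])
  out
}

#' Map an alignment row onto KRAB coordinates
#'
#' Non-gap characters receive the coordinate of their alignment column; gap
#' columns stay unmapped. This is how aKRAB sequences acquire the `A32` hole:
#' the gap in the alignment is kept as an unoccupied coordinate rather than a
#' gap character in the stored string.
#'
#' @param aligned_seq Gapped string (gap characters `-` or `.`).
#' @param reference_columns Character vector of KRAB coordinates, one per
#'   alignment column.
#' @inheritParams krab_sequence
#' @return A [krab_sequence()].
#' @export
#' @examples
#' s <- map_alignment_to_coordinates("VT-KD", c("A1", "A2", "A3", "A4", "A5"))
#' residue_at(s, c("A2", "A3", "A4"))
map_alignment_to_coordinates <- function(aligned_seq, reference_columns,
                                         source_id = "", species = "") {
  aligned_seq <- normalize_residues(aligned_seq, allow_gap = TRUE)
  chars <- strsplit(aligned_seq, "")[[1]]
  if (length(chars) != length(reference_columns)) {
    abort(sprintf("aligned sequence has %d columns but %d reference columns given",
                  length(chars), length(reference_columns)),
          class = "krabstrat_structure_error")
  }
  keep <- chars != "-"
  krab_sequence(
    residues = paste(chars[keep], collapse = ""),
    coords = tibble(coord = reference_columns[keep],
                    res_index = seq_len(sum(keep))),
    source_id = source_id, species = species
  )
}

#' Re-emit a krab_sequence as a gapped alignment row
#'
#' Inverse of [map_alignment_to_coordinates()] over a column frame: mapped
#' coordinates print their residue, unmapped frame columns print `-`.
#' Residues not mapped to any frame column are dropped.
#'
#' @param seq A [krab_sequence()].
#' @param reference_columns Coordinate labels of the output columns
#'   (default: the full [krab_frame()]).
#' @return Gapped string of `length(reference_columns)` characters.
#' @export
emit_alignment_row <- function(seq, reference_columns = krab_frame()$coord) {
  res <- residue_at(seq, reference_columns)
  res[is.na(res)] <- "-"
  paste(res, collapse = "")
}

#' Signed length difference between two sequences
#'
#' Returns `nchar(b) - nchar(a)`. The one-residue gain of the aKRAB-A to
#' mKRAB-A transition (gap+KR replaced by MLE at A32--A34) shows up here
#' as `+1`.
#'
#' @param a,b [krab_sequence()] objects (or plain strings).
#' @return Integer.
#' @export
length_delta <- function(a, b) {
  len <- function(x) if (inherits(x, "krab_sequence")) nchar(x$residues) else nchar(x)
  if (len(a) == 0L || len(b) == 0L) {
    abort("length_delta needs non-empty sequences", class = "krabstrat_structure_error")
  }
  as.integer(len(b) - len(a))
}
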