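#' Per-column residue and gap counts of an alignment
#'
#' X-class (ambiguity) characters are excluded from residue counts but do
#' count as occupied for the occupancy fraction.
#'
#' @param alignment Character vector of equal-length gapped rows.
#' @return Tibble `column`, `residue`, `count` (long, zero counts omitted)
#'   plus per-column `gap_count`, `n_rows`, `occupancy` repeated on each row;
#'   columns with no observed residue keep a single row with `residue = NA`.
#' @export
column_frequencies <- function(alignment) {
  alignment <- vapply(as.character(alignment), normalize_residues, "",
                      USE.NAMES = FALSE)
  if (length(alignment) == 0) {
    abort("empty alignment", class = "krabstrat_logo_error")
  }
  if (length(unique(nchar(alignment))) != 1) {
    abort("alignment rows must have uniform length", class = "krabstrat_logo_error")
  }
  mat <- do.call(rbind, strsplit(alignment, ""))
  purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    chars <- mat[, j]
    gap <- sum(chars == "-")
    counts <- table(factor(chars[chars %in% AA20], levels = AA20))
    counts <- counts[counts > 0]
    base <- tibble(column = j,
                   residue = if (length(counts)) names(counts) else NA_character_,
                   count = if (length(counts)) as.integer(counts) else 0L)
    base$gap_count <- gap
    base$n_rows <- nrow(mat)
    base$occupancy <- 1 - gap / nrow(mat)
    base
  })
}

#' Information content of one alignment column
#'
#' Relative entropy (in bits) of the observed residue frequencies against
#' the background: `sum(p * log2(p / q))` over observed residues, with no
#' pseudocounts. With a uniform background this is at most `log2(20)`;
#' a single-residue column attains it exactly.
#'
#' @param counts Named count vector (names are residues), or the tibble rows
#'   of one column from [column_frequencies()].
#' @param background Named probability vector over the 20 residues, or
#'   `"uniform"`.
#' @return Information content in bits.
#' @export
#' @examples
#' information_content(c(A = 4))             # log2(20)
#' information_content(c(A = 3, C = 1))
information_content <- function(counts, background = "uniform") {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$count, counts$residue)
  }
  counts <- counts[!is.na(names(counts)) & counts > 0]
  if (length(counts) == 0) {
    abort("at least one residue must be observed", class = "krabstrat_logo_error")
  }
  q <- resolve_background(background)
  p <- counts / sum(counts)
  sum(p * log2(p / q[names(p)]))
}

resolve_background <- function(background) {
  if (identical(background, "uniform")) {
    return(setNames(rep(1 / 20, 20), AA20))
  }
  if (is.numeric(background) && length(background) == 20 &&
      !is.null(names(background))) {
    return(background / sum(background))
  }
  abort("background must be 'uniform' or a named probability vector over 20 residues",
        class = "krabstrat_logo_error")
}

#' Sequence-logo matrix (information content above background)
#'
#' Computes, per column, the information content and the letter heights
#' (`height = ic * p`), the representation behind "information content above
#' background" sequence logos. Column heights always decompose exactly into
#' the letter heights.
#'
#' @param alignment Character vector of equal-length gapped rows.
#' @param background See [information_content()].
#' @param columns Optional coordinate labels for the columns (e.g. KRAB
#'   coordinates); defaults to column indices.
#' @return A `krab_logo` object: tibble `column`, `coord`, `residue`,
#'   `height`, `ic`, `occupancy`.
#' @export
logo_matrix <- function(alignment, background = "uniform", columns = NULL) {
  freqs <- column_frequencies(alignment)
  if (is.null(columns)) {
    columns <- as.character(seq_len(max(freqs$column)))
  }
  if (length(columns) != max(freqs$column)) {
    abort("length(columns) must equal the number of alignment columns",
          class = "krabstrat_logo_error")
  }
  out <- freqs %>%
    filter(!is.na(.data$residue)) %>%
    group_by(.data$column) %>%
    mutate(ic = information_content(setNames(.data$count, .data$residue),
                                    background),
           height = .data$ic * .data$count / sum(.data$count)) %>%
    ungroup() %>%
    mutate(coord = columns[.data$column]) %>%
    select("column", "coord", "residue", "height", "ic", "occupancy")
  class(out) <- c("krab_logo", class(out))
  attr(out, "n_rows") <- freqs$n_rows[1]
  out
}

#' Drop mostly-empty alignment columns
#'
#' Removes columns whose gap fraction exceeds `max_gap_fraction` (the
#' "remove mostly-empty columns" logo option) and keeps the index map for
#' coordinate bookkeeping.
#'
#' @param alignment Character vector of equal-length gapped rows.
#' @param max_gap_fraction Columns with a strictly larger gap fraction are
#'   dropped. Default 0.5.
#' @return List with `alignment` (the reduced rows) and `kept_columns`
#'   (original indices of the retained columns).
#' @export
drop_sparse_columns <- function(alignment, max_gap_fraction = 0.5) {
  alignment <- vapply(as.character(alignment), normalize_residues, "",
                      USE.NAMES = FALSE)
  mat <- do.call(rbind, strsplit(alignment, ""))
  gap_frac <- colMeans(mat == "-")
  keep <- which(gap_frac <= max_gap_fraction)
  if (length(keep) == 0) {
    abort("all columns were removed", class = "krabstrat_logo_error")
  }
  list(alignment = apply(mat[, keep, drop = FALSE], 1, paste, collapse = ""),
       kept_columns = keep)
}

#' Positional residue frequencies across subgroups
#'
#' Counts, for each query (coordinate, residue), how many sequences of each
#' subgroup carry that residue at that column, with the denominator being
#' the number of sequences occupying the column at all. KRAB-B positions are
#' counted in whatever follows KRAB-A, irrespective of whether a conserved
#' B subdomain exists in the subgroup.
#'
#' @param alignments Named list (one element per subgroup) of character
#'   vectors, all aligned to the same coordinate frame.
#' @param queries Tibble with columns `coord` and `residue`.
#' @param columns Coordinate labels of the alignment columns; defaults to
#'   the full [krab_frame()].
#' @return A tibble `coord`, `residue`, `subgroup`, `count`, `denominator`.
#' @export
position_counts <- function(alignments, queries,
                            columns = krab_frame()$coord) {
  stopifnot(is.list(alignments), !is.null(names(alignments)))
  queries <- as_tibble(queries)
  bad <- setdiff(queries$coord, columns)
  if (length(bad) > 0) {
    abort(sprintf("query coordinate '%s' is outside the alignment frame", bad[1]),
          class = "krabstrat_logo_error")
  }
  purrr::map_dfr(names(alignments), function(grp) {
    rows <- vapply(as.character(alignments[[grp]]), normalize_residues, "",
                   USE.NAMES = FALSE)
    if (length(rows) > 0 && any(nchar(rows) != length(columns))) {
      abort(sprintf("subgroup '%s' rows do not match the coordinate frame", grp),
            class = "krabstrat_logo_error")
    }
    mat <- if (length(rows) > 0) do.call(rbind, strsplit(rows, "")) else
      matrix("", 0, length(columns))
    purrr::map_dfr(seq_len(nrow(queries)), function(k) {
      j <- match(queries$coord[k], columns)
      chars <- if (nrow(mat) > 0) mat[, j] else character()
      tibble(coord = queries$coord[k], residue = queries$residue[k],
             subgroup = grp,
             count = sum(chars == queries$residue[k]),
             denominator = sum(chars != "-" ))
    })
  })
}
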