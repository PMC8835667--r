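#' Parse an edit in KRAB-coordinate notation
#'
#' The grammar is `<coord>:<from]><to>` for substitutions (`"A27:R>V"`) and
#' `<coord>-<coord>:<from>><to>` for block replacements
#' (`"A32-A34:KR>MLE"`). For block replacements the lengths of `from` and
#' `to` may differ; when a range spans unmapped coordinates (the aKRAB `A32`
#' gap) the missing positions are simply absorbed: `from` is matched against
#' the residues actually mapped inside the range, and `to` is laid out over
#' consecutive coordinates starting at the range start.
#'
#' @param spec Edit specification string.
#' @return An `edit` tibble row: `kind`, `start`, `end`, `from`, `to`.
#' @export
#' @examples
#' parse_edit("A27:R>V")
#' parse_edit("A32-A34:KR>MLE")
parse_edit <- function(spec) {
  m <- regexec("^([AB][0-9]+)(?:-([AB][0-9]+))?:([A-Z]*)>([A-Z]*)$", spec,
               perl = TRUE)
  g <- regmatches(spec, m)[[1]]
  if (length(g) != 5) {
    abort(sprintf("malformed edit spec: '%s'", spec),
          class = "krabstrat_edit_error")
  }
  start <- g[2]
  end <- if (nzchar(g[3])) g[3] else g[2]
  from <- normalize_residues(g[4], allow_gap = FALSE)
  to <- normalize_residues(g[5], allow_gap = FALSE)
  is_block <- nzchar(g[3])
  if (!is_block && (nchar(from) != 1 || nchar(to) != 1)) {
    abort(sprintf("substitution '%s' must replace exactly one residue", spec),
          class = "krabstrat_edit_error")
  }
  rs <- parse_krab_coord(start)$rank
  re <- parse_krab_coord(end)$rank
  if (re < rs) {
    abort(sprintf("edit range runs backwards: '%s'", spec),
          class = "krabstrat_edit_error")
  }
  tibble(kind = if (is_block) "block_replacement" else "substitution",
         start = start, end = end, from = from, to = to,
         start_rank = rs, end_rank = re)
}

#' Assemble an ordered, non-overlapping edit script
#'
#' @param name Script name (e.g. `"P9Am10"`).
#' @param specs Character vector of edit specifications (see [parse_edit()]),
#'   may be empty for an identity script.
#' @param provenance `"fully_specified"` for scripts whose residue content
#'   is given in running text, `"figure_dependent"` for stubs that refuse
#'   application.
#' @return An `edit_script` object.
#' @export
edit_script <- function(name, specs = character(),
                        provenance = c("fully_specified", "figure_dependent")) {
  provenance <- match.arg(provenance)
  edits <- if (length(specs) > 0) {
    purrr::map_dfr(specs, parse_edit) %>% arrange(.data$start_rank)
  } else {
    parse_edit("A1:A>A")[0, ]
  }
  if (nrow(edits) > 1) {
    overlap <- edits$start_rank[-1] <= edits$end_rank[-nrow(edits)]
    if (any(overlap)) {
      abort(sprintf("overlapping edits in script '%s' at %s", name,
                    edits$start[-1][overlap][1]),
            class = "krabstrat_edit_error")
    }
  }
  structure(list(name = name, edits = edits, provenance = provenance),
            class = "edit_script")
}

#' @export
print.edit_script <- function(x, ...) {
  cat(sprintf("<edit_script> %s (%s): %d edit(s)\n", x$name, x$provenance,
              nrow(x$edits)))
  if (nrow(x$edits) > 0) {
    cat(paste0("  ", format_edit(x$edits), collapse = "\n"), "\n")
  }
  invisible(x)
}

format_edit <- function(edits) {
  ifelse(edits$kind == "substitution",
         sprintf("%s:%s>%s", edits$start, edits$from, edits$to),
         sprintf("%s-%s:%s>%s", edits$start, edits$end, edits$from, edits$to))
}

#' @method tidy edit_script
#' @export
tidy.edit_script <- function(x, ...) {
  mutate(x$edits, script = x$name, provenance = x$provenance,
         length_delta = nchar(.data$to) - nchar(.data$from)) %>%
    select("script", "provenance", "kind", "start", "end", "from", "to",
           "length_delta")
}

#' Invert an edit script
#'
#' Swaps `from` and `to` of every edit, so that applying a script and then
#' its inverse is the identity.
#'
#' @param script An `edit_script`.
#' @return The inverted `edit_script`.
#' @export
invert_script <- function(script) {
  inv <- script$edits
  tmp <- inv$from; inv$from <- inv$to; inv$to <- tmp
  out <- script
  out$edits <- inv
  out$name <- paste0(script$name, "_inv")
  out
}

#' Apply an edit script to a KRAB sequence
#'
#' Every edit's `from` residues must match the target at its coordinates
#' (unmapped coordinates inside a range are skipped); a mismatch refuses the
#' whole application with a position report, guarding against stale
#' coordinates. After block replacements the coordinate map is re-derived:
#' replacement residues claim consecutive coordinates from the range start,
#' so a KR -> MLE block at A32-A34 maps A32, A33 and A34 even when A32 was
#' the aKRAB gap.
#'
#' @param seq A [krab_sequence()].
#' @param script An `edit_script` (must be `fully_specified`).
#' @return The edited [krab_sequence()].
#' @export
apply_script <- function(seq, script) {
  stopifnot(inherits(seq, "krab_sequence"), inherits(script, "edit_script"))
  if (script$provenance == "figure_dependent") {
    abort(sprintf("script '%s' is figure-dependent and underdetermined; it cannot be applied",
                  script$name),
          class = "krabstrat_edit_error")
  }
  frame <- krab_frame()
  coords <- seq$coords %>%
    mutate(rank = frame$rank[match(.data$coord, frame$coord)])
  residues <- strsplit(seq$residues, "")[[1]]
  # work on (rank, residue) pairs so insertions re-number cleanly; interior
  # residues without a coordinate (earlier insertions) ride along on
  # fractional ranks just after their mapped predecessor
  rank_by_index <- rep(NA_real_, length(residues))
  rank_by_index[coords$res_index] <- coords$rank
  first_m <- if (nrow(coords) > 0) min(coords$res_index) else Inf
  last_m <- if (nrow(coords) > 0) max(coords$res_index) else -Inf
  if (is.finite(first_m)) {
    for (i in seq(first_m, last_m)) {
      if (is.na(rank_by_index[i])) {
        rank_by_index[i] <- rank_by_index[i - 1] + 1e-3
      }
    }
  }
  body_idx <- if (is.finite(first_m)) seq(first_m, last_m) else integer()
  work <- tibble(rank = rank_by_index[body_idx], residue = residues[body_idx])
  extra_head <- if (is.finite(first_m)) head(residues, first_m - 1) else residues
  extra_tail <- if (is.finite(last_m) && last_m < length(residues)) {
    residues[(last_m + 1):length(residues)]
  } else character()

  edits <- script$edits
  for (k in seq_len(nrow(edits))) {
    e <- edits[k, ]
    # the range covers fractional ranks too, so previously inserted
    # (coordinate-less) residues hanging off the range end stay editable
    sel <- which(work$rank >= e$start_rank & work$rank < e$end_rank + 1)
    found <- paste(work$residue[sel], collapse = "")
    if (!identical(found, e$from)) {
      abort(sprintf("script '%s': edit %s expects '%s' at %s but found '%s'",
                    script$name, format_edit(e), e$from,
                    if (e$start == e$end) e$start else paste0(e$start, "-", e$end),
                    found),
            class = "krabstrat_edit_error")
    }
    to_chars <- strsplit(e$to, "")[[1]]
    n_slots <- e$end_rank - e$start_rank + 1
    # replacement residues claim consecutive frame coordinates from the
    # range start; residues beyond the range width (pure insertions, e.g.
    # the helix-breaking PP) stay in the string but get no coordinate
    repl <- tibble(
      rank = ifelse(seq_along(to_chars) <= n_slots,
                    e$start_rank + seq_along(to_chars) - 1,
                    e$end_rank + (seq_along(to_chars) - n_slots) * 1e-3),
      residue = to_chars
    )
    keep <- if (length(sel) > 0) work[-sel, , drop = FALSE] else work
    work <- bind_rows(keep, repl) %>% arrange(.data$rank)
  }

  new_res <- c(extra_head, work$residue, extra_tail)
  mapped <- work$rank == round(work$rank)
  krab_sequence(
    residues = paste(new_res, collapse = ""),
    coords = tibble(coord = frame$coord[match(work$rank[mapped], frame$rank)],
                    res_index = (length(extra_head) + seq_len(nrow(work)))[mapped]),
    source_id = if (nzchar(seq$source_id)) {
      paste0(seq$source_id, ":", script$name)
    } else script$name,
    species = seq$species
  )
}

#' Diff inventory between wild type and mutant under a script
#'
#' Verifies that `mutant` is exactly `apply_script(wild_type, script)` and
#' tallies the script: substitution count, block replacement count, signed
#' length delta, and the positions touched.
#'
#' @param wild_type,mutant [krab_sequence()] objects.
#' @param script The `edit_script` relating them.
#' @return A tibble row: `n_substitutions`, `n_block_replacements`,
#'   `length_delta`, `positions` (list column).
#' @export
diff_inventory <- function(wild_type, mutant, script) {
  rebuilt <- apply_script(wild_type, script)
  if (!identical(rebuilt$residues, mutant$residues)) {
    abort("mutant does not equal apply_script(wild_type, script)",
          class = "krabstrat_edit_error")
  }
  ed <- script$edits
  tibble(
    script = script$name,
    n_substitutions = sum(ed$kind == "substitution"),
    n_block_replacements = sum(ed$kind == "block_replacement"),
    length_delta = as.integer(sum(nchar(ed$to) - nchar(ed$from))),
    positions = list(ed$start)
  )
}

#' Join an A-subdomain and a B-subdomain construct
#'
#' Concatenates the residue strings and unifies the coordinate maps (all A
#' coordinates from the first part, all B coordinates from the second), as
#' in hybrids of PRDM9 aKRAB-A mutants with the ZNF10 KRAB-B. An empty B
#' part yields an A-only (B-ablated) construct.
#'
#' @param a_domain [krab_sequence()] mapped only to A coordinates.
#' @param b_domain [krab_sequence()] mapped only to B coordinates (or with
#'   an empty residue string).
#' @return The hybrid [krab_sequence()], named `"<a>-<b>"`.
#' @export
assemble_hybrid <- function(a_domain, b_domain) {
  stopifnot(inherits(a_domain, "krab_sequence"), inherits(b_domain, "krab_sequence"))
  sub_a <- substr(a_domain$coords$coord, 1, 1)
  sub_b <- substr(b_domain$coords$coord, 1, 1)
  if (any(sub_a == "B") || any(sub_b == "A")) {
    abort("overlapping coordinate frames: parts must cover A and B exclusively",
          class = "krabstrat_edit_error")
  }
  n_a <- nchar(a_domain$residues)
  krab_sequence(
    residues = paste0(a_domain$residues, b_domain$residues),
    coords = bind_rows(
      a_domain$coords,
      mutate(b_domain$coords, res_index = .data$res_index + n_a)
    ),
    source_id = paste0(
      if (nzchar(a_domain$source_id)) a_domain$source_id else "A",
      if (nchar(b_domain$residues) > 0) {
        paste0("-", if (nzchar(b_domain$source_id)) b_domain$source_id else "B")
      } else ""
    ),
    species = a_domain$species
  )
}

#' The packaged library of mutant construct scripts
#'
#' Reads the shipped config of named edit scripts for the aKRAB-to-mKRAB
#' transformation roadmap. Scripts whose residue content is given in running
#' text (P9Am1, P9Am10-P9Am13, ZNF10Am1, ZNF10-PP) are `fully_specified`;
#' the intermediate P9Am2-P9Am9 constructs are defined only graphically in
#' the source figure and ship as `figure_dependent` stubs that refuse
#' application. Scripts are data, not code: the config can be extended
#' without touching the engine.
#'
#' @return Named list of `edit_script` objects.
#' @export
mutant_library <- function() {
  path <- system.file("extdata", "mutant_library.tsv", package = "krabstrat")
  cfg <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  out <- purrr::map(seq_len(nrow(cfg)), function(i) {
    specs <- if (is.na(cfg$edits[i]) || !nzchar(cfg$edits[i])) character() else
      strsplit(cfg$edits[i], ";", fixed = TRUE)[[1]]
    edit_script(cfg$name[i], trimws(specs), provenance = cfg$provenance[i])
  })
  setNames(out, cfg$name)
}
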