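# Subgroup consensus sequences over the A1-A42 / B1-B35 frame. These are
# synthetic emulations of the published subgroup logos, not accession
# sequences: they carry the planted diagnostic motifs (mKRAB A7-8/DV,
# A32-34/MLE, B13-14/LE, B19-20/PW; aKRAB A7-8/DI, A32 gap, A33-34/KR;
# PRDM9-specific S9/M20/R27 and B31/W; lcha B5-10/PKPDFM; SSX-specific
# divergence) on a shared scaffold.
SUBGROUP_CONSENSUS <- list(
  hs_mKRAB = list(
    A = "VTFKDVDVFFVDTREEWKLLDTAQQIVYRNVMLENYKNLVSL",
    B = "GYQLTKPDVISRLEQGEEPWLVEREIHQETHPDSE"
  ),
  PRDM9_ortho = list(
    A = "VTFKDVDISSIYTREEWKLMDTAEQIRYRNV-KRNYKNLVSL",
    B = "SFQLTRPSFMSRRRQGEESLLVEREIHQETWPDSE"
  ),
  SSX_ortho = list(
    A = "VTFQDVDISSIYSREEWRLMDSAEQLRYRNV-KRNYKNLVSL",
    B = "SFRLTRPSFLSKRRQGEESLLVEREIHQETGPDSE"
  ),
  lcha_ZNF = list(
    A = "VSFKDVDISSIYTREEWKLMDTWEQIRYRNV-KENYKNLVSL",
    B = "SYQLPKPDFMSRRRQGEESLLVEREIHQETGPDSE"
  )
)

#' Synthetic stand-in reference sequences
#'
#' The subgroup consensus at divergence 0 as a [krab_sequence()] over the
#' full KRAB frame. These stand in for the named wild-type blueprints
#' (ZNF10-AB, PRDM9, SSX1, lcha KZNF) in examples and tests; they are
#' synthetic, not accession sequences, but satisfy the positional residues
#' that the mutant edit scripts address (PRDM9 S9/M20/R27/gap-KR, ZNF10
#' F9/FVD10-12/MLE32-34, and so on).
#'
#' @param group Subgroup label (see [KRAB_SUBGROUPS]).
#' @param subdomain `"AB"` (default), `"A"` or `"B"`.
#' @return A [krab_sequence()].
#' @export
synthetic_reference <- function(group = c("PRDM9_ortho", "hs_mKRAB",
                                          "SSX_ortho", "lcha_ZNF"),
                                subdomain = c("AB", "A", "B")) {
  group <- match.arg(group)
  subdomain <- match.arg(subdomain)
  cons <- SUBGROUP_CONSENSUS[[group]]
  frame <- krab_frame()
  aligned <- switch(subdomain,
    AB = paste0(cons$A, cons$B),
    A = cons$A,
    B = cons$B)
  cols <- switch(subdomain,
    AB = frame$coord,
    A = frame$coord[frame$subdomain == "A"],
    B = frame$coord[frame$subdomain == "B"])
  map_alignment_to_coordinates(aligned, cols,
                               source_id = paste0("synthetic_", group, "_", subdomain),
                               species = "synthetic")
}

#' Per-position emission profiles of the built-in subgroup generators
#'
#' Each generator is a per-position distribution over the 20 residues plus
#' gap across the 77-column KRAB frame. Consensus residues carry
#' `1 - divergence` extra mass on top of a uniform `divergence` spread
#' (so consensus probability is `1 - divergence + divergence/20`); aKRAB
#' generators put all mass on the gap at `A32` and never emit there. The
#' lcha generator plants B14/E at rate 0.4, emulating the partial
#' modern-type E at that position in the coelacanth subgroup.
#'
#' @param divergence Per-position substitution probability toward uniform,
#'   in `[0, 1]`. Default 0.1.
#' @param indel_rate Per-position probability of emitting a gap at
#'   non-anchor positions. Default 0 (KRAB domains have a well-defined
#'   size).
#' @return Named list of `subgroup_generator` objects with fields `name`,
#'   `profile` (77 x 21 matrix, columns the residues plus `"-"`),
#'   `divergence`, `indel_rate`.
#' @export
builtin_generators <- function(divergence = 0.1, indel_rate = 0) {
  stopifnot(divergence >= 0, divergence <= 1, indel_rate >= 0, indel_rate < 1)
  frame <- krab_frame()
  purrr::imap(SUBGROUP_CONSENSUS, function(cons, grp) {
    consensus <- strsplit(paste0(cons$A, cons$B), "")[[1]]
    stopifnot(length(consensus) == nrow(frame))
    profile <- matrix(0, nrow = nrow(frame), ncol = 21,
                      dimnames = list(frame$coord, c(AA20, "-")))
    for (i in seq_along(consensus)) {
      if (consensus[i] == "-") {
        profile[i, "-"] <- 1  # the aKRAB A32 hole: never emits
      } else {
        row <- setNames(rep(divergence / 20, 20), AA20)
        row[consensus[i]] <- row[consensus[i]] + 1 - divergence
        profile[i, AA20] <- (1 - indel_rate) * row
        profile[i, "-"] <- indel_rate
      }
    }
    if (grp == "lcha_ZNF") {
      base <- profile["B14", ]
      mixed <- 0.6 * base
      mixed["E"] <- mixed["E"] + 0.4
      profile["B14", ] <- mixed
    }
    structure(list(name = grp, profile = profile,
                   divergence = divergence, indel_rate = indel_rate),
              class = "subgroup_generator")
  })
}

#' @export
print.subgroup_generator <- function(x, ...) {
  cat(sprintf("<subgroup_generator> %s (divergence %.3f, indel rate %.3f)\n",
              x$name, x$divergence, x$indel_rate))
  invisible(x)
}

#' Specification for a synthetic catalog
#'
#' @param n_per_group Sequences sampled per subgroup generator.
#' @param divergence Passed to [builtin_generators()].
#' @param seed Integer seed; the same spec yields a byte-identical catalog.
#' @param species_pool Species names sampled with replacement.
#' @param duplicate_rate Fraction of entries re-emitted verbatim under the
#'   same species (exercises within-species deduplication).
#' @param indel_rate Passed to [builtin_generators()].
#' @return A `synthetic_catalog_spec` list.
#' @export
synthetic_catalog_spec <- function(n_per_group = 50, divergence = 0.1,
                                   seed = 1072, species_pool = NULL,
                                   duplicate_rate = 0, indel_rate = 0) {
  if (is.null(species_pool)) {
    species_pool <- c(
      "Homo sapiens", "Mus musculus", "Latimeria chalumnae",
      "Mytilus galloprovincialis", "Protopterus annectens", "Bos taurus",
      "Danio rerio", "Xenopus tropicalis", "Monodelphis domestica",
      "Callorhinchus milii", "Strongylocentrotus purpuratus",
      "Drosophila melanogaster", "Crassostrea gigas", "Canis lupus",
      "Equus caballus", "Loxodonta africana", "Ornithorhynchus anatinus",
      "Anolis carolinensis", "Oryzias latipes", "Petromyzon marinus"
    )
  }
  structure(list(n_per_group = n_per_group, divergence = divergence,
                 seed = as.integer(seed), species_pool = species_pool,
                 duplicate_rate = duplicate_rate, indel_rate = indel_rate),
            class = "synthetic_catalog_spec")
}

#' Sample a synthetic KRAB catalog
#'
#' Draws `n_per_group` aligned sequences from each built-in subgroup
#' generator, assigns species from the pool, and (optionally) re-emits a
#' `duplicate_rate` fraction verbatim under the same species. Deterministic
#' under the spec's seed.
#'
#' @param spec A [synthetic_catalog_spec()].
#' @return List with `catalog` (a catalog tibble whose `subgroup` column is
#'   the generating truth) and `truth` (tibble `id`, `group`).
#' @export
sample_catalog <- function(spec = synthetic_catalog_spec()) {
  stopifnot(inherits(spec, "synthetic_catalog_spec"))
  gens <- builtin_generators(spec$divergence, spec$indel_rate)
  local_with_seed(spec$seed, {
    rows <- purrr::map_dfr(gens, function(g) {
      letters21 <- colnames(g$profile)
      seqs <- vapply(seq_len(spec$n_per_group), function(i) {
        paste(vapply(seq_len(nrow(g$profile)), function(p) {
          sample(letters21, 1, prob = g$profile[p, ])
        }, ""), collapse = "")
      }, "")
      tibble(id = sprintf("%s_%03d", g$name, seq_len(spec$n_per_group)),
             species = sample(spec$species_pool, spec$n_per_group,
                              replace = TRUE),
             subgroup = g$name,
             alignment = seqs)
    })
    if (spec$duplicate_rate > 0) {
      dup <- runif(nrow(rows)) < spec$duplicate_rate
      if (any(dup)) {
        dup_rows <- rows[dup, ] %>% mutate(id = paste0(.data$id, "_dup"))
        rows <- bind_rows(rows, dup_rows)
      }
    }
    list(catalog = as_catalog(rows),
         truth = tibble(id = rows$id, group = rows$subgroup))
  })
}

#' Ideal alpha-helix coordinates
#'
#' CA atoms on a regular helix about the z axis (default 1.5 A rise and 100
#' degrees twist per residue, 2.3 A radius: the ideal alpha-helix with 3.6
#' residues per turn); CB atoms sit radially outward of their CA, and
#' approximate backbone N and C atoms are placed at one-third-residue phase
#' offsets so that pseudo-CB construction has something to work with.
#'
#' @param n_res Number of residues (>= 1).
#' @param rise Rise per residue, Angstrom.
#' @param twist Twist per residue, degrees.
#' @param radius CA helix radius, Angstrom.
#' @param with_cb Place CB atoms. Default `TRUE`.
#' @return A `residue_coords` tibble: `resno`, `resname`, `chain`, `plddt`
#'   and `ca_*`, `cb_*`, `n_*`, `c_*` coordinate columns.
#' @export
ideal_helix <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                        with_cb = TRUE) {
  if (n_res < 1) abort("n_res must be >= 1", class = "krabstrat_geom_error")
  i <- seq_len(n_res)
  th <- (i - 1) * twist * pi / 180
  out <- tibble(
    resno = i, resname = "ALA", chain = "A", plddt = NA_real_,
    ca_x = radius * cos(th), ca_y = radius * sin(th), ca_z = (i - 1) * rise
  )
  if (with_cb) {
    rb <- radius + 1.5
    out$cb_x <- rb * cos(th); out$cb_y <- rb * sin(th); out$cb_z <- out$ca_z
  } else {
    out$cb_x <- out$cb_y <- out$cb_z <- NA_real_
  }
  thn <- th - (twist / 3) * pi / 180
  thc <- th + (twist / 3) * pi / 180
  rn <- radius * 0.7
  out$n_x <- rn * cos(thn); out$n_y <- rn * sin(thn); out$n_z <- out$ca_z - rise / 3
  out$c_x <- rn * cos(thc); out$c_y <- rn * sin(thc); out$c_z <- out$ca_z + rise / 3
  class(out) <- c("residue_coords", class(out))
  out
}

# apply a rigid transform (3x3 rotation + translation) to all atom columns
transform_coords <- function(coords, rotation = diag(3), translation = c(0, 0, 0)) {
  for (atom in c("ca", "cb", "n", "c")) {
    cols <- paste0(atom, "_", c("x", "y", "z"))
    if (all(cols %in% names(coords))) {
      m <- as.matrix(coords[, cols])
      ok <- stats::complete.cases(m)
      m[ok, ] <- t(rotation %*% t(m[ok, , drop = FALSE]) + translation)
      coords[, cols] <- as_tibble(m)
    }
  }
  coords
}

#' Composite multi-helix structure with known geometry
#'
#' Concatenates ideal helix segments under given rigid placements, joined by
#' straight coil linkers (which never satisfy the helix distance criteria),
#' so detection and angle measurements can be tested against constructed
#' ground truth.
#'
#' @param segments List of segment specs: each a list with `n_res` and
#'   optionally `rise`, `twist`, `radius`, `rotation` (3x3), `translation`
#'   (length 3).
#' @param coil Number of linker residues between consecutive segments.
#' @return A `residue_coords` tibble with consecutive `resno`.
#' @export
composite_structure <- function(segments, coil = 4) {
  if (length(segments) < 1) abort("need at least one segment",
                                  class = "krabstrat_geom_error")
  placed <- purrr::map(segments, function(s) {
    if (is.null(s$n_res) || s$n_res < 1) {
      abort("segment with zero length", class = "krabstrat_geom_error")
    }
    h <- ideal_helix(s$n_res,
                     rise = s$rise %||% 1.5, twist = s$twist %||% 100,
                     radius = s$radius %||% 2.3)
    transform_coords(h, s$rotation %||% diag(3), s$translation %||% c(0, 0, 0))
  })
  # overlap check between placed segments
  if (length(placed) > 1) {
    for (a in seq_len(length(placed) - 1)) {
      for (b in (a + 1):length(placed)) {
        da <- as.matrix(placed[[a]][, c("ca_x", "ca_y", "ca_z")])
        db <- as.matrix(placed[[b]][, c("ca_x", "ca_y", "ca_z")])
        d2 <- outer(rowSums(da^2), rowSums(db^2), "+") - 2 * da %*% t(db)
        if (min(d2) < 1) {
          abort("overlapping segment placements", class = "krabstrat_geom_error")
        }
      }
    }
  }
  out <- placed[[1]]
  for (k in seq_along(placed)[-1]) {
    prev_end <- as.numeric(out[nrow(out), c("ca_x", "ca_y", "ca_z")])
    nxt <- placed[[k]]
    nxt_start <- as.numeric(nxt[1, c("ca_x", "ca_y", "ca_z")])
    if (coil > 0) {
      frac <- seq_len(coil) / (coil + 1)
      link <- tibble(
        resno = 0L, resname = "GLY", chain = "A", plddt = NA_real_,
        ca_x = prev_end[1] + frac * (nxt_start[1] - prev_end[1]),
        ca_y = prev_end[2] + frac * (nxt_start[2] - prev_end[2]),
        ca_z = prev_end[3] + frac * (nxt_start[3] - prev_end[3]),
        cb_x = NA_real_, cb_y = NA_real_, cb_z = NA_real_,
        n_x = NA_real_, n_y = NA_real_, n_z = NA_real_,
        c_x = NA_real_, c_y = NA_real_, c_z = NA_real_
      )
      out <- bind_rows(out, link)
    }
    out <- bind_rows(out, nxt)
  }
  out$resno <- seq_len(nrow(out))
  class(out) <- c("residue_coords", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
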