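test_that("edit grammar parses substitutions and block replacements", {
  e1 <- parse_edit("A27:R>V")
  expect_equal(e1$kind, "substitution")
  expect_equal(c(e1$start, e1$from, e1$to), c("A27", "R", "V"))

  # the MLE block gains one residue whichever range notation is used
  for (spec in c("A32-A34:KR>MLE", "A32-A33:KR>MLE")) {
    e <- parse_edit(spec)
    expect_equal(e$kind, "block_replacement")
    expect_equal(nchar(e$to) - nchar(e$from), 1L)
  }
  e3 <- parse_edit("A10-A12:FVD>SIY")
  expect_equal(nchar(e3$to) - nchar(e3$from), 0L)

  expect_error(parse_edit("A27RV"), class = "krabstrat_edit_error")
  expect_error(parse_edit("A12-A10:FV>DS"), class = "krabstrat_edit_error")
  expect_error(parse_edit("A27:RR>VV"), class = "krabstrat_edit_error")
  expect_error(edit_script("bad", c("A10-A12:FVD>SIY", "A11:V>I")),
               class = "krabstrat_edit_error")  # overlap
})

test_that("script application verifies context, remaps coordinates, and inverts", {
  ref <- synthetic_reference("PRDM9_ortho")
  lib <- mutant_library()

  # empty script is the identity
  expect_identical(apply_script(ref, edit_script("noop"))$residues, ref$residues)

  # KR -> MLE claims the vacant A32 and maps A32..A34
  m1 <- apply_script(ref, lib$P9Am1)
  expect_equal(residue_at(m1, c("A32", "A33", "A34")), c("M", "L", "E"))
  expect_equal(length_delta(ref, m1), 1L)

  # mismatching context refuses with a position report
  wrong <- apply_script(ref, edit_script("pre", "A9:S>W"))
  expect_error(apply_script(wrong, lib$P9Am10), regexp = "A9",
               class = "krabstrat_edit_error")

  # apply then inverse is the identity for every fully specified script
  z10 <- synthetic_reference("hs_mKRAB")
  for (nm in names(lib)) {
    sc <- lib[[nm]]
    if (sc$provenance != "fully_specified") next
    wt <- if (grepl("^ZNF10", nm)) z10 else ref
    mut <- apply_script(wt, sc)
    back <- apply_script(mut, invert_script(sc))
    expect_identical(back$residues, wt$residues, label = nm)
    # coordinate monotonicity survives application
    expect_true(all(diff(mut$coords$res_index) > 0), label = nm)
  }
})

test_that("the P9Am10 roadmap counts 3 substitutions, 1 block, +1 residue", {
  ref <- synthetic_reference("PRDM9_ortho")
  lib <- mutant_library()
  mut <- apply_script(ref, lib$P9Am10)
  inv <- diff_inventory(ref, mut, lib$P9Am10)
  expect_equal(inv$n_substitutions, 3L)
  expect_equal(inv$n_block_replacements, 1L)
  expect_equal(inv$length_delta, 1L)
  expect_setequal(inv$positions[[1]], c("A9", "A20", "A27", "A32"))
  # inconsistent triples refuse
  expect_error(diff_inventory(ref, ref, lib$P9Am10),
               class = "krabstrat_edit_error")
  # identity script: all zeros
  noop <- edit_script("noop")
  inv0 <- diff_inventory(ref, apply_script(ref, noop), noop)
  expect_equal(c(inv0$n_substitutions, inv0$n_block_replacements,
                 inv0$length_delta), c(0L, 0L, 0L))
})

test_that("the library encodes the construct roster faithfully", {
  lib <- mutant_library()
  expect_equal(nrow(lib$P9Am10$edits), 4L)
  # every script with the MLE block gains one residue; pure-substitution
  # scripts stay length-neutral
  for (nm in names(lib)) {
    sc <- lib[[nm]]
    if (sc$provenance != "fully_specified") next
    delta <- sum(nchar(sc$edits$to) - nchar(sc$edits$from))
    if (any(sc$edits$to == "MLE")) {
      expect_equal(delta, 1L, label = nm)
    } else if (all(sc$edits$kind == "substitution")) {
      expect_equal(delta, 0L, label = nm)
    }
  }
  # P9Am13 equals P9Am10 with the MLE block backed out
  ref <- synthetic_reference("PRDM9_ortho")
  m13 <- apply_script(ref, lib$P9Am13)
  m10 <- apply_script(ref, lib$P9Am10)
  backed <- apply_script(m10, invert_script(edit_script("mle", "A32-A34:KR>MLE")))
  expect_identical(m13$residues, backed$residues)

  # figure-dependent stubs refuse application
  expect_error(apply_script(ref, lib$P9Am5), regexp = "figure-dependent",
               class = "krabstrat_edit_error")

  # random scripts: inventory equals a direct per-edit recount
  set.seed(41)
  z10 <- synthetic_reference("hs_mKRAB")
  for (k in 1:10) {
    pos <- sort(sample(setdiff(1:42, 32), 3))
    from <- residue_at(z10, paste0("A", pos))
    to <- vapply(from, function(f) sample(setdiff(c("A", "G", "W"), f), 1), "")
    sc <- edit_script("rand", sprintf("A%d:%s>%s", pos, from, to))
    inv <- diff_inventory(z10, apply_script(z10, sc), sc)
    expect_equal(inv$n_substitutions, 3L)
    expect_equal(inv$length_delta, 0L)
  }
})

test_that("hybrid assembly unifies A and B coordinate maps", {
  a <- synthetic_reference("PRDM9_ortho", "A"); a$source_id <- "P9Am10"
  b <- synthetic_reference("hs_mKRAB", "B"); b$source_id <- "Z10B"
  hyb <- assemble_hybrid(a, b)
  expect_equal(hyb$source_id, "P9Am10-Z10B")
  expect_equal(nchar(hyb$residues),
               nchar(a$residues) + nchar(b$residues))
  ranks <- parse_krab_coord(hyb$coords$coord)$rank
  expect_true(all(diff(ranks) > 0))
  expect_true(all(diff(hyb$coords$res_index) > 0))
  # B-ablated control: empty B part gives an A-only construct
  empty_b <- krab_sequence("")
  ab <- assemble_hybrid(a, empty_b)
  expect_identical(ab$residues, a$residues)
  # overlapping frames refuse
  expect_error(assemble_hybrid(a, a), class = "krabstrat_edit_error")
})
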