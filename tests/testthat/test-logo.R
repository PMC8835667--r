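test_that("column frequencies count residues, gaps and occupancy", {
  cf <- column_frequencies(c("AA", "A-", "AC", "A-"))
  col1 <- cf[cf$column == 1, ]
  expect_equal(col1$count[col1$residue == "A"], 4L)
  expect_equal(unique(col1$gap_count), 0L)
  col2 <- cf[cf$column == 2, ]
  expect_equal(sort(col2$residue), c("A", "C"))
  expect_equal(unique(col2$gap_count), 2L)
  expect_equal(unique(col2$occupancy), 0.5)
  expect_error(column_frequencies(character()), class = "krabstrat_logo_error")

  # conservation: per-column counts plus gaps account for every row
  set.seed(12)
  aln <- replicate(6, paste(sample(c("A", "C", "D", "-"), 15, replace = TRUE),
                            collapse = ""))
  cf2 <- column_frequencies(aln)
  tot <- dplyr::summarise(dplyr::group_by(as.data.frame(cf2), column),
                          n = sum(count) + unique(gap_count))
  expect_true(all(tot$n == 6))
})

test_that("information content matches relative-entropy closed forms", {
  # single-residue column at uniform background: log2(20) bits
  expect_equal(information_content(c(A = 4)), log2(20), tolerance = 1e-9)
  # hand evaluation for p = {0.75, 0.25}
  expect_equal(information_content(c(A = 3, C = 1)),
               0.75 * log2(15) + 0.25 * log2(5), tolerance = 1e-6)
  expect_equal(information_content(c(A = 3, C = 1)), 3.5106, tolerance = 1e-4)
  # p equal to background: zero bits
  bg <- setNames(c(0.75, 0.25, rep(0, 18)),
                 c("A", "C", setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                     c("A", "C"))))
  bg <- bg + 1e-12; bg <- bg / sum(bg)
  expect_equal(information_content(c(A = 3, C = 1), bg), 0, tolerance = 1e-6)
  expect_error(information_content(c(A = 0)), class = "krabstrat_logo_error")
})

test_that("logo letter heights decompose the column information content", {
  set.seed(9)
  aln <- replicate(20, paste(sample(c("A", "C", "D", "E", "-"), 12,
                                    replace = TRUE, prob = c(4, 2, 1, 1, 1) / 9),
                             collapse = ""))
  lm <- logo_matrix(aln)
  sums <- dplyr::summarise(dplyr::group_by(as.data.frame(lm), column),
                           h = sum(height), ic = unique(ic))
  expect_equal(sums$h, sums$ic, tolerance = 1e-9)
  expect_true(all(lm$ic >= 0 & lm$ic <= log2(20) + 1e-12))
})

test_that("mostly-empty columns are dropped with an index map", {
  aln <- c("A-C", "A-C", "AAC", "A--", "A-C", "A-C", "A-C", "A-C", "A-C", "A-C")
  out <- drop_sparse_columns(aln, max_gap_fraction = 0.5)
  expect_equal(out$kept_columns, c(1L, 3L))
  expect_equal(out$alignment[1], "AC")
  # no gaps: identity
  out2 <- drop_sparse_columns(c("ACD", "ACD"))
  expect_equal(out2$kept_columns, 1:3)
  expect_error(drop_sparse_columns(c("-", "-")), class = "krabstrat_logo_error")
  # composing with column_frequencies leaves only well-occupied columns
  cf <- column_frequencies(out$alignment)
  expect_true(all(unique(cf$occupancy) >= 0.5))
})

test_that("positional counts recover a planted residue rate per subgroup", {
  sim <- sample_catalog(synthetic_catalog_spec(n_per_group = 200, seed = 13))
  alns <- split(sim$catalog$alignment, sim$catalog$subgroup)
  pc <- position_counts(alns, tibble::tibble(coord = "B14", residue = "E"))
  lcha <- pc[pc$subgroup == "lcha_ZNF", ]
  # planted at rate 0.4 in the lcha generator: count within 3 binomial SE
  expect_equal(lcha$denominator, 200L)
  se <- sqrt(200 * 0.4 * 0.6)
  expect_lt(abs(lcha$count - 80), 3 * se)
  # near-absent elsewhere (only divergence noise)
  p9 <- pc[pc$subgroup == "PRDM9_ortho", ]
  expect_lt(p9$count, 15)

  # empty subgroup: 0 of 0
  pc0 <- position_counts(list(none = character()),
                         tibble::tibble(coord = "B14", residue = "E"))
  expect_equal(c(pc0$count, pc0$denominator), c(0L, 0L))
  # coordinates outside the frame refuse
  expect_error(position_counts(alns, tibble::tibble(coord = "B36", residue = "E")),
               class = "krabstrat_logo_error")

  # permutation invariance of the totals
  perm <- lapply(alns, function(a) a[sample(length(a))])
  pc_perm <- position_counts(perm, tibble::tibble(coord = "B14", residue = "E"))
  expect_equal(dplyr::arrange(pc_perm, subgroup)$count,
               dplyr::arrange(pc, subgroup)$count)
})
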