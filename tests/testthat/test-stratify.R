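test_that("the clamp floor maps weak E-values to exactly 2", {
  cl <- clamp_neglog10(c(0.01, 1e-10, 0.5))
  expect_equal(cl$value, c(2, 10, 2))
  expect_equal(cl$clamped, c(TRUE, FALSE, TRUE))
  expect_error(clamp_neglog10(0), class = "krabstrat_stratify_error")
  expect_error(clamp_neglog10(-1), class = "krabstrat_stratify_error")
  # configurable floor: anything at or above it lands exactly on the floor
  cl2 <- clamp_neglog10(1e-3, floor_evalue = 1e-4)
  expect_equal(cl2$value, 4)
  expect_true(cl2$clamped)
  expect_equal(clamp_neglog10(1e-6, floor_evalue = 1e-4)$value, 6)
})

make_panel <- function(catalog, n_cal = 200, seed = 3) {
  groups <- unique(catalog$subgroup)
  setNames(lapply(groups, function(g) {
    calibrate_evd(build_profile(catalog$alignment[catalog$subgroup == g],
                                name = g),
                  n_samples = n_cal, seed = seed + match(g, groups))
  }), groups)
}

test_that("cross-scoring yields one clamped score per entry and model", {
  sim <- sample_catalog(synthetic_catalog_spec(n_per_group = 8, seed = 21))
  panel <- make_panel(sim$catalog)
  sc <- cross_score(sim$catalog, panel)
  expect_equal(nrow(sc), nrow(sim$catalog) * length(panel))
  expect_true(all(sc$score >= 2))
  expect_true(all(sc$evalue > 0))

  # no floor violations anywhere (clamping invariant)
  expect_true(all(sc$score[sc$clamped] == 2))

  # 1 entry x 1 model
  sc1 <- cross_score(sim$catalog[1, ], panel[1])
  expect_equal(nrow(sc1), 1L)

  expect_error(cross_score(sim$catalog, list()),
               class = "krabstrat_stratify_error")
  expect_error(cross_score(sim$catalog, list(m = build_profile("ACD"))),
               class = "krabstrat_calibration_error")
})

test_that("subgroup assignment picks the top model with margins; ties are unknown", {
  sc <- tibble::tibble(id = c("e1", "e1", "e2", "e2"),
                       model = c("A", "B", "A", "B"),
                       score = c(12, 4, 2, 2),
                       clamped = c(FALSE, FALSE, TRUE, TRUE))
  asg <- assign_subgroup(sc)
  expect_equal(asg$label[asg$id == "e1"], "A")
  expect_equal(asg$margin[asg$id == "e1"], 8)
  expect_equal(asg$label[asg$id == "e2"], "unknown")
  expect_equal(asg$margin[asg$id == "e2"], 0)
})

test_that("group summaries report count, median and range; groups of one collapse", {
  sc <- tibble::tibble(id = paste0("e", 1:4),
                       model = "A",
                       score = c(2, 3, 4, 7),
                       clamped = c(TRUE, FALSE, FALSE, FALSE))
  truth <- tibble::tibble(id = paste0("e", 1:4),
                          group = c("g1", "g1", "g1", "g2"))
  sm <- summarize_groups(sc, truth)
  g1 <- sm[sm$group == "g1", ]
  expect_equal(g1$median, 3)
  expect_equal(c(g1$min, g1$max), c(2, 4))
  expect_true(g1$min_clamped)
  g2 <- sm[sm$group == "g2", ]
  expect_equal(c(g2$median, g2$min, g2$max), c(7, 7, 7))
  disp <- format_group_summary(sm)
  expect_equal(disp$display[disp$group == "g1"], "3.00[<2-4.00]")
  expect_error(summarize_groups(sc, truth[1:3, ]),
               class = "krabstrat_stratify_error")
})

test_that("WMW p-values: exact enumeration cases and the ties convention", {
  # identical samples with ties: p = 1
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3)), 1)
  # fully separated: exactly 2 of the 70 assignments are as extreme
  expect_equal(compare_groups(c(1, 2, 3, 4), c(10, 11, 12, 13)), 2 / 70,
               tolerance = 1e-12)
  expect_error(compare_groups(numeric(), 1),
               class = "krabstrat_stratify_error")
})

test_that("exact WMW branch matches the reference implementation on untied data", {
  set.seed(8)
  for (k in 1:25) {
    n_a <- sample(2:8, 1); n_b <- sample(2:8, 1)
    x <- sample(1:100, n_a); y <- sample(setdiff(1:100, x), n_b)
    p_ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(compare_groups(x, y), p_ref, tolerance = 1e-12,
                 label = sprintf("n_a=%d n_b=%d", n_a, n_b))
  }
})

test_that("normal approximation tracks the exact distribution at n = 8 + 8", {
  # for untied data p depends only on U, so covering many subsets of the
  # ranks 1..16 exercises the whole distribution
  set.seed(64)
  seen_u <- c()
  for (k in 1:150) {
    x <- sort(sample(1:16, 8))
    y <- setdiff(1:16, x)
    t_ex <- wmw_test(x, y, method = "exact")
    seen_u <- union(seen_u, t_ex$statistic)
    p_ap <- wmw_test(x, y, method = "approximate")$p.value
    expect_lt(abs(t_ex$p.value - p_ap), 0.02)
  }
  # include the extreme configurations explicitly
  for (x in list(1:8, c(1:7, 16), 9:16)) {
    y <- setdiff(1:16, x)
    expect_lt(abs(wmw_test(x, y, method = "exact")$p.value -
                  wmw_test(x, y, method = "approximate")$p.value), 0.02)
  }
  expect_gt(length(seen_u), 20)
})

test_that("curation filters on the E-value boundary and is idempotent", {
  sim <- sample_catalog(synthetic_catalog_spec(n_per_group = 6, seed = 33))
  own <- make_panel(sim$catalog)[["hs_mKRAB"]]
  # random junk entries score above the permissive threshold and are removed
  set.seed(1)
  junk <- tibble::tibble(
    id = paste0("junk", 1:4), species = "Nullus exemplum",
    subgroup = "unknown",
    alignment = replicate(4, paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                          77, replace = TRUE), collapse = "")))
  cat_all <- dplyr::bind_rows(sim$catalog, junk)
  kept <- curate_filter(cat_all, own, keep_below = 0.01)
  removed <- attr(kept, "removed")
  expect_true(all(junk$id %in% removed$id))
  expect_true(all(removed$evalue >= 0.01))
  # boundary: an entry at exactly the threshold is removed
  expect_true(all(kept$id %in% cat_all$id))
  # idempotence
  again <- curate_filter(kept, own, keep_below = 0.01, n_db = nrow(cat_all))
  expect_equal(nrow(attr(again, "removed")), 0L)
  # empty in, empty out
  empty <- curate_filter(cat_all[0, ], own)
  expect_equal(nrow(empty), 0L)
})

test_that("deduplication collapses identical sequences within a species only", {
  cat <- tibble::tibble(
    id = c("a1", "a2", "b1", "c1", "c2", "c3"),
    species = c("sp1", "sp1", "sp2", "sp3", "sp3", "sp3"),
    subgroup = "unknown",
    sequence = c("ACDEF", "ACDEF", "ACDEF", "GGGGG", "GGGGG", "HHHHH"))
  out <- dedup_within_species(cat)
  # a2 merges into a1; b1 survives (different species); c2 merges into c1
  expect_equal(out$id, c("a1", "b1", "c1", "c3"))
  merged <- attr(out, "merged")
  expect_equal(merged$merged_id, c("a2", "c2"))
  expect_equal(merged$kept_id, c("a1", "c1"))
})
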