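test_that("forward and Viterbi equal brute-force path enumeration on toy models", {
  seqs <- reduced_alphabet_seqs(3)
  for (nm in 1:3) {
    hmm <- random_toy_hmm(nm, seed = 100 + nm)
    for (s in seqs) {
      expect_equal(forward_score(hmm, s), oracle_forward_bits(hmm, s),
                   tolerance = 1e-9,
                   label = sprintf("forward n_match=%d seq=%s", nm, s))
      expect_equal(viterbi_score(hmm, s)$bit_score, oracle_viterbi_bits(hmm, s),
                   tolerance = 1e-9,
                   label = sprintf("viterbi n_match=%d seq=%s", nm, s))
    }
  }
})

test_that("Viterbi is bounded by forward and decodes all-match on peaked models", {
  # sharply peaked model: consensus scores positive, path is all match
  peaked <- build_profile(rep("ACDEF", 50), pseudocount_weight = 0.1)
  cons <- hmm_consensus(peaked)
  expect_identical(cons, "ACDEF")
  expect_gt(forward_score(peaked, cons), 0)
  v <- viterbi_score(peaked, cons)
  expect_identical(unique(v$path$state_type), "M")
  expect_equal(nrow(v$path), 5L)

  # max over paths can never exceed the sum over paths
  set.seed(31)
  for (k in 1:10) {
    hmm <- random_toy_hmm(sample(1:3, 1), seed = 200 + k)
    s <- paste(sample(c("A", "C", "D", "E"), sample(1:4, 1), replace = TRUE),
               collapse = "")
    expect_lte(viterbi_score(hmm, s)$bit_score, forward_score(hmm, s) + 1e-12)
  }
})

test_that("background sequences score below the consensus on average", {
  hmm <- build_profile(rep(c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEYGHIKL"), 5))
  cons_score <- forward_score(hmm, hmm_consensus(hmm))
  set.seed(17)
  null_scores <- replicate(50, {
    forward_score(hmm, sample_background_sequence(10, hmm$background))
  })
  expect_lt(mean(null_scores), cons_score)
})

test_that("local mode: background-typical flanks shift the score only boundedly", {
  hmm <- build_profile(rep("ACDEFGHIKL", 20))
  core <- hmm_consensus(hmm)
  s0 <- forward_score(hmm, core)
  set.seed(23)
  deltas <- replicate(20, {
    flank_l <- sample_background_sequence(sample(1:10, 1), hmm$background)
    flank_r <- sample_background_sequence(sample(1:10, 1), hmm$background)
    forward_score(hmm, paste0(flank_l, core, flank_r)) - s0
  })
  # flanks emit near-background residues: no unbounded drift either way
  expect_lt(max(abs(deltas)), 5)
})

test_that("Gumbel calibration recovers known parameters and is deterministic", {
  # parameter recovery on synthetic Gumbel(mu = 0, lambda = 0.7) draws
  set.seed(4711)
  draws <- -log(-log(runif(2000))) / 0.7
  fit <- krabstrat:::fit_gumbel(draws)
  expect_equal(fit$lambda, 0.7, tolerance = 0.1)
  expect_equal(fit$mu, 0, tolerance = 0.15)

  hmm <- build_profile(rep("ACDEFGHIKL", 10))
  c1 <- calibrate_evd(hmm, n_samples = 150, seed = 99)
  c2 <- calibrate_evd(hmm, n_samples = 150, seed = 99)
  expect_identical(c1$evd, c2$evd)
  expect_error(calibrate_evd(hmm, n_samples = 50),
               class = "krabstrat_calibration_error")

  # degenerate score distributions refuse to calibrate
  expect_error(krabstrat:::fit_gumbel(rep(1, 500)),
               class = "krabstrat_calibration_error")
})

test_that("E-values follow the fitted Gumbel tail", {
  hmm <- calibrate_evd(build_profile(rep("ACDEFGHIKLMNPQ", 10)),
                       n_samples = 400, seed = 12)
  # closed form at the mode: E(mu) with n_db = 1 is 1 - 1/e
  expect_equal(evalue(hmm, hmm$evd$mu, n_db = 1), 1 - exp(-1),
               tolerance = 1e-12)
  # monotone decreasing in score, vanishing in the limit
  s_grid <- seq(hmm$evd$mu - 5, hmm$evd$mu + 30, length.out = 40)
  ev <- vapply(s_grid, function(s) evalue(hmm, s, n_db = 100), numeric(1))
  expect_true(all(diff(ev) < 0))
  expect_lt(evalue(hmm, hmm$evd$mu + 1e6, n_db = 100), 1e-12)
  # uncalibrated models refuse
  expect_error(evalue(build_profile("ACD"), 1),
               class = "krabstrat_calibration_error")

  # empirical tail: fraction of null sequences above s matches E(s)/n
  set.seed(5)
  null_scores <- replicate(2000, {
    forward_score(hmm, sample_background_sequence(hmm$n_match, hmm$background))
  })
  for (q in c(0.8, 0.9, 0.95)) {
    s <- quantile(null_scores, q)
    p_fit <- evalue(hmm, as.numeric(s), n_db = 1)
    p_emp <- mean(null_scores >= s)
    se <- sqrt(p_emp * (1 - p_emp) / length(null_scores))
    expect_lt(abs(p_fit - p_emp), 3 * se + 0.01)
  }
})
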