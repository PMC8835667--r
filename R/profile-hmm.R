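#' Build a profile HMM from a multiple alignment
#'
#' Match states are alignment columns whose residue occupancy is at least
#' `occupancy_threshold` (the "remove mostly-empty columns" rule); other
#' columns feed the flanking insert states. Emissions are
#' `(count + weight * background) / (n + weight)` per column; transitions are
#' tallied from the observed match/insert/delete usage of every row and
#' Laplace-smoothed. The model is scored local-in-sequence,
#' global-in-model (domain-scan semantics).
#'
#' @param alignment Character vector of equal-length gapped rows (or an
#'   object coercible via `as.character`, e.g. a Biostrings alignment).
#' @param occupancy_threshold Minimum fraction of non-gap characters for a
#'   column to become a match state. Default 0.5.
#' @param pseudocount_weight Total background-proportional pseudocount mass
#'   added per emission column. Default 1.
#' @param background `"uniform"` (1/20 each, the default) or `"alignment"`
#'   (overall residue composition of the alignment, pseudocounted).
#' @param name Model name stored with the profile.
#' @return A `profile_hmm` object.
#' @export
build_profile <- function(alignment, occupancy_threshold = 0.5,
                          pseudocount_weight = 1,
                          background = c("uniform", "alignment"),
                          name = "model") {
  background <- match.arg(background)
  alignment <- vapply(as.character(alignment), normalize_residues, "",
                      USE.NAMES = FALSE)
  if (length(alignment) < 1) {
    abort("empty alignment", class = "krabstrat_hmm_error")
  }
  if (length(unique(nchar(alignment))) != 1) {
    abort("alignment rows must have uniform length", class = "krabstrat_hmm_error")
  }
  mat <- do.call(rbind, strsplit(alignment, ""))
  n_rows <- nrow(mat)
  n_cols <- ncol(mat)

  occupancy <- colMeans(mat != "-")
  match_cols <- which(occupancy >= occupancy_threshold)
  n_match <- length(match_cols)
  if (n_match == 0) {
    abort("no column reaches the occupancy threshold", class = "krabstrat_hmm_error")
  }

  if (background == "uniform") {
    bg <- setNames(rep(1 / 20, 20), AA20)
  } else {
    all_counts <- table(factor(mat[mat %in% AA20], levels = AA20))
    bg <- (as.numeric(all_counts) + 1) / (sum(all_counts) + 20)
    bg <- setNames(bg / sum(bg), AA20)
  }

  count_column <- function(chars) {
    as.numeric(table(factor(chars[chars %in% AA20], levels = AA20)))
  }
  smooth <- function(counts) {
    p <- (counts + pseudocount_weight * bg) / (sum(counts) + pseudocount_weight)
    p / sum(p)
  }

  match_emissions <- t(vapply(match_cols,
                              function(j) smooth(count_column(mat[, j])),
                              numeric(20)))
  colnames(match_emissions) <- AA20

  # residues in non-match columns pool into the insert state that precedes
  # the next match column
  insert_state_of_col <- integer(n_cols)
  k <- 0L
  for (j in seq_len(n_cols)) {
    if (j %in% match_cols) k <- k + 1L else insert_state_of_col[j] <- -1L
    if (insert_state_of_col[j] == -1L) insert_state_of_col[j] <- k
  }
  insert_counts <- matrix(0, nrow = n_match + 1, ncol = 20,
                          dimnames = list(NULL, AA20))
  for (j in setdiff(seq_len(n_cols), match_cols)) {
    insert_counts[insert_state_of_col[j] + 1L, ] <-
      insert_counts[insert_state_of_col[j] + 1L, ] + count_column(mat[, j])
  }
  insert_emissions <- t(apply(insert_counts, 1, smooth))
  colnames(insert_emissions) <- AA20

  # transition counts from per-row state paths
  tc <- matrix(0, nrow = n_match + 1, ncol = 7,
               dimnames = list(NULL, c("mm", "mi", "md", "im", "ii", "dm", "dd")))
  is_match_col <- seq_len(n_cols) %in% match_cols
  # D<->I transitions are not part of the state plan; such row events are
  # tallied as the corresponding exit through a match state
  tally <- function(from_state, from_idx, to_state) {
    pair <- paste0(tolower(from_state), tolower(to_state))
    if (pair == "di") pair <- "dm"
    if (pair == "id") pair <- "im"
    tc[from_idx + 1L, pair] <<- tc[from_idx + 1L, pair] + 1
  }
  for (r in seq_len(n_rows)) {
    prev_state <- "M"; prev_idx <- 0L  # begin
    for (j in seq_len(n_cols)) {
      ch <- mat[r, j]
      if (is_match_col[j]) {
        state <- if (ch == "-") "D" else "M"
        tally(prev_state, prev_idx, state)
        prev_state <- state
        prev_idx <- sum(is_match_col[seq_len(j)])
      } else if (ch != "-") {
        tally(prev_state, prev_idx, "I")
        prev_state <- "I"
      }
    }
    tally(prev_state, prev_idx, "M")  # exit to end state
  }

  transitions <- matrix(0, nrow = n_match + 1, ncol = 7,
                        dimnames = dimnames(tc))
  norm_triple <- function(x) (x + 1) / sum(x + 1)
  for (j in seq_len(n_match + 1)) {
    last <- j == n_match + 1
    if (last) {
      mm_mi <- norm_triple(tc[j, c("mm", "mi")])
      transitions[j, c("mm", "mi")] <- mm_mi
      transitions[j, "md"] <- 0
    } else {
      transitions[j, c("mm", "mi", "md")] <- norm_triple(tc[j, c("mm", "mi", "md")])
    }
    transitions[j, c("im", "ii")] <- norm_triple(tc[j, c("im", "ii")])
    if (j == 1) {
      transitions[j, c("dm", "dd")] <- c(1, 0)  # no D_0 state
    } else if (last) {
      transitions[j, c("dm", "dd")] <- c(1, 0)  # D_n can only exit
    } else {
      transitions[j, c("dm", "dd")] <- norm_triple(tc[j, c("dm", "dd")])
    }
  }

  new_profile_hmm(name = name, n_match = n_match,
                  match_emissions = match_emissions,
                  insert_emissions = insert_emissions,
                  transitions = transitions, background = bg,
                  match_columns = match_cols, evd = NULL)
}

new_profile_hmm <- function(name, n_match, match_emissions, insert_emissions,
                            transitions, background, match_columns = NULL,
                            evd = NULL) {
  hmm <- structure(
    list(name = name, n_match = as.integer(n_match),
         match_emissions = match_emissions,
         insert_emissions = insert_emissions,
         transitions = transitions,
         background = background,
         match_columns = match_columns,
         evd = evd),
    class = "profile_hmm"
  )
  validate_profile_hmm(hmm)
  hmm
}

#' Validate profile HMM normalization invariants
#'
#' Every emission vector and every outgoing transition group must sum to 1
#' (within `tol`); probabilities must be non-negative, and strictly positive
#' except at structural zeros (no delete state 0, no transitions beyond the
#' last match state).
#'
#' @param hmm A `profile_hmm`.
#' @param tol Tolerance on the sums.
#' @return `hmm`, invisibly; errors on violation.
#' @export
validate_profile_hmm <- function(hmm, tol = 1e-9) {
  n <- hmm$n_match
  if (n < 1) abort("n_match must be >= 1", class = "krabstrat_hmm_error")
  check_rows <- function(m, what) {
    s <- rowSums(m)
    if (any(abs(s - 1) > tol)) {
      abort(sprintf("%s row %d sums to %.6f, expected 1", what,
                    which(abs(s - 1) > tol)[1], s[which(abs(s - 1) > tol)[1]]),
            class = "krabstrat_hmm_error")
    }
    if (any(m <= 0)) {
      abort(sprintf("%s contains non-positive probabilities", what),
            class = "krabstrat_hmm_error")
    }
  }
  check_rows(hmm$match_emissions, "match emissions")
  check_rows(hmm$insert_emissions, "insert emissions")
  if (abs(sum(hmm$background) - 1) > tol || any(hmm$background <= 0)) {
    abort("background must be a positive probability vector",
          class = "krabstrat_hmm_error")
  }
  tr <- hmm$transitions
  for (j in seq_len(n + 1)) {
    last <- j == n + 1
    m_out <- if (last) tr[j, c("mm", "mi")] else tr[j, c("mm", "mi", "md")]
    groups <- list(m_out = m_out, i_out = tr[j, c("im", "ii")])
    if (!last && j > 1) groups$d_out <- tr[j, c("dm", "dd")]
    for (g in names(groups)) {
      if (abs(sum(groups[[g]]) - 1) > tol || any(groups[[g]] < 0)) {
        abort(sprintf("transition group %s at state %d does not normalize",
                      g, j - 1L),
              class = "krabstrat_hmm_error")
      }
    }
  }
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> '%s': %d match states, %s\n", x$name, x$n_match,
              if (is.null(x$evd)) "uncalibrated"
              else sprintf("Gumbel(mu = %.3f, lambda = %.3f, n = %d)",
                           x$evd$mu, x$evd$lambda, x$evd$n_calibration)))
  cat("  consensus:", hmm_consensus(x), "\n")
  invisible(x)
}

#' Consensus string of a profile HMM
#'
#' The highest-probability match emission per state.
#' @param hmm A `profile_hmm`.
#' @return Character scalar of length `n_match`.
#' @export
hmm_consensus <- function(hmm) {
  paste(AA20[apply(hmm$match_emissions, 1, which.max)], collapse = "")
}

#' @method tidy profile_hmm
#' @export
tidy.profile_hmm <- function(x, ...) {
  as_tibble(x$match_emissions) %>%
    mutate(state = dplyr::row_number()) %>%
    tidyr::pivot_longer(-"state", names_to = "residue", values_to = "probability") %>%
    mutate(model = x$name) %>%
    select("model", "state", "residue", "probability")
}

#' @method glance profile_hmm
#' @export
glance.profile_hmm <- function(x, ...) {
  tibble(model = x$name, n_match = x$n_match,
         calibrated = !is.null(x$evd),
         evd_mu = if (is.null(x$evd)) NA_real_ else x$evd$mu,
         evd_lambda = if (is.null(x$evd)) NA_real_ else x$evd$lambda,
         n_calibration = if (is.null(x$evd)) NA_integer_ else x$evd$n_calibration)
}

# encode a sequence as 0-based emission-column indices; X-class residues map
# to the extra zero log-odds column
encode_sequence <- function(seq) {
  seq <- normalize_residues(seq, allow_gap = FALSE)
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, AA20) - 1L
  idx[is.na(idx)] <- 20L
  idx
}

# log2-odds emission matrices with the trailing X column
hmm_log_odds <- function(hmm) {
  lb <- log2(hmm$background)
  lmatch <- cbind(sweep(log2(hmm$match_emissions), 2, lb), X = 0)
  lins <- cbind(sweep(log2(hmm$insert_emissions), 2, lb), X = 0)
  ltrans <- log2(hmm$transitions)
  list(lmatch = lmatch, lins = lins, ltrans = ltrans)
}

#' Score a sequence against a profile HMM
#'
#' `forward_score()` returns the forward bit score: log2 of the ratio of the
#' sequence likelihood under the model (summed over all local alignments) to
#' its likelihood under the background null. `viterbi_score()` returns the
#' best single alignment with its decoded match/insert/delete path.
#'
#' @param hmm A `profile_hmm`.
#' @param seq Amino-acid string (ambiguity codes score zero log-odds).
#' @return `forward_score()`: numeric bit score. `viterbi_score()`: a
#'   `score_result` list with `bit_score`, `evalue` (if calibrated, else
#'   `NA`) and `path`, a tibble of the model-state trace.
#' @export
forward_score <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (!nzchar(seq)) abort("empty sequence", class = "krabstrat_hmm_error")
  lo <- hmm_log_odds(hmm)
  .forward_bits_cpp(lo$lmatch, lo$lins, lo$ltrans, encode_sequence(seq))
}

#' @rdname forward_score
#' @export
viterbi_score <- function(hmm, seq) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (!nzchar(seq)) abort("empty sequence", class = "krabstrat_hmm_error")
  lo <- hmm_log_odds(hmm)
  res <- .viterbi_bits_cpp(lo$lmatch, lo$lins, lo$ltrans, encode_sequence(seq))
  path <- as_tibble(res$path)
  path$state_type <- c("M", "I", "D")[path$type]
  ev <- if (is.null(hmm$evd)) NA_real_ else evalue(hmm, res$bits, n_db = 1L)
  structure(list(bit_score = res$bits, evalue = ev,
                 path = select(path, "state_type", "state", "seq_pos")),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> %.3f bits%s, path %s\n", x$bit_score,
              if (is.na(x$evalue)) "" else sprintf(" (E = %.3g)", x$evalue),
              paste0(head(x$path$state_type, 20), collapse = "")))
  invisible(x)
}

#' Sample a background sequence
#'
#' @param n Length.
#' @param background Probability vector over the 20 residues.
#' @return Amino-acid string.
#' @export
sample_background_sequence <- function(n, background) {
  paste(sample(AA20, n, replace = TRUE, prob = background), collapse = "")
}

# maximum-likelihood Gumbel fit (distribution of maxima):
# f(s) = lambda exp(-lambda (s - mu) - exp(-lambda (s - mu)))
fit_gumbel <- function(x) {
  if (var(x) < 1e-12) {
    abort("degenerate score distribution: zero variance",
          class = "krabstrat_calibration_error")
  }
  xc <- x - min(x)  # keeps the exponentials in (0, 1]
  h <- function(beta) {
    w <- exp(-xc / beta)
    beta - mean(xc) + sum(xc * w) / sum(w)
  }
  beta0 <- sqrt(6 * var(x)) / pi  # moment estimate seeds the bracket
  lo <- beta0 / 10; up <- beta0 * 10
  while (h(lo) > 0 && lo > beta0 / 1e6) lo <- lo / 2
  while (h(up) < 0 && up < beta0 * 1e6) up <- up * 2
  beta <- uniroot(h, c(lo, up), tol = 1e-10)$root
  mu <- min(x) - beta * log(mean(exp(-xc / beta)))
  list(mu = mu, lambda = 1 / beta)
}

#' Calibrate E-values against a Gumbel null
#'
#' Scores `n_samples` random background sequences with [forward_score()] and
#' fits Gumbel (extreme-value) location/scale by maximum likelihood. The
#' fitted `(mu, lambda)` turn bit scores into E-values via
#' `E(s) = n_db * (1 - exp(-exp(-lambda * (s - mu))))`.
#'
#' @inheritParams forward_score
#' @param n_samples Number of null sequences (>= 100).
#' @param length_sampler Function `(k)` returning `k` sequence lengths;
#'   defaults to constant `n_match`.
#' @param seed Integer seed; the calibration is deterministic given it.
#' @return The `profile_hmm` with an `evd` component.
#' @export
calibrate_evd <- function(hmm, n_samples = 1000, length_sampler = NULL,
                          seed = 1072) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (n_samples < 100) {
    abort("n_samples must be >= 100", class = "krabstrat_calibration_error")
  }
  if (is.null(length_sampler)) {
    length_sampler <- function(k) rep(hmm$n_match, k)
  }
  lo <- hmm_log_odds(hmm)
  scores <- local_with_seed(seed, {
    lens <- length_sampler(n_samples)
    vapply(lens, function(L) {
      s <- sample.int(20L, L, replace = TRUE, prob = hmm$background) - 1L
      .forward_bits_cpp(lo$lmatch, lo$lins, lo$ltrans, s)
    }, numeric(1))
  })
  fit <- fit_gumbel(scores)
  hmm$evd <- list(mu = fit$mu, lambda = fit$lambda,
                  n_calibration = as.integer(n_samples))
  hmm
}

# evaluate expr under a temporary RNG state
local_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' E-value of a score or sequence
#'
#' Expected number of hits scoring at least as well in a database of `n_db`
#' sequences under the calibrated Gumbel null.
#'
#' @inheritParams forward_score
#' @param x A bit score (numeric) or a sequence (character, scored with
#'   [forward_score()] first).
#' @param n_db Database size the expectation refers to.
#' @return Positive E-value.
#' @export
evalue <- function(hmm, x, n_db = 1L) {
  stopifnot(inherits(hmm, "profile_hmm"))
  if (is.null(hmm$evd)) {
    abort("model is not calibrated; run calibrate_evd() first",
          class = "krabstrat_calibration_error")
  }
  s <- if (is.character(x)) forward_score(hmm, x) else x
  z <- exp(-hmm$evd$lambda * (s - hmm$evd$mu))
  e <- n_db * (-expm1(-z))
  pmax(e, .Machine$double.xmin)
}
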