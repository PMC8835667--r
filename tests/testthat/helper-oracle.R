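# Independent brute-force oracle for profile-HMM scoring: explicit
# enumeration of every state path (flank prefix, model traversal with all
# M/I/D choices, flank suffix), summing / maximizing the log2-odds directly.
# Written against the model semantics, not the DP recursion.

enumerate_paths <- function(hmm, seq) {
  chars <- strsplit(seq, "")[[1]]
  x <- match(chars, krabstrat:::AA20)
  L <- length(x)
  n <- hmm$n_match
  tr <- hmm$transitions
  m_odds <- hmm$match_emissions / matrix(hmm$background, n, 20, byrow = TRUE)
  i_odds <- hmm$insert_emissions / matrix(hmm$background, n + 1, 20, byrow = TRUE)

  results <- numeric(0)
  # walk(state, j, i, odds): state already entered and emitted; extend
  walk <- function(state, j, i, odds) {
    if (state == "E") {
      results[[length(results) + 1]] <<- odds  # suffix flanks carry odds 1
      return(invisible())
    }
    if (state == "M" || state == "D") {
      # to M_{j+1} or E
      if (j < n) {
        if (i < L) walk("M", j + 1, i + 1,
                        odds * tr[j + 1, paste0(tolower(state), "m")] *
                          m_odds[j + 1, x[i + 1]])
        walk("D", j + 1, i, odds * tr[j + 1, paste0(tolower(state), "d")])
      } else {
        walk("E", j, i, odds * tr[j + 1, paste0(tolower(state), "m")])
      }
      if (state == "M" && i < L) {
        walk("I", j, i + 1, odds * tr[j + 1, "mi"] * i_odds[j + 1, x[i + 1]])
      }
    } else if (state == "I") {
      if (j < n) {
        if (i < L) walk("M", j + 1, i + 1,
                        odds * tr[j + 1, "im"] * m_odds[j + 1, x[i + 1]])
      } else {
        walk("E", j, i, odds * tr[j + 1, "im"])
      }
      if (i < L) walk("I", j, i + 1, odds * tr[j + 1, "ii"] * i_odds[j + 1, x[i + 1]])
    }
  }
  for (f in 0:L) {
    # enter the model after f flank residues (odds 1 each)
    if (f < L) walk("M", 1, f + 1, tr[1, "mm"] * m_odds[1, x[f + 1]])
    walk("D", 1, f, tr[1, "md"])
    if (f < L) walk("I", 0, f + 1, tr[1, "mi"] * i_odds[1, x[f + 1]])
  }
  results
}

oracle_forward_bits <- function(hmm, seq) log2(sum(enumerate_paths(hmm, seq)))
oracle_viterbi_bits <- function(hmm, seq) log2(max(enumerate_paths(hmm, seq)))

# random toy model over the full alphabet (sequences in tests use a reduced
# 4-letter alphabet so the path space stays enumerable)
random_toy_hmm <- function(n_match, seed) {
  set.seed(seed)
  rdir <- function(k) { v <- rgamma(k, 1) + 1e-3; v / sum(v) }
  me <- t(vapply(seq_len(n_match), function(j) rdir(20), numeric(20)))
  ie <- t(vapply(seq_len(n_match + 1), function(j) rdir(20), numeric(20)))
  colnames(me) <- colnames(ie) <- krabstrat:::AA20
  tr <- matrix(0, n_match + 1, 7,
               dimnames = list(NULL, c("mm", "mi", "md", "im", "ii", "dm", "dd")))
  for (j in seq_len(n_match + 1)) {
    last <- j == n_match + 1
    if (last) {
      tr[j, c("mm", "mi")] <- rdir(2)
    } else {
      tr[j, c("mm", "mi", "md")] <- rdir(3)
    }
    tr[j, c("im", "ii")] <- rdir(2)
    tr[j, c("dm", "dd")] <- if (j == 1 || last) c(1, 0) else rdir(2)
  }
  krabstrat:::new_profile_hmm(name = paste0("toy", seed), n_match = n_match,
                              match_emissions = me, insert_emissions = ie,
                              transitions = tr,
                              background = setNames(rep(1 / 20, 20),
                                                    krabstrat:::AA20))
}

# every sequence over the reduced alphabet up to a length
reduced_alphabet_seqs <- function(max_len, letters4 = c("A", "C", "D", "E")) {
  unlist(lapply(seq_len(max_len), function(L) {
    apply(expand.grid(rep(list(letters4), L)), 1, paste, collapse = "")
  }))
}
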