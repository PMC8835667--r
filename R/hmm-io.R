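#' Write / read a profile HMM as versioned text
#'
#' The format is line-oriented and lossless to 6 significant digits:
#' a `KRABSTRAT HMM 1` header, `NAME`/`LENG`/`ALPH` lines, an optional `EVD`
#' line with the Gumbel calibration, the background (`BG`), one `MATCH` and
#' `TRANS` line per state, `INSERT` lines for states 0..n, and `END`.
#' Emissions are validated (and then renormalized to machine precision) on
#' read; malformed input raises a parse error naming the offending line.
#'
#' @param hmm A `profile_hmm`.
#' @param path Output file.
#' @return `write_profile()`: `path`, invisibly. `read_profile()`: a
#'   `profile_hmm`.
#' @export
write_profile <- function(hmm, path) {
  stopifnot(inherits(hmm, "profile_hmm"))
  fmt <- function(x) format(signif(x, 6), scientific = TRUE, digits = 6)
  lines <- c(
    "KRABSTRAT HMM 1",
    paste("NAME", hmm$name),
    paste("LENG", hmm$n_match),
    paste("ALPH", paste(AA20, collapse = "")),
    if (!is.null(hmm$evd)) {
      paste("EVD", fmt(hmm$evd$mu), fmt(hmm$evd$lambda), hmm$evd$n_calibration)
    },
    paste("BG", paste(fmt(hmm$background), collapse = " ")),
    vapply(seq_len(hmm$n_match), function(j) {
      paste("MATCH", j, paste(fmt(hmm$match_emissions[j, ]), collapse = " "))
    }, ""),
    vapply(seq_len(hmm$n_match + 1), function(j) {
      paste("INSERT", j - 1, paste(fmt(hmm$insert_emissions[j, ]), collapse = " "))
    }, ""),
    vapply(seq_len(hmm$n_match + 1), function(j) {
      paste("TRANS", j - 1, paste(fmt(hmm$transitions[j, ]), collapse = " "))
    }, ""),
    "END"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fail <- function(i, msg) {
    abort(sprintf("%s at line %d of '%s'", msg, i, path),
          class = "krabstrat_parse_error")
  }
  if (length(lines) < 1 || !identical(lines[1], "KRABSTRAT HMM 1")) {
    fail(1, "not a KRABSTRAT HMM 1 file")
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  key <- vapply(fields, function(f) if (length(f)) f[1] else "", "")
  grab1 <- function(what) {
    i <- which(key == what)
    if (length(i) != 1) fail(length(lines), paste("missing", what, "line"))
    fields[[i]][-1]
  }
  num_row <- function(i, n_expect) {
    v <- suppressWarnings(as.numeric(fields[[i]][-(1:2)]))
    if (length(v) != n_expect || anyNA(v)) {
      fail(i, sprintf("expected %d numeric values", n_expect))
    }
    v
  }
  name <- paste(grab1("NAME"), collapse = " ")
  n_match <- as.integer(grab1("LENG")[1])
  if (is.na(n_match) || n_match < 1) fail(which(key == "LENG"), "bad LENG value")
  alph <- grab1("ALPH")[1]
  if (!identical(alph, paste(AA20, collapse = ""))) {
    fail(which(key == "ALPH"), "unsupported alphabet")
  }
  bg_i <- which(key == "BG")
  if (length(bg_i) != 1) fail(length(lines), "missing BG line")
  bg <- suppressWarnings(as.numeric(fields[[bg_i]][-1]))
  if (length(bg) != 20 || anyNA(bg)) fail(bg_i, "expected 20 numeric values")
  if (!any(key == "END")) fail(length(lines), "truncated file: missing END")

  read_block <- function(what, n_rows, n_vals, zero_based) {
    idx <- which(key == what)
    if (length(idx) != n_rows) {
      fail(length(lines), sprintf("expected %d %s lines, found %d",
                                  n_rows, what, length(idx)))
    }
    got <- as.integer(vapply(idx, function(i) fields[[i]][2], ""))
    want <- seq_len(n_rows) - as.integer(zero_based)
    if (anyNA(got) || !identical(got, want)) {
      fail(idx[1], sprintf("%s state indices must run %d..%d in order",
                           what, want[1], want[n_rows]))
    }
    t(vapply(idx, num_row, numeric(n_vals), n_expect = n_vals))
  }
  match_em <- read_block("MATCH", n_match, 20, zero_based = FALSE)
  insert_em <- read_block("INSERT", n_match + 1, 20, zero_based = TRUE)
  trans <- read_block("TRANS", n_match + 1, 7, zero_based = TRUE)
  colnames(match_em) <- colnames(insert_em) <- AA20
  colnames(trans) <- c("mm", "mi", "md", "im", "ii", "dm", "dd")

  evd <- NULL
  if (any(key == "EVD")) {
    i <- which(key == "EVD")[1]
    v <- suppressWarnings(as.numeric(fields[[i]][-1]))
    if (length(v) != 3 || anyNA(v)) fail(i, "expected 'EVD mu lambda n'")
    evd <- list(mu = v[1], lambda = v[2], n_calibration = as.integer(v[3]))
  }

  # serialization rounds to 6 significant digits: accept that, then snap
  # rows back to exact normalization
  check_norm <- function(m, what, groups) {
    for (g in groups) {
      s <- rowSums(m[, g, drop = FALSE])
      if (any(abs(s - 1) > 1e-3)) {
        fail(length(lines), sprintf("non-normalized %s row (sum %.4f)",
                                    what, s[which.max(abs(s - 1))]))
      }
    }
    m
  }
  renorm <- function(m, g) {
    m[, g] <- m[, g, drop = FALSE] / rowSums(m[, g, drop = FALSE])
    m
  }
  match_em <- renorm(check_norm(match_em, "MATCH", list(seq_len(20))), seq_len(20))
  insert_em <- renorm(check_norm(insert_em, "INSERT", list(seq_len(20))), seq_len(20))
  trans <- check_norm(trans, "TRANS", list(c("im", "ii")))
  trans <- renorm(trans, c("im", "ii"))
  m_cols <- c("mm", "mi", "md")
  s <- rowSums(trans[, m_cols])
  if (any(abs(s - 1) > 1e-3)) fail(length(lines), "non-normalized TRANS row")
  trans[, m_cols] <- trans[, m_cols] / s
  d_rows <- setdiff(seq_len(n_match + 1), c(1, n_match + 1))
  if (length(d_rows) > 0) {
    sd <- rowSums(trans[d_rows, c("dm", "dd"), drop = FALSE])
    if (any(abs(sd - 1) > 1e-3)) fail(length(lines), "non-normalized TRANS row")
    trans[d_rows, c("dm", "dd")] <- trans[d_rows, c("dm", "dd"), drop = FALSE] / sd
  }
  trans[c(1, n_match + 1), c("dm", "dd")] <- rep(c(1, 0), each = 2)
  bg <- bg / sum(bg)

  new_profile_hmm(name = name, n_match = n_match, match_emissions = match_em,
                  insert_emissions = insert_em, transitions = trans,
                  background = setNames(bg, AA20), evd = evd)
}
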