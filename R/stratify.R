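#' Clamped -log10 transform of E-values
#'
#' E-values at or above the curation floor (default 0.01) are set to the
#' floor before the -log10 transform, so weak and absent hits enter medians
#' and tests uniformly at a score of 2. Reports render clamped minima as
#' `"<2"`.
#'
#' @param evalue Positive E-value(s).
#' @param floor_evalue Clamp floor. Default 0.01.
#' @return A tibble with columns `value` (the -log10 score) and `clamped`.
#' @export
#' @examples
#' clamp_neglog10(c(0.01, 1e-10, 0.5))
clamp_neglog10 <- function(evalue, floor_evalue = 0.01) {
  if (any(evalue <= 0) || anyNA(evalue)) {
    abort("E-values must be positive", class = "krabstrat_stratify_error")
  }
  clamped <- evalue >= floor_evalue
  tibble(value = -log10(ifelse(clamped, floor_evalue, evalue)),
         clamped = clamped)
}

#' Cross-score a catalog against a model panel
#'
#' Scores every catalog entry with every calibrated profile HMM in the
#' panel and returns the long score table: bit score, E-value, and the
#' clamped -log10 score used for stratification.
#'
#' @param catalog A catalog tibble (see [as_catalog()]).
#' @param panel Named list of calibrated `profile_hmm` objects.
#' @param n_db Database size for E-values; defaults to the number of
#'   catalog entries in this scoring run.
#' @param floor_evalue Clamp floor passed to [clamp_neglog10()].
#' @return A `krab_scores` tibble: `id`, `model`, `bit_score`, `evalue`,
#'   `score` (clamped -log10), `clamped`.
#' @export
cross_score <- function(catalog, panel, n_db = nrow(catalog),
                        floor_evalue = 0.01) {
  catalog <- as_catalog(catalog)
  if (length(panel) == 0) {
    abort("empty model panel", class = "krabstrat_stratify_error")
  }
  if (is.null(names(panel)) || any(!nzchar(names(panel)))) {
    names(panel) <- vapply(panel, function(h) h$name, "")
  }
  uncal <- vapply(panel, function(h) is.null(h$evd), TRUE)
  if (any(uncal)) {
    abort(sprintf("model '%s' is not calibrated", names(panel)[uncal][1]),
          class = "krabstrat_calibration_error")
  }
  out <- purrr::map_dfr(names(panel), function(m) {
    hmm <- panel[[m]]
    bits <- vapply(catalog$sequence, function(s) forward_score(hmm, s),
                   numeric(1), USE.NAMES = FALSE)
    tibble(id = catalog$id, model = m, bit_score = bits,
           evalue = evalue(hmm, bits, n_db = n_db))
  })
  cl <- clamp_neglog10(out$evalue, floor_evalue)
  out$score <- cl$value
  out$clamped <- cl$clamped
  class(out) <- c("krab_scores", class(out))
  attr(out, "floor_evalue") <- floor_evalue
  attr(out, "n_db") <- n_db
  out
}

#' Assign each entry to the best-scoring subgroup model
#'
#' The label is the model with the maximal clamped -log10 score; the margin
#' is best minus second best. Strict ties (margin below `1e-12`) and rows
#' where every model is clamped at the floor are labelled `"unknown"` with
#' margin 0.
#'
#' @param scores A `krab_scores` tibble from [cross_score()] (columns `id`,
#'   `model`, `score`, `clamped`).
#' @return Tibble `id`, `label`, `margin`.
#' @export
assign_subgroup <- function(scores) {
  scores %>%
    as_tibble() %>%
    group_by(.data$id) %>%
    summarise(label = {
      ord <- order(-.data$score)
      best <- ord[1]
      second <- if (n() > 1) .data$score[ord[2]] else -Inf
      tie <- n() > 1 && (.data$score[best] - second) < 1e-12
      if (tie || all(.data$clamped)) "unknown" else .data$model[best]
    },
    margin = {
      ord <- order(-.data$score)
      m <- if (n() > 1) .data$score[ord[1]] - .data$score[ord[2]] else 0
      if (m < 1e-12 || all(.data$clamped)) 0 else m
    },
    .groups = "drop")
}

#' Per-group score summaries (medians and ranges)
#'
#' @param scores A `krab_scores` tibble.
#' @param truth Tibble `id`, `group` with one label per entry.
#' @return Tibble `group`, `model`, `n`, `median`, `min`, `max`,
#'   `min_clamped` (whether the minimum sits at the clamp floor, rendered
#'   `"<2"` in reports).
#' @export
summarize_groups <- function(scores, truth) {
  missing_ids <- setdiff(unique(scores$id), truth$id)
  if (length(missing_ids) > 0) {
    abort(sprintf("no truth label for id '%s'", missing_ids[1]),
          class = "krabstrat_stratify_error")
  }
  scores %>%
    as_tibble() %>%
    left_join(truth, by = "id") %>%
    group_by(.data$group, .data$model) %>%
    summarise(n = n(), median = median(.data$score),
              min = min(.data$score), max = max(.data$score),
              min_clamped = any(.data$clamped[.data$score == min(.data$score)]),
              .groups = "drop")
}

#' Render a group summary the way stratification tables print it
#'
#' @param summary Output of [summarize_groups()].
#' @return Tibble with a formatted `display` column, e.g. `"26.50[<2-31.20]"`.
#' @export
format_group_summary <- function(summary) {
  summary %>%
    mutate(display = sprintf("%.2f[%s-%.2f]", .data$median,
                             ifelse(.data$min_clamped, "<2",
                                    sprintf("%.2f", .data$min)),
                             .data$max))
}

#' Two-sided Wilcoxon-Mann-Whitney comparison of two score samples
#'
#' Used on clamped -log10 E-value distributions of two subgroups. Small
#' samples (both sizes at most 8) are handled by exact enumeration of all
#' group assignments of the pooled values (ties included, via midranks);
#' larger samples use the normal approximation with tie correction and
#' continuity correction. Two constant, equal samples give p = 1 by
#' convention.
#'
#' @param values_a,values_b Numeric samples (each at least one value).
#' @param method `"auto"` (the default: exact when both samples are small),
#'   `"exact"`, or `"approximate"`.
#' @return `compare_groups()`: the two-sided p-value. `wmw_test()`: a
#'   `wmw_test` object with `statistic` (U for sample a), `p.value`,
#'   `method`.
#' @export
compare_groups <- function(values_a, values_b) {
  wmw_test(values_a, values_b)$p.value
}

#' @rdname compare_groups
#' @export
wmw_test <- function(values_a, values_b,
                     method = c("auto", "exact", "approximate")) {
  method <- match.arg(method)
  n_a <- length(values_a); n_b <- length(values_b)
  if (n_a < 1 || n_b < 1) {
    abort("each sample needs at least one value", class = "krabstrat_stratify_error")
  }
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2

  exact <- switch(method, auto = max(n_a, n_b) <= 8, exact = TRUE,
                  approximate = FALSE)
  if (exact) {
    combos <- combn(n_a + n_b, n_a)
    dev <- apply(combos, 2, function(sel) {
      abs(sum(r[sel]) - n_a * (n_a + 1) / 2 - mu)
    })
    p <- mean(dev >= abs(u_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    n <- n_a + n_b
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal approximation with tie correction"
  }
  structure(list(statistic = u_obs, p.value = p, method = method,
                 n_a = n_a, n_b = n_b),
            class = "wmw_test")
}

#' @export
print.wmw_test <- function(x, ...) {
  cat(sprintf("Wilcoxon-Mann-Whitney (two-sided, %s)\nU = %g, n = (%d, %d), p = %.4g\n",
              x$method, x$statistic, x$n_a, x$n_b, x$p.value))
  invisible(x)
}

#' @method tidy wmw_test
#' @export
tidy.wmw_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, method = x$method,
         n_a = x$n_a, n_b = x$n_b)
}

#' Pairwise group comparisons of clamped scores
#'
#' For each pair of truth groups, compares the two groups' score
#' distributions under a chosen model (their own models by default is not
#' implied; pass `model`).
#'
#' @param scores A `krab_scores` tibble.
#' @param truth Tibble `id`, `group`.
#' @param model Model column to compare under.
#' @return Tibble `group_a`, `group_b`, `p_value`.
#' @export
compare_all_groups <- function(scores, truth, model) {
  sc <- scores %>%
    as_tibble() %>%
    filter(.data$model == !!model) %>%
    left_join(truth, by = "id")
  groups <- sort(unique(sc$group))
  pairs <- combn(groups, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- sc$score[sc$group == pairs[1, k]]
    b <- sc$score[sc$group == pairs[2, k]]
    tibble(group_a = pairs[1, k], group_b = pairs[2, k], model = model,
           p_value = compare_groups(a, b))
  })
}

#' Curate a catalog by E-value threshold
#'
#' Retains entries scoring E-value strictly below `keep_below` against the
#' given model (the removal boundary is `>=`, so an entry at exactly the
#' threshold is removed). Idempotent. Removed ids and their E-values are
#' recorded in the `"removed"` attribute.
#'
#' @param catalog A catalog tibble.
#' @param hmm A calibrated `profile_hmm`.
#' @param keep_below E-value threshold (0.01 for the permissive pass,
#'   1e-10 for the strict truncation pass).
#' @param n_db Database size for E-values (default: catalog size).
#' @return Filtered catalog with a `"removed"` attribute tibble.
#' @export
curate_filter <- function(catalog, hmm, keep_below = 0.01, n_db = nrow(catalog)) {
  catalog <- as_catalog(catalog)
  if (nrow(catalog) == 0) {
    attr(catalog, "removed") <- tibble(id = character(), evalue = numeric(),
                                       reason = character())
    return(catalog)
  }
  if (is.null(hmm$evd)) {
    abort("model is not calibrated", class = "krabstrat_calibration_error")
  }
  ev <- vapply(catalog$sequence,
               function(s) evalue(hmm, s, n_db = n_db), numeric(1),
               USE.NAMES = FALSE)
  drop <- ev >= keep_below
  removed <- tibble(id = catalog$id[drop], evalue = ev[drop],
                    reason = sprintf("E-value >= %g against '%s'",
                                     keep_below, hmm$name))
  out <- catalog[!drop, ]
  attr(out, "removed") <- removed
  out
}

#' Collapse within-species duplicate sequences
#'
#' Within each species, entries with identical domain sequences collapse to
#' the first occurrence; identical sequences in different species are kept.
#' Merged ids are recorded in the `"merged"` attribute.
#'
#' @param catalog A catalog tibble.
#' @return Deduplicated catalog with a `"merged"` attribute tibble
#'   (`kept_id`, `merged_id`).
#' @export
dedup_within_species <- function(catalog) {
  catalog <- as_catalog(catalog)
  key <- paste(catalog$species, catalog$sequence, sep = "\r")
  first <- !duplicated(key)
  merged <- tibble(
    kept_id = catalog$id[match(key[!first], key)],
    merged_id = catalog$id[!first]
  )
  out <- catalog[first, ]
  attr(out, "merged") <- merged
  out
}
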