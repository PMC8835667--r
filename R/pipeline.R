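#' Default pipeline configuration
#'
#' All tunables of the end-to-end run in one list: generator settings,
#' curation thresholds (permissive 0.01 and strict 1e-10 E-value cutoffs,
#' clamp floor), model-build parameters and seeds. A configuration is fully
#' serialized into the run report, and a report suffices to re-run
#' identically.
#'
#' @param seed Master seed for the run.
#' @param n_per_group,divergence,duplicate_rate Synthetic catalog settings
#'   (see [synthetic_catalog_spec()]).
#' @param occupancy_threshold,pseudocount_weight Model build settings.
#' @param curation_evalue,strict_evalue,floor_evalue Curation thresholds.
#' @param n_calibration Null sequences per model calibration.
#' @return A named list.
#' @export
default_config <- function(seed = 1072, n_per_group = 30, divergence = 0.1,
                           duplicate_rate = 0.1, occupancy_threshold = 0.5,
                           pseudocount_weight = 1, curation_evalue = 0.01,
                           strict_evalue = 1e-10, floor_evalue = 0.01,
                           n_calibration = 300) {
  list(seed = as.integer(seed), n_per_group = n_per_group,
       divergence = divergence, duplicate_rate = duplicate_rate,
       occupancy_threshold = occupancy_threshold,
       pseudocount_weight = pseudocount_weight,
       curation_evalue = curation_evalue, strict_evalue = strict_evalue,
       floor_evalue = floor_evalue, n_calibration = n_calibration)
}

#' Run the stratification pipeline end to end
#'
#' Orchestrates simulate, build, curate (permissive filter, within-species
#' dedup, strict filter), cross-score, assign, summarize, compare, logo and
#' frequency stages on a synthetic catalog, writing TSV stage outputs and a
#' JSON run report (config, seeds, per-stage counts) to `out_dir`.
#'
#' @param config A configuration list, a YAML file path, or a previous run
#'   report path (re-running from a report reproduces the run).
#' @param out_dir Output directory, created if needed.
#' @return The run report, invisibly (a list; also written as JSON).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("krabstrat_run_")) {
  if (is.character(config)) {
    loaded <- yaml::read_yaml(config)
    config <- utils::modifyList(default_config(),
                                loaded$config %||% loaded)
    # YAML 1.1 reads bare scientific notation like 1e-10 as a string
    for (nm in setdiff(names(default_config()), "seed")) {
      config[[nm]] <- as.numeric(config[[nm]])
    }
    config$seed <- as.integer(config$seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "krabstrat_pipeline_error")
    })
  }

  # simulate
  spec <- synthetic_catalog_spec(n_per_group = config$n_per_group,
                                 divergence = config$divergence,
                                 seed = config$seed,
                                 duplicate_rate = config$duplicate_rate)
  sim <- stage("simulate", sample_catalog(spec))
  catalog <- sim$catalog
  write_catalog(catalog, file.path(out_dir, "catalog.tsv"))
  readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"), progress = FALSE)

  # build per-subgroup models plus the pooled curation model
  groups <- setdiff(unique(catalog$subgroup), "unknown")
  panel <- stage("build", {
    p <- purrr::map(groups, function(g) {
      aln <- catalog$alignment[catalog$subgroup == g]
      hmm <- build_profile(aln, occupancy_threshold = config$occupancy_threshold,
                           pseudocount_weight = config$pseudocount_weight,
                           name = g)
      calibrate_evd(hmm, n_samples = config$n_calibration,
                    seed = config$seed + match(g, groups))
    })
    setNames(p, groups)
  })
  overall <- stage("build", {
    hmm <- build_profile(catalog$alignment,
                         occupancy_threshold = config$occupancy_threshold,
                         pseudocount_weight = config$pseudocount_weight,
                         name = "overall")
    calibrate_evd(hmm, n_samples = config$n_calibration, seed = config$seed)
  })
  for (g in groups) {
    write_profile(panel[[g]], file.path(out_dir, paste0("hmm_", g, ".txt")))
  }

  # curate: permissive filter, dedup, strict filter
  curated <- stage("curate", {
    step1 <- curate_filter(catalog, overall, keep_below = config$curation_evalue)
    step2 <- dedup_within_species(step1)
    step3 <- curate_filter(step2, overall, keep_below = config$strict_evalue)
    list(catalog = step3,
         removed_permissive = attr(step1, "removed"),
         merged = attr(step2, "merged"),
         removed_strict = attr(step3, "removed"))
  })
  write_catalog(curated$catalog, file.path(out_dir, "catalog_curated.tsv"))

  # score, assign, summarize, compare
  scores <- stage("score", cross_score(curated$catalog, panel,
                                       floor_evalue = config$floor_evalue))
  readr::write_tsv(as_tibble(scores), file.path(out_dir, "scores.tsv"),
                   progress = FALSE)
  truth <- sim$truth[sim$truth$id %in% curated$catalog$id, ]
  assignments <- stage("assign", assign_subgroup(scores))
  readr::write_tsv(assignments, file.path(out_dir, "assignments.tsv"),
                   progress = FALSE)
  summary_tbl <- stage("summarize",
                       format_group_summary(summarize_groups(scores, truth)))
  readr::write_tsv(summary_tbl, file.path(out_dir, "group_summary.tsv"),
                   progress = FALSE)
  comparisons <- stage("compare", purrr::map_dfr(groups, function(m) {
    compare_all_groups(scores, truth, model = m)
  }))
  readr::write_tsv(comparisons, file.path(out_dir, "group_comparisons.tsv"),
                   progress = FALSE)

  # logos and positional frequencies per subgroup
  frame_cols <- krab_frame()$coord
  logos <- stage("logo", purrr::map(groups, function(g) {
    aln <- curated$catalog$alignment[curated$catalog$subgroup == g]
    kept <- drop_sparse_columns(aln)
    logo_matrix(kept$alignment, columns = frame_cols[kept$kept_columns])
  }))
  for (g in groups) {
    readr::write_tsv(as_tibble(logos[[match(g, groups)]]),
                     file.path(out_dir, paste0("logo_", g, ".tsv")),
                     progress = FALSE)
  }
  queries <- tibble(coord = c("B14", "A32", "A34"), residue = c("E", "M", "E"))
  freq <- stage("freq", position_counts(
    purrr::map(setNames(groups, groups),
               function(g) curated$catalog$alignment[curated$catalog$subgroup == g]),
    queries))
  readr::write_tsv(freq, file.path(out_dir, "position_counts.tsv"),
                   progress = FALSE)

  accuracy <- assignments %>%
    left_join(truth, by = "id") %>%
    summarise(acc = mean(.data$label == .data$group)) %>%
    pull("acc")

  report <- list(
    package = "krabstrat",
    version = as.character(utils::packageVersion("krabstrat")),
    config = config,
    clamp_floor_neglog10 = -log10(config$floor_evalue),
    n_simulated = nrow(catalog),
    n_removed_permissive = nrow(curated$removed_permissive),
    n_merged_duplicates = nrow(curated$merged),
    n_removed_strict = nrow(curated$removed_strict),
    n_final = nrow(curated$catalog),
    assignment_accuracy = accuracy,
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
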