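#' Serialize / restore a cohort specification
#'
#' A `cohort_spec` round-trips through YAML so a run's configuration can
#' be archived next to its outputs and later reproduce the run exactly.
#'
#' @param spec a [cohort_spec()].
#' @param path YAML file path.
#' @export
write_cohort_spec <- function(spec, path) {
  ser <- unclass(spec)
  for (nm in c("completion_time_params", "activation_effects",
               "coupling_effects")) {
    if (!is.null(ser[[nm]])) {
      ser[[nm]] <- lapply(seq_len(nrow(ser[[nm]])),
                          function(i) as.list(ser[[nm]][i, ]))
    }
  }
  ser$design_counts <- as.list(ser$design_counts)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  ser <- yaml::read_yaml(path)
  for (nm in c("completion_time_params", "activation_effects",
               "coupling_effects")) {
    if (!is.null(ser[[nm]])) {
      ser[[nm]] <- dplyr::bind_rows(lapply(ser[[nm]], as_tibble))
    }
  }
  args <- ser[setdiff(names(ser), "design_counts")]
  do.call(cohort_spec, args)
}

process_participant <- function(rec, log, cfg, threshold, base_window,
                                louvain_seed, restarts = 20) {
  hemo <- run_preprocessing(rec, cfg)
  base <- baseline_mean(hemo, base_window)
  trials <- trial_activation(hemo, log, base, phase = "evaluation")
  spliced <- splice_task_segments(hemo, log)
  conn <- correlation_matrix(spliced, threshold = threshold)
  counts <- count_connections(conn)
  metrics <- graph_metrics(conn, seed = louvain_seed, restarts = restarts)
  list(trials = trials, connections = counts, metrics = metrics)
}

#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates preprocessing, trial-wise ROI activation, spliced-task
#' functional connectivity with thresholded connection counts, weighted
#' graph metrics, outlier flagging, and the normality-gated factorial
#' statistics, for every participant of a simulated (or loaded) cohort.
#' Reruns with the same spec are seed-identical.
#'
#' @param cohort a `cohort` from [simulate_cohort()], or a [cohort_spec()]
#'   (which is then simulated).
#' @param cfg a [preprocess_config()].
#' @param threshold spuriousness threshold for connection counts
#'   (default 0.291).
#' @param out_dir optional directory: writes `activation.tsv`,
#'   `network.tsv`, `graph_metrics.tsv`, `stats.tsv`, `behavior.tsv`,
#'   `report.md`, `run_spec.yml` and a `MANIFEST.tsv`.
#' @param louvain_restarts Louvain restarts per participant.
#' @return a `pipeline_run` list of tibbles: `activation` (per
#'   participant x interaction x region), `connections`, `metrics`,
#'   `behavior`, `stats` (one row per family x effect with Bonferroni
#'   adjustment within family), and the spec.
#' @export
run_pipeline <- function(cohort, cfg = preprocess_config(),
                         threshold = 0.291, out_dir = NULL,
                         louvain_restarts = 20) {
  if (inherits(cohort, "cohort_spec")) cohort <- simulate_cohort(cohort, cfg = cfg)
  if (!inherits(cohort, "cohort")) abort("cohort must be a cohort or cohort_spec")
  spec <- cohort$spec
  base_window <- baseline_window(min(60, spec$baseline_s / 3),
                                 spec$baseline_s)
  participants <- cohort$participants
  trials_all <- list(); counts_all <- list(); metrics_all <- list()
  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant_id[i]
    res <- tryCatch(
      process_participant(
        cohort$recordings[[pid]], cohort$logs[[pid]], cfg, threshold,
        base_window, louvain_seed = participant_seed(spec, i) + 3,
        restarts = louvain_restarts
      ),
      error = function(e) {
        abort(sprintf("pipeline failed for participant %s: %s", pid,
                      conditionMessage(e)))
      }
    )
    trials_all[[pid]] <- res$trials
    counts_all[[pid]] <- res$connections
    metrics_all[[pid]] <- res$metrics
  }
  montage <- cohort$recordings[[1L]]$montage
  activation <- roi_activation_table(
    dplyr::bind_rows(trials_all), montage,
    participants = participants[, c("participant_id", "group", "sex")]
  ) |>
    filter_outliers(.data$mean_dHbO, family = c("interaction", "roi"))
  meta <- participants[, c("participant_id", "group", "sex")]
  connections <- dplyr::bind_rows(counts_all) |>
    dplyr::left_join(meta, by = "participant_id")
  metrics <- dplyr::bind_rows(metrics_all) |>
    dplyr::left_join(meta, by = "participant_id")
  stats_tbl <- pipeline_stats(activation, connections, metrics,
                              cohort$behavior)
  run <- structure(
    list(spec = spec, activation = activation, connections = connections,
         metrics = metrics, behavior = cohort$behavior, stats = stats_tbl,
         threshold = threshold),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) write_pipeline_run(run, out_dir)
  run
}

fit_family <- function(data, value_col, family_id) {
  data <- data[!is.na(data[[value_col]]), ]
  cells <- table(data$group, data$sex)
  if (length(cells) < 4L || any(cells < 2L)) return(NULL)
  # a constant measure (e.g. a saturated connection count) carries no
  # group information; skip the family rather than fail the gate
  if (sd(data[[value_col]]) == 0) return(NULL)
  fit <- factorial_analysis(data, !!rlang::sym(value_col), group, sex)
  dplyr::mutate(tidy(fit), family = family_id, .before = 1L)
}

pipeline_stats <- function(activation, connections, metrics, behavior) {
  out <- list()
  act <- activation
  act$mean_dHbO[act$outlier] <- NA_real_
  for (int in sort(unique(act$interaction))) {
    for (roi in sort(unique(act$roi))) {
      d <- act[act$interaction == int & act$roi == roi, ]
      out[[length(out) + 1L]] <-
        fit_family(d, "mean_dHbO", sprintf("activation/%s/%s", int, roi))
    }
  }
  for (m in c("within_motor", "within_frontal", "between")) {
    d <- connections
    d[[m]][filter_outliers(d, .data[[m]], family = character(0))$outlier] <- NA
    out[[length(out) + 1L]] <- fit_family(d, m, paste0("connections/", m))
  }
  for (m in c("global_efficiency", "local_efficiency",
              "clustering_coefficient", "modularity")) {
    d <- metrics
    d[[m]][filter_outliers(d, .data[[m]], family = character(0))$outlier] <- NA
    out[[length(out) + 1L]] <- fit_family(d, m, paste0("graph/", m))
  }
  for (int in sort(unique(behavior$interaction))) {
    d <- behavior[behavior$interaction == int, ]
    out[[length(out) + 1L]] <-
      fit_family(d, "completion_time_s", paste0("performance/", int))
  }
  tbl <- dplyr::bind_rows(out)
  if (!nrow(tbl)) return(tbl)
  # Bonferroni within each family group (the measure class x interaction)
  tbl$family_group <- sub("/[^/]*$", "", tbl$family)
  tbl |>
    dplyr::group_by(.data$family_group, .data$effect) |>
    dplyr::mutate(p_adj = bonferroni(.data$p, m = dplyr::n())) |>
    dplyr::ungroup()
}

write_pipeline_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    utils::write.table(as.data.frame(x), file.path(out_dir, name),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    name
  }
  files <- c(
    tsv(run$activation, "activation.tsv"),
    tsv(run$connections, "network.tsv"),
    tsv(run$metrics, "graph_metrics.tsv"),
    tsv(run$behavior, "behavior.tsv"),
    tsv(run$stats, "stats.tsv")
  )
  write_cohort_spec(run$spec, file.path(out_dir, "run_spec.yml"))
  writeLines(report_markdown(run), file.path(out_dir, "report.md"))
  files <- c(files, "run_spec.yml", "report.md")
  utils::write.table(tibble(file = files, seed = run$spec$seed),
                     file.path(out_dir, "MANIFEST.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' Markdown summary report of a pipeline run
#'
#' Group x sex summaries of performance, activation, connection counts
#' and graph metrics, plus the effect table with families flagged when
#' they survive Bonferroni adjustment. Regeneration is idempotent: the
#' same run yields the same text.
#'
#' @param run a `pipeline_run` (or a run directory containing
#'   `stats.tsv` etc., for which a partial report is assembled).
#' @return character vector of markdown lines.
#' @export
report_markdown <- function(run) {
  if (is.character(run)) run <- read_pipeline_run(run)
  lines <- c("# Pipeline run report", "")
  if (is.null(run$activation) || !nrow(run$activation %||% tibble())) {
    return(c(lines, "**Warning:** run is empty or incomplete; no outputs available."))
  }
  have_stats <- !is.null(run$stats) && nrow(run$stats %||% tibble()) > 0
  fmt <- function(x) formatC(x, digits = 3, format = "fg")
  lines <- c(lines, sprintf("Participants: %d | spuriousness threshold |r| = %s",
                            length(unique(run$activation$participant_id)),
                            fmt(run$threshold)), "")
  lines <- c(lines, "## Performance (evaluation completion time, s)", "",
             "| interaction | group | mean | sd |", "|---|---|---|---|")
  perf <- run$behavior |>
    dplyr::group_by(.data$interaction, .data$group) |>
    dplyr::summarise(mean = mean(.data$completion_time_s),
                     sd = sd(.data$completion_time_s), .groups = "drop")
  lines <- c(lines, sprintf("| %s | %s | %s | %s |", perf$interaction,
                            perf$group, fmt(perf$mean), fmt(perf$sd)))
  lines <- c(lines, "", "## Activation coverage", "",
             sprintf("Regions: %d | Interactions: %d | flagged outliers: %d",
                     length(unique(run$activation$roi)),
                     length(unique(run$activation$interaction)),
                     sum(run$activation$outlier)), "")
  lines <- c(lines, "## Graph metrics by group x sex", "",
             "| group | sex | E_glob | E_loc | C | Q |", "|---|---|---|---|---|---|")
  gm <- run$metrics |>
    dplyr::group_by(.data$group, .data$sex) |>
    dplyr::summarise(dplyr::across(c("global_efficiency", "local_efficiency",
                                     "clustering_coefficient", "modularity"),
                                   mean), .groups = "drop")
  lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s |", gm$group, gm$sex,
                            fmt(gm$global_efficiency), fmt(gm$local_efficiency),
                            fmt(gm$clustering_coefficient), fmt(gm$modularity)))
  lines <- c(lines, "", "## Effects significant after Bonferroni adjustment", "")
  if (!have_stats) {
    return(c(lines,
             "**Warning:** no group statistics (cohort too small for the factorial design)."))
  }
  sig <- run$stats[run$stats$p_adj < 0.05, ]
  if (nrow(sig)) {
    lines <- c(lines, sprintf(
      "- %s: %s F(%d, %d) = %s, p_adj = %s%s", sig$family, sig$effect,
      sig$df_num, sig$df_den, fmt(sig$F), fmt(sig$p_adj),
      ifelse(sig$method == "art", " (aligned-rank branch)", "")
    ))
  } else {
    lines <- c(lines, "- none")
  }
  lines
}

read_pipeline_run <- function(dir) {
  rd <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) as_tibble(read.csv(p, sep = "\t")) else NULL
  }
  structure(
    list(
      activation = rd("activation.tsv"), connections = rd("network.tsv"),
      metrics = rd("graph_metrics.tsv"), behavior = rd("behavior.tsv"),
      stats = rd("stats.tsv"),
      threshold = {
        n <- rd("network.tsv")
        if (!is.null(n) && "threshold" %in% names(n)) n$threshold[1L] else NA_real_
      }
    ),
    class = "pipeline_run"
  )
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf(
    "<pipeline_run> %d participants; %d activation rows; %d stats families\n",
    length(unique(x$activation$participant_id)), nrow(x$activation),
    length(unique(x$stats$family))
  ))
  invisible(x)
}
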