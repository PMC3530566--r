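#' Default run configuration
#'
#' Assembles the full set of pipeline parameters with spec'd defaults: 1-h
#' slots, 6-slot padding bound, 30% day exclusion, 1% location lumping,
#' 30-day user acceptance, both clustering methods, matching guess rule,
#' 12-slot lag horizon and the default workday thresholds.
#'
#' @param ... overrides for any field (see source for names).
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    trace_file = NULL,                 # CSV of raw events, or NULL
    generator = list(),                # generator_config() overrides
    tz = "UTC",
    slot_minutes = 60L,
    max_gap_slots = 6L,
    max_missing_fraction = 0.30,
    min_days = 30L,
    significance_fraction = 0.01,
    clustering = "both",               # "eo", "kmeans", "both"
    delta = NULL,                      # day-graph scale; NULL = n_slots/4
    tau = 1.4,
    k = NULL,                          # k-means k; NULL = EO-emergent count
    n_runs = 200L,
    rule = "matching",                 # or "mode"
    dt_max = 12L,
    daytime_hours = c(9, 17),
    min_workdays = 20L,
    min_consecutive = 4L,
    min_pooled_lengths = 100L,
    seed = 1L,
    out_dir = NULL)
  over <- list(...)
  .assert(all(names(over) %in% names(cfg)),
          paste("unknown config fields:",
                paste(setdiff(names(over), names(cfg)), collapse = ", ")))
  utils::modifyList(cfg, over, keep.null = TRUE)
}

#' Read a run configuration from YAML or JSON
#' @param path config file (`.yaml`/`.yml` needs the yaml package).
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    .assert(requireNamespace("yaml", quietly = TRUE),
            "yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, lst)
}

.stage_log <- function(stage, t0, quiet) {
  if (!quiet)
    message(sprintf("[lifepatterns] %-10s %6.2fs", stage,
                    as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> ingest -> location stats -> clustering -> entropy
#' -> predictability -> workday model, returning one consolidated report and
#' (optionally) writing all per-module outputs under `config$out_dir`.
#'
#' @param config a [run_config()] list, or a path readable by
#'   [read_run_config()].
#' @param quiet suppress stage-timing log messages.
#' @return a `pipeline_report` list: `users` (per-user results), `pooled`
#'   (rank-frequency curve, power-law fit, entropy medians, departure fit),
#'   `config` echo, `exclusions`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  set.seed(config$seed)
  t0 <- as.numeric(Sys.time())
  truth <- NULL
  if (!is.null(config$trace_file)) {
    events <- read_traces(config$trace_file, tz = config$tz)
  } else {
    gen <- do.call(generator_config,
                   utils::modifyList(list(seed = config$seed,
                                          slot_minutes = config$slot_minutes),
                                     config$generator, keep.null = TRUE))
    panel_sim <- generate_panel(gen)
    events <- panel_sim$events
    truth <- panel_sim$truth
  }
  .stage_log("simulate", t0, quiet); t0 <- as.numeric(Sys.time())

  ing <- ingest_traces(events, slot_minutes = config$slot_minutes,
                       max_gap_slots = config$max_gap_slots,
                       max_missing_fraction = config$max_missing_fraction,
                       min_days = config$min_days, tz = config$tz)
  panel <- ing$panel
  .assert(length(panel) > 0, "pipeline aborted at ingest: no accepted users")
  .stage_log("ingest", t0, quiet); t0 <- as.numeric(Sys.time())

  users <- list()
  workday_tables <- list()
  do_eo <- config$clustering %in% c("eo", "both")
  do_km <- config$clustering %in% c("kmeans", "both")
  for (ui in seq_along(panel)) {
    uid <- names(panel)[ui]
    mat <- panel[[uid]]
    lf <- location_frequencies(mat, config$significance_fraction)
    th <- threshold_locations(mat, lf)
    days <- day_matrix(th$days, uid, rownames(mat), config$slot_minutes)
    assignments <- list()
    if (do_eo) {
      g <- build_day_graph(days, delta = config$delta)
      assignments$eo <- eo_modularity(g, tau = config$tau,
                                      seed = config$seed + 1000L + ui)
    }
    if (do_km) {
      kk <- config$k %||% if (do_eo) assignments$eo$k else 2L
      assignments$kmeans <- kmeans_days(days, k = min(kk, nrow(days)),
                                        n_runs = config$n_runs,
                                        seed = config$seed + 2000L + ui)
    }
    primary <- assignments[[1]]
    ent <- entropy_report(days, assignments, alphabet = lf)
    profile <- cluster_profile(primary, days, alphabet = lf)
    q <- list(
      static_plain = static_quality(days, NULL, config$rule)$overall,
      static_patterns = static_quality(days, primary, config$rule)$overall,
      transition_plain = transition_quality(
        fit_transition_model(days, 1L), days, config$rule)$overall,
      transition_patterns = transition_quality(
        fit_transition_model(days, 1L, primary), days, config$rule)$overall)
    curve <- long_range_curve(days, dt_max = config$dt_max,
                              assignment = primary, rule = config$rule)
    wl <- find_work_location(days, config$daytime_hours,
                             min_workdays = config$min_workdays,
                             min_consecutive = config$min_consecutive)
    wt <- if (!is.null(wl$work))
      day_lengths(days, wl$work, min_run = config$min_consecutive) else NULL
    if (!is.null(wt) && wl$qualified) workday_tables[[uid]] <- wt
    users[[uid]] <- list(
      user_id = uid, n_days = nrow(days),
      n_significant_locations = sum(lf$significant),
      alphabet = lf, entropy = ent,
      n_patterns = primary$k,
      slot_location_counts = slot_location_counts(days),
      quality = q, q_dt = curve,
      rank_enrichment = profile$rank_enrichment,
      assignments = lapply(assignments, function(a)
        a[c("labels", "k", "sizes", "method", "modularity", "objective")]),
      workday = wl)
  }
  .stage_log("analyse", t0, quiet); t0 <- as.numeric(Sys.time())

  pooled_curve <- pooled_rank_frequency(panel)
  per_counts <- lapply(panel, function(m) {
    f <- location_frequencies(m)
    cnt <- numeric(max(f$rank))
    cnt[f$rank] <- f$count
    cnt
  })
  rmax <- max(lengths(per_counts))
  pooled_counts <- Reduce(`+`, lapply(per_counts, function(cnt) {
    length(cnt) <- rmax
    cnt[is.na(cnt)] <- 0
    cnt
  }))
  pl_fit <- tryCatch(fit_power_law(pooled_counts), error = function(e) NULL)
  ents <- do.call(rbind, lapply(users, `[[`, "entropy"))
  dists <- if (length(users) >= 2)
    entropy_distributions(ents)["medians"] else NULL
  pooled_len <- pool_day_lengths(workday_tables, config$min_workdays)
  dep_fit <- NULL
  if (nrow(pooled_len) >= config$min_pooled_lengths) {
    step_z <- 1 / mean(vapply(workday_tables, function(t)
      stats::sd(t$length), numeric(1)), na.rm = TRUE)
    dep_fit <- tryCatch(
      fit_departure_model(pooled_len$z, step = step_z,
                          min_n = config$min_pooled_lengths),
      error = function(e) {
        if (!quiet) message("[lifepatterns] departure fit failed: ",
                            conditionMessage(e))
        NULL
      })
  }
  .stage_log("pooled", t0, quiet)

  report <- list(users = users,
                 pooled = list(rank_frequency = pooled_curve,
                               power_law = pl_fit,
                               entropy_medians = dists$medians,
                               n_pooled_lengths = nrow(pooled_len),
                               pooled_lengths = pooled_len,
                               departure_fit = dep_fit),
                 exclusions = ing$exclusions,
                 truth_available = !is.null(truth),
                 config = config[setdiff(names(config), "out_dir")])
  if (!is.null(truth)) attr(report, "truth") <- truth
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write the consolidated report and per-module outputs
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  slim <- report
  attr(slim, "truth") <- NULL
  slim$users <- lapply(slim$users, function(u) {
    u$alphabet <- NULL
    u
  })
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  tabs <- render_fig_tables(report, out_dir)
  invisible(c(path, tabs))
}

#' Tabular analogues of the headline figures
#'
#' Writes CSV/JSON tables: the pooled rank-frequency curve (locations
#' figure), the per-user pattern/entropy table plus entropy medians
#' (entropy figure), per-slot and per-lag prediction-quality tables
#' (predictability figure), and the scaled working-day-length histogram with
#' the fitted density (departure figure). Missing report sections are
#' skipped with a warning.
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory.
#' @return character vector of written paths.
#' @export
render_fig_tables <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$pooled$rank_frequency))
    w(report$pooled$rank_frequency, "fig_locations_rank_frequency.csv")
  else warning("no rank-frequency section")
  ents <- do.call(rbind, lapply(report$users, `[[`, "entropy"))
  if (!is.null(ents)) {
    rownames(ents) <- NULL
    w(ents, "fig_entropy_users.csv")
  } else warning("no entropy section")
  qs <- do.call(rbind, lapply(report$users, function(u)
    data.frame(user_id = u$user_id, as.data.frame(u$quality))))
  if (!is.null(qs)) w(qs, "fig_prediction_quality.csv")
  qdt <- do.call(rbind, lapply(report$users, function(u)
    cbind(user_id = u$user_id, u$q_dt$curve)))
  if (!is.null(qdt)) w(qdt, "fig_prediction_qdt.csv")
  if (!is.null(report$pooled$departure_fit)) {
    fit <- report$pooled$departure_fit
    pdf <- departure_pdf(fit, fit$grid)
    z <- report$pooled$pooled_lengths$z
    br <- c(fit$grid - fit$step / 2, max(fit$grid) + fit$step / 2)
    hist_df <- data.frame(t = fit$grid,
                          density = graphics::hist(
                            pmin(pmax(z, min(br)), max(br)),
                            breaks = br, plot = FALSE)$density * fit$step,
                          fitted_pdf = pdf$pdf)
    w(hist_df, "fig_departure_lengths.csv")
  } else warning("no departure-fit section")
  paths
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d users\n", length(x$users)))
  for (u in x$users)
    cat(sprintf("  %s: %d days, %d locations, %d patterns, S=%.2f->%.2f\n",
                u$user_id, u$n_days, u$n_significant_locations, u$n_patterns,
                u$entropy$S_bare[1], u$entropy$S_clustered[1]))
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic trace + ground truth),
#' `run-all` (full pipeline), and the stage aliases `ingest`, `stats`,
#' `cluster`, `entropy`, `predict`, `workday`, `render` (all run the
#' pipeline and write outputs; they differ only in what they print).
#' Typical use from `inst/cli/lifepatterns.R`:
#' `Rscript lifepatterns.R run-all --config cfg.yaml --out outdir`.
#'
#' @param args character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return exit status 0 on success (invisibly); stage failures raise errors.
#' @export
lifepatterns_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  .assert(requireNamespace("optparse", quietly = TRUE),
          "optparse package required for the CLI")
  .assert(length(args) >= 1, paste(
    "usage: lifepatterns.R <simulate|run-all|ingest|stats|cluster|entropy|",
    "predict|workday|render> [options]"))
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--slot-minutes", type = "integer", default = 60L,
                          dest = "slot_minutes"),
    optparse::make_option("--clustering", type = "character",
                          default = "both"),
    optparse::make_option("--rule", type = "character", default = "matching"),
    optparse::make_option("--traces", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = "lp_out")))
  opt <- optparse::parse_args(parser, args = args[-1])
  cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else
    run_config()
  cfg$seed <- opt$seed
  cfg$slot_minutes <- opt$slot_minutes
  cfg$clustering <- opt$clustering
  cfg$rule <- opt$rule
  if (!is.null(opt$traces)) cfg$trace_file <- opt$traces
  cfg$out_dir <- opt$out
  message(sprintf("[lifepatterns] %s seed=%d out=%s", cmd, cfg$seed, opt$out))
  if (cmd == "simulate") {
    gen <- do.call(generator_config,
                   utils::modifyList(list(seed = cfg$seed,
                                          slot_minutes = cfg$slot_minutes),
                                     cfg$generator, keep.null = TRUE))
    sim <- generate_panel(gen)
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    write_traces(sim$events, file.path(opt$out, "traces.csv"))
    write_ground_truth(sim$truth, file.path(opt$out, "ground_truth.json"))
  } else if (cmd %in% c("run-all", "ingest", "stats", "cluster", "entropy",
                        "predict", "workday", "render")) {
    report <- run_pipeline(cfg)
    print(report)
  } else stop("unknown subcommand: ", cmd)
  invisible(0L)
}
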