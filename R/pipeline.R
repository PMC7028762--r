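#' Validate a pipeline run configuration
#'
#' Fail-fast validation of everything \code{\link{run_pipeline}} needs:
#' input sources (either a synthetic \code{\link{cohort_spec}} / spec YAML,
#' or the three input CSVs), coefficient files, bootstrap size,
#' willingness-to-pay grid and output directory. All file paths must
#' resolve at validation time, before any computation.
#'
#' @param output_dir Directory for all outputs.
#' @param cohort A \code{\link{cohort_spec}}, or path to a spec YAML;
#'   mutually exclusive with \code{clients_csv}/\code{utilization_csv}/
#'   \code{sf12_csv}.
#' @param clients_csv,utilization_csv,sf12_csv Input CSVs with the layouts
#'   written by \code{\link{write_cohort}}.
#' @param unit_cost_csv,tariff_csv,weights_csv Coefficient files;
#'   \code{NULL} uses the shipped defaults.
#' @param B Bootstrap replicates (>= 1).
#' @param seed Master seed for simulation and bootstrap.
#' @param lambda Willingness-to-pay grid, EUR per QALY.
#' @param fee_per_client Counseling fee, EUR.
#' @return Validated list of class \code{"run_config"}.
#' @export
run_config <- function(output_dir, cohort = NULL, clients_csv = NULL,
                       utilization_csv = NULL, sf12_csv = NULL,
                       unit_cost_csv = NULL, tariff_csv = NULL,
                       weights_csv = NULL, B = 1000, seed = 1L,
                       lambda = seq(0, 100000, by = 1000),
                       fee_per_client = 100) {
  if (is.character(cohort)) {
    if (!file.exists(cohort)) stop_("cohort spec file not found: %s", cohort)
    cohort <- read_cohort_spec(cohort)
  }
  csvs <- list(clients_csv = clients_csv, utilization_csv = utilization_csv,
               sf12_csv = sf12_csv)
  have_csv <- !vapply(csvs, is.null, TRUE)
  if (is.null(cohort) && !all(have_csv))
    stop_("provide either 'cohort' or all three input CSVs")
  if (!is.null(cohort) && any(have_csv))
    stop_("'cohort' and input CSVs are mutually exclusive")
  if (!is.null(cohort) && !inherits(cohort, "cohort_spec"))
    stop_("'cohort' must be a cohort_spec or a spec YAML path")
  for (nm in names(csvs))
    if (!is.null(csvs[[nm]]) && !file.exists(csvs[[nm]]))
      stop_("'%s' not found: %s", nm, csvs[[nm]])
  for (nm in c("unit_cost_csv", "tariff_csv", "weights_csv")) {
    p <- get(nm)
    if (!is.null(p) && !file.exists(p))
      stop_("'%s' not found: %s", nm, p)
  }
  check_number(B, "B", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (length(lambda) == 0L || any(lambda < 0))
    stop_("'lambda' must be a nonempty grid of nonnegative thresholds")
  check_number(fee_per_client, "fee_per_client", lower = 0)
  structure(list(output_dir = output_dir, cohort = cohort,
                 clients_csv = clients_csv,
                 utilization_csv = utilization_csv, sf12_csv = sf12_csv,
                 unit_cost_csv = unit_cost_csv, tariff_csv = tariff_csv,
                 weights_csv = weights_csv, B = as.integer(B),
                 seed = as.integer(seed), lambda = lambda,
                 fee_per_client = fee_per_client),
            class = "run_config")
}

# carry scores forward over visits within client (complete-case visits)
locf_fill <- function(df, cols) {
  df <- df[order(df$client_id, df$visit), , drop = FALSE]
  for (cid in unique(df$client_id)) {
    i <- which(df$client_id == cid)
    for (cl in cols) {
      v <- df[[cl]][i]
      for (k in seq_along(v)[-1]) if (is.na(v[k])) v[k] <- v[k - 1]
      df[[cl]][i] <- v
    }
  }
  df
}

#' Run the full pre-post cost-effectiveness pipeline
#'
#' Executes simulate (or load) -> cost -> quality of life -> QALY ->
#' cost-effectiveness, and writes the report bundle: the cohort tables
#' (when simulated), the per-user/per-client/total cost summary, a
#' visit-level quality-of-life summary (PCS, MCS, utility; LOCF-completed),
#' the per-client QALY table, the bootstrap plane and acceptability-curve
#' data, a JSON cost-effectiveness summary, and a deterministic run log
#' with the seed, package version, config hash and coefficient-file
#' checksums. Identical config and seed yield byte-identical outputs.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list with the fitted \code{\link{cea}} object, the
#'   \code{cost_summary}, the QALY table, the QoL summary and all output
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop_("'config' must be a run_config (validated before running)")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message("[prepostCEA] ", line)
    log_lines <<- c(log_lines, line)
  }

  uc <- unit_cost_table(config$unit_cost_csv)
  tariff <- sf6d_tariff(config$tariff_csv)
  weights <- sf12_weights(config$weights_csv)

  paths <- character()
  if (!is.null(config$cohort)) {
    sim <- simulate_cohort(config$cohort, seed = config$seed)
    clients <- sim$clients
    utilization <- sim$utilization
    sf12 <- sim$sf12
    paths <- c(paths, write_cohort(sim, config$output_dir))
    say("simulate: %d clients, %d utilization records, %d SF-12 responses",
        nrow(clients), nrow(utilization), nrow(sf12))
  } else {
    clients <- utils::read.csv(config$clients_csv, stringsAsFactors = FALSE)
    utilization <- utils::read.csv(config$utilization_csv,
                                   stringsAsFactors = FALSE)
    sf12 <- utils::read.csv(config$sf12_csv, stringsAsFactors = FALSE)
    say("load: %d clients, %d utilization records, %d SF-12 responses",
        nrow(clients), nrow(utilization), nrow(sf12))
  }
  check_columns(clients, c("client_id", "last_observed_visit"), "clients")

  # --- costs ---
  exp0 <- cost_records(utilization, uc)
  exp1 <- impute_cost_locf(exp0, clients)
  exp2 <- add_counseling_fee(exp1, clients, config$fee_per_client)
  cs <- aggregate_costs(exp2, clients)
  ctc <- client_total_costs(exp2, clients)
  say("cost: total pre %.0f EUR, post %.0f EUR (%d imputed rows)",
      sum(ctc$cost_pre), sum(ctc$cost_post), sum(exp2$imputed))
  p_cost <- file.path(config$output_dir, "cost_summary.csv")
  write_cost_summary(cs, p_cost)
  paths <- c(paths, cost_summary = p_cost)

  # --- quality of life ---
  scores <- score_sf12(sf12, weights)
  grid <- expand.grid(client_id = unique(clients$client_id), visit = 0:3,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- merge(grid, scores, by = c("client_id", "visit"), all.x = TRUE)
  scores <- locf_fill(scores, c("pcs", "mcs"))
  traj <- utility_trajectories(sf12, tariff)
  traj <- impute_qol_locf(traj)
  qs <- do.call(rbind, lapply(0:3, function(v) {
    p <- mean_ci95(scores$pcs[scores$visit == v])
    m <- mean_ci95(scores$mcs[scores$visit == v])
    u <- mean_ci95(traj$utility[traj$visit == v])
    data.frame(visit = v, pcs = p[["mean"]], pcs_lo = p[["lo"]],
               pcs_hi = p[["hi"]], mcs = m[["mean"]], mcs_lo = m[["lo"]],
               mcs_hi = m[["hi"]], utility = u[["mean"]],
               utility_lo = u[["lo"]], utility_hi = u[["hi"]],
               n_imputed = sum(traj$imputed[traj$visit == v]))
  }))
  say("qol: mean utility %.4f (baseline) -> %.4f (12 months)",
      qs$utility[1], qs$utility[4])
  p_qol <- file.path(config$output_dir, "qol_summary.csv")
  utils::write.csv(qs, p_qol, row.names = FALSE)
  paths <- c(paths, qol_summary = p_qol)

  # --- QALYs ---
  qp <- qaly_pairs(traj)
  say("qaly: mean pre %.4f, post %.4f, delta %.4f",
      attr(qp, "means")[["qaly_pre"]], attr(qp, "means")[["qaly_post"]],
      attr(qp, "means")[["delta"]])
  p_qaly <- file.path(config$output_dir, "qaly.csv")
  utils::write.csv(qp, p_qaly, row.names = FALSE)
  paths <- c(paths, qaly = p_qaly)

  # --- cost-effectiveness ---
  deltas <- client_deltas(ctc, qp)
  fit <- cea(deltas, B = config$B, lambda = config$lambda,
             seed = config$seed)
  say("cea: mean delta cost %.0f EUR, delta QALY %.4f, quadrant %s",
      fit$delta_cost, fit$delta_qaly, fit$quadrant)
  paths <- c(paths, write_ce_outputs(fit, config$output_dir))

  # --- run log (deterministic: no wall-clock content) ---
  cfg_hash <- object_md5(list(
    B = config$B, seed = config$seed, lambda = config$lambda,
    fee = config$fee_per_client,
    cohort = if (is.null(config$cohort)) NULL else unclass(config$cohort)))
  log_head <- c(
    sprintf("prepostCEA %s",
            as.character(utils::packageVersion("prepostCEA"))),
    sprintf("seed: %d", config$seed),
    sprintf("config_hash: %s", cfg_hash),
    sprintf("unit_costs_md5: %s", file_md5(attr(uc, "path") %||%
              (config$unit_cost_csv %||%
                 system.file("extdata", "unit_costs_default.csv",
                             package = "prepostCEA")))),
    sprintf("tariff_md5: %s", tariff$checksum),
    sprintf("sf12_weights_md5: %s", weights$checksum))
  p_log <- file.path(config$output_dir, "run_log.txt")
  writeLines(c(log_head, log_lines), p_log)
  paths <- c(paths, log = p_log)

  invisible(list(cea = fit, cost_summary = cs, qaly = qp,
                 qol_summary = qs, deltas = deltas, paths = paths))
}
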