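#' The pre-registered simulation condition matrix
#'
#' Enumerates the standard study conditions: every combination of release
#' mode (constant or decaying efflux), calsequestrin (on/off) and SERCA
#' (on/off), each over the short (20 ms) and long (2 s) windows -- 16 runs.
#'
#' @param windows window durations in s (default `c(0.02, 2)`).
#' @return A data frame with one row per condition: `name`, `duration`,
#'   `efflux_mode`, `casq`, `serca`.
#' @export
condition_matrix <- function(windows = c(0.02, 2)) {
  g <- expand.grid(serca = c(FALSE, TRUE), casq = c(FALSE, TRUE),
                   efflux_mode = c("constant", "decaying"),
                   duration = windows, stringsAsFactors = FALSE)
  g$name <- sprintf("%s_casq-%s_serca-%s_%gms", g$efflux_mode,
                    ifelse(g$casq, "on", "off"),
                    ifelse(g$serca, "on", "off"), g$duration * 1000)
  g[, c("name", "duration", "efflux_mode", "casq", "serca")]
}

#' Run the condition matrix and export observables
#'
#' Runs [sr_simulate()] for every row of a condition matrix, writes the
#' per-condition exports (time series of efflux and end-face free Ca2+;
#' axial free and total position-by-time matrices) as comment-headed CSV
#' files, and collects the headline statistics into a top-level
#' `summary.csv`. A failing condition is reported and skipped; the others
#' continue.
#'
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output and only the summary is returned.
#' @param matrix a data frame as from [condition_matrix()].
#' @param params an [sr_parameters()] object.
#' @param spacing 1D grid spacing, m.
#' @param n_output_points output samples per run.
#' @param quiet suppress progress messages.
#' @return The summary data frame (one row per completed condition),
#'   invisibly when writing files.
#' @export
run_condition_matrix <- function(out_dir = NULL,
                                 matrix = condition_matrix(),
                                 params = sr_parameters(),
                                 spacing = 1e-8,
                                 n_output_points = 1000L,
                                 quiet = FALSE) {
  if (!is.null(out_dir) && !dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  rows <- vector("list", nrow(matrix))
  for (i in seq_len(nrow(matrix))) {
    cond <- matrix[i, ]
    res <- tryCatch({
      cfg <- simulation_config(duration = cond$duration,
                               n_output_points = n_output_points,
                               efflux_mode = cond$efflux_mode,
                               serca_enabled = cond$serca,
                               casq_enabled = cond$casq,
                               spacing = spacing)
      sim <- sr_simulate(cfg, params = params)
      if (!is.null(out_dir))
        .export_condition(sim, file.path(out_dir, cond$name))
      s <- condition_summary(sim)
      s$name <- cond$name
      s$mass_balance_rel_err <- mass_balance_error(sim)
      s
    }, error = function(e) {
      warning("condition '", cond$name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!quiet && !is.null(res))
      message(sprintf(
        "%-36s efflux decline %8.4f%%  CSR free decline %8.4f%%  LSR-CSR %7.3f uM",
        cond$name, res$efflux_decline_pct, res$csr_free_decline_pct,
        res$lsr_csr_diff_uM))
    rows[[i]] <- res
  }
  summary <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  summary <- summary[, c("name", setdiff(names(summary), "name"))]
  if (!is.null(out_dir)) {
    .write_commented_csv(summary, file.path(out_dir, "summary.csv"),
                         params)
    invisible(summary)
  } else summary
}

.export_condition <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create condition directory: ", dir)
  fr <- free_field(sim$field)
  nzn <- ncol(fr)
  ts <- data.frame(time = sim$fluxes$time,
                   efflux_density = sim$fluxes$efflux_density,
                   csr_free = fr[, 1L], lsr_free = fr[, nzn],
                   diff_uM = (fr[, nzn] - fr[, 1L]) * 1000)
  .write_commented_csv(ts, file.path(dir, "timeseries.csv"), sim$params)
  for (q in c("free", "total")) {
    m <- colormap_matrix(sim$field, "axial", q)
    df <- data.frame(position = as.numeric(rownames(m)), m,
                     check.names = FALSE)
    .write_commented_csv(df, file.path(dir, paste0("axial_", q, ".csv")),
                         sim$params)
  }
  prov <- c(
    sprintf("# condition: efflux=%s casq=%s serca=%s duration=%g s",
            sim$efflux$mode, sim$config$casq_enabled,
            sim$config$serca_enabled, sim$config$duration),
    sprintf("# grid: %s, %d nodes", sim$grid$mode,
            if (sim$grid$mode == "axial_1d") sim$grid$n_nodes
            else sim$grid$n_r * sim$grid$n_z),
    sprintf("# tolerances: rtol=%g atol=%g", sim$config$rel_tol,
            sim$config$abs_tol),
    sprintf("# mass balance rel err: %.3g", mass_balance_error(sim)))
  writeLines(prov, file.path(dir, "provenance.txt"))
}

.write_commented_csv <- function(df, path, params) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# srlumen export",
               sprintf("# parameters: %s",
                       paste(sprintf("%s=%g", .display_units$symbol,
                                     vapply(.display_units$field,
                                            function(f) params[[f]],
                                            numeric(1))),
                             collapse = " "))), con)
  utils::write.csv(df, con, row.names = FALSE)
}
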