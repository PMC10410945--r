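#' Run the full reporting pipeline for a scenario
#'
#' Ties the stages together: deterministic evaluation, one-way
#' deterministic sensitivity analysis, probabilistic sensitivity analysis
#' with the acceptability curve, written as CSV tables (plus optional
#' ggplot figures regenerable from the CSVs alone) and a JSON run manifest
#' recording the seed and every convention flag that affects a number.
#' Output is idempotent given the seed; if any stage fails, files written
#' by this run are removed and the error is re-thrown with a stage label.
#'
#' @param scenario A [cea_scenario()] or the path of a YAML scenario file.
#' @param output_dir Directory to write into (created if needed).
#' @param analyses Which stages to run, a subset of
#'   `c("evaluate", "dsa", "psa")`; the acceptability curve accompanies
#'   `"psa"`.
#' @param seed Integer RNG seed for the PSA.
#' @param n_iterations PSA iterations (defaults to the scenario's
#'   setting).
#' @param figures If `TRUE`, also write PNG figures (requires a PNG
#'   device).
#' @return Invisibly, a named list of the in-memory results
#'   (`result`, `tornado`, `psa`, `ceac`, `manifest`).
#' @export
run_pipeline <- function(scenario, output_dir,
                         analyses = c("evaluate", "dsa", "psa"),
                         seed = 1L, n_iterations = NULL, figures = FALSE) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  stopifnot(inherits(scenario, "cea_scenario"))
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (is.null(n_iterations)) n_iterations <- scenario$psa$n_iterations
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, file) {
    path <- file.path(output_dir, file)
    readr::write_csv(df, path)
    written <<- c(written, path)
    path
  }
  emit_fig <- function(plot, file) {
    if (!figures) return(invisible(NULL))
    path <- file.path(output_dir, file)
    ggplot2::ggsave(path, plot, width = 7, height = 5, dpi = 150)
    written <<- c(written, path)
  }
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", label, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- list()
  if ("evaluate" %in% analyses) {
    stage("evaluate", {
      res <- evaluate_scenario(scenario)
      out$result <- res
      emit(tidy(res), "summary.csv")
      emit(dplyr::bind_rows(tidy(res$reference), tidy(res$comparator)),
           "per_cycle.csv")
    })
  }
  if ("dsa" %in% analyses) {
    stage("dsa", {
      tor <- one_way_dsa(scenario)
      out$tornado <- tor
      emit(tibble::as_tibble(tor), "tornado.csv")
      emit_fig(plot_tornado(tor), "tornado.png")
    })
  }
  if ("psa" %in% analyses) {
    stage("psa", {
      cloud <- run_psa(scenario, n_iterations = n_iterations, seed = seed)
      out$psa <- cloud
      emit(dplyr::select(tibble::as_tibble(cloud), "iteration",
                         "delta_cost", "delta_effect"),
           "psa_cloud.csv")
      curve <- ceac(cloud, scenario$ceac_grid)
      out$ceac <- curve
      emit(tibble::as_tibble(curve), "ceac.csv")
      emit_fig(plot_ce_plane(cloud, scenario$threshold), "ce_plane.png")
      emit_fig(plot_ceac(curve), "ceac.png")
    })
  }
  manifest <- list(
    package = "ceamarkov",
    version = as.character(utils::packageVersion("ceamarkov")),
    scenario = scenario$name,
    seed = seed,
    n_iterations = if ("psa" %in% analyses) n_iterations else NULL,
    analyses = analyses,
    threshold = scenario$threshold,
    horizon = scenario$horizon,
    cohort_size = scenario$cohort_size,
    entry_state = scenario$entry_state,
    discount = scenario$discount,
    relative_risk = scenario$comparator$relative_risk,
    conventions = scenario$conventions,
    psa_uncertainty = scenario$psa$uncertainty
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
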