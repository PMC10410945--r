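#' Load a scenario from a YAML configuration file
#'
#' The configuration is a human-editable YAML document holding the state
#' space, the base transition matrix (nested maps, origin state then
#' destination state), shared utilities, per-arm costs, the treatment
#' effect, discounting, threshold, evaluation conventions and PSA
#' settings. Schema violations are reported with the path of the missing
#' or invalid field; the matrix is checked by
#' [validate_transition_matrix()].
#'
#' @param path Path to a YAML scenario file.
#' @return A validated [cea_scenario()].
#' @seealso [write_scenario()], [alzheimer_scenario()]
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- function(field) {
    x <- cfg
    for (key in strsplit(field, ".", fixed = TRUE)[[1]]) {
      if (is.null(x[[key]])) {
        stop("scenario config missing field '", field, "'", call. = FALSE)
      }
      x <- x[[key]]
    }
    x
  }
  lab <- as.character(need("states"))
  named_over_states <- function(field) {
    x <- need(field)
    vals <- vapply(lab, function(s) {
      if (is.null(x[[s]])) {
        stop("scenario config missing field '", field, ".", s, "'",
             call. = FALSE)
      }
      as.numeric(x[[s]])
    }, numeric(1))
    vals
  }
  p <- do.call(rbind, lapply(lab, function(from) {
    row <- need(paste0("transition_matrix.", from))
    vapply(lab, function(to) {
      if (is.null(row[[to]])) {
        stop("scenario config missing field 'transition_matrix.", from,
             ".", to, "'", call. = FALSE)
      }
      as.numeric(row[[to]])
    }, numeric(1))
  }))
  rownames(p) <- lab
  m <- transition_matrix(p, absorbing = as.character(need("absorbing")))
  ceac <- need("ceac_grid")
  cea_scenario(
    name = need("name"),
    matrix = m,
    utilities = named_over_states("utilities"),
    reference = list(name = need("reference.name"),
                     cost = named_over_states("reference.costs")),
    comparator = list(name = need("comparator.name"),
                      cost = named_over_states("comparator.costs"),
                      relative_risk = need("comparator.relative_risk"),
                      source_state = need("comparator.source_state")),
    conventions = need("conventions"),
    discount = need("discount"),
    threshold = need("threshold.value"),
    threshold_meta = cfg$threshold[setdiff(names(cfg$threshold), "value")],
    entry_state = need("entry_state"),
    cohort_size = need("cohort_size"),
    horizon = need("horizon"),
    psa = need("psa"),
    ceac_grid = seq(ceac$from, ceac$to, by = ceac$by),
    calibration_targets = unlist(cfg$calibration_targets)
  )
}

#' Write a scenario back to YAML
#'
#' Round-trips with [load_scenario()] (numeric values to 12 significant
#' digits).
#'
#' @param scenario A [cea_scenario()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "cea_scenario"))
  lab <- states(scenario$matrix)
  grid <- scenario$ceac_grid
  cfg <- list(
    name = scenario$name,
    states = lab,
    absorbing = absorbing_states(scenario$matrix),
    entry_state = scenario$entry_state,
    cohort_size = scenario$cohort_size,
    horizon = scenario$horizon,
    transition_matrix = purrr::map(
      stats::setNames(lab, lab),
      function(from) as.list(scenario$matrix[from, ])),
    utilities = as.list(scenario$utilities),
    reference = list(name = scenario$reference$name,
                     costs = as.list(scenario$reference$cost)),
    comparator = list(name = scenario$comparator$name,
                      costs = as.list(scenario$comparator$cost),
                      relative_risk = scenario$comparator$relative_risk,
                      source_state = scenario$comparator$source_state),
    conventions = scenario$conventions,
    discount = scenario$discount,
    threshold = c(list(value = scenario$threshold), scenario$threshold_meta),
    psa = scenario$psa,
    ceac_grid = list(from = grid[1], to = grid[length(grid)],
                     by = grid[2] - grid[1]),
    calibration_targets = as.list(scenario$calibration_targets)
  )
  if (is.null(scenario$calibration_targets)) cfg$calibration_targets <- NULL
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' The shipped Alzheimer's disease scenario
#'
#' Loads the packaged Aducanumab-versus-standard-of-care scenario for mild
#' Alzheimer's disease: four states (mild, moderate, severe, death with
#' death absorbing), the published annual transition matrix, annual state
#' costs (SoC mild $3,140 / moderate $9,460 / severe $16,956; Aducanumab
#' mild $22,000), utilities (0.73 / 0.69 / 0.27), RR = 0.6 on the mild
#' row, a 5-year horizon, cohort of 1000, 6% discount rate and a
#' willingness-to-pay threshold of $28,617/QALY (three times GDP per
#' capita). The evaluation conventions frozen in the file are the winners
#' of [calibrate_conventions()] against the published base-case totals.
#'
#' @return A [cea_scenario()].
#' @export
alzheimer_scenario <- function() {
  load_scenario(system.file("extdata", "alzheimer.yaml",
                            package = "ceamarkov", mustWork = TRUE))
}
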