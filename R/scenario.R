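#' Bundle a full design scenario
#'
#' Validates and bundles everything needed to compare designs: the cost
#' structure, ICC rectangle, power specification, the designs to compare,
#' the effect of interest, and simulation settings.
#'
#' @param costs A [cost_structure].
#' @param rect An [icc_rect].
#' @param spec A [power_spec].
#' @param designs Character vector of designs to compare.
#' @param effect `"treatment"` or `"treatment_by_period"`.
#' @param sigma_y_sq Total outcome variance for simulation.
#' @param n_sim Monte Carlo replications (0 disables simulation).
#' @param seed Master seed for simulation.
#' @param name Optional scenario label.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(costs, rect, spec,
                            designs = c("crossover", "parallel",
                                        "extended_parallel"),
                            effect = "treatment", sigma_y_sq = 2,
                            n_sim = 0, seed = 1, name = "scenario") {
  stopifnot(inherits(costs, "cost_structure"), inherits(rect, "icc_rect"),
            inherits(spec, "power_spec"))
  effect <- match_effect(effect)
  designs <- vapply(designs, match_design, "")
  if (effect == "treatment_by_period") {
    designs <- setdiff(designs, "parallel")
  }
  if (length(designs) == 0) stop("no valid designs", call. = FALSE)
  structure(list(costs = costs, rect = rect, spec = spec,
                 designs = unname(designs), effect = effect,
                 sigma_y_sq = sigma_y_sq, n_sim = n_sim, seed = seed,
                 name = name),
            class = "scenario_config")
}

#' Read a scenario from a flat key-value config file
#'
#' The file (YAML) uses the symbol names of the model: costs `c_A`, `c_B`,
#' `c_t`, `c_sp`, `c_s2p`, `c_ts`; ICC bounds `rhoA_low`, `rhoA_high`,
#' `rhoB_low`, `rhoB_high`; planning keys `ES`, `alpha`, `power`; optional
#' `designs`, `effect`, `sigma_y_sq`, `n_sim`, `seed`, `name`.
#'
#' @param path Path to the config file.
#' @return A [scenario_config].
#' @examples
#' cfg <- read_scenario_config(system.file("extdata", "copd_scenario.yaml",
#'                                         package = "maximindesign"))
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  get <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  costs <- cost_structure(c_A = get("c_A", 0), c_B = get("c_B", 0),
                          c_t = get("c_t", 0), c_sp = get("c_sp", 1),
                          c_s2p = get("c_s2p", get("c_sp", 1)),
                          c_ts = get("c_ts", 0))
  rect <- icc_rect(raw$rhoA_low, get("rhoA_high", raw$rhoA_low),
                   get("rhoB_low", raw$rhoA_low),
                   get("rhoB_high", get("rhoB_low", raw$rhoA_low)))
  spec <- power_spec(ES = raw$ES, alpha = get("alpha", 0.05),
                     power = get("power", 0.80))
  scenario_config(costs, rect, spec,
                  designs = get("designs",
                                c("crossover", "parallel",
                                  "extended_parallel")),
                  effect = get("effect", "treatment"),
                  sigma_y_sq = get("sigma_y_sq", 2),
                  n_sim = get("n_sim", 0), seed = get("seed", 1),
                  name = get("name", basename(path)))
}

#' Run a design scenario end to end
#'
#' For each design in the scenario: the maximin solution over the ICC
#' rectangle, the maximin sample-size plan, relative efficiencies across the
#' designs, and (if `n_sim > 0`) Monte Carlo power at the planned sizes.
#' Optionally writes CSV and JSON reports.
#'
#' @param config A [scenario_config] (or path to a config file).
#' @param out_dir Optional directory for `report.csv` / `report.json`.
#' @return An object of class `design_report`: the scenario, a per-design
#'   results `table` (data frame), and the underlying solution objects.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_scenario_config(config)
  stopifnot(inherits(config, "scenario_config"))
  solutions <- lapply(config$designs, function(d) {
    maximin_params(d, config$effect, config$costs, config$rect)
  })
  plans <- lapply(config$designs, function(d) {
    maximin_sample_size(d, config$effect, config$spec, config$costs,
                        config$rect)
  })
  eff <- relative_efficiency(solutions)
  powers <- rep(NA_real_, length(config$designs))
  if (config$n_sim > 0) {
    powers <- vapply(seq_along(config$designs), function(i) {
      monte_carlo_power(config$designs[i], config$effect, config$spec,
                        config$costs, config$rect,
                        sigma_y_sq = config$sigma_y_sq,
                        n_sim = config$n_sim, seed = config$seed)$power
    }, 0)
  }
  tab <- data.frame(
    design = config$designs,
    effect = config$effect,
    rho_A = vapply(solutions, function(s) unname(s$rho_at["rhoA"]), 0),
    rho_B = vapply(solutions, function(s) unname(s$rho_at["rhoB"]), 0),
    allocation_ratio = vapply(solutions, `[[`, 0, "allocation_ratio"),
    p1 = vapply(solutions, `[[`, 0, "p1"),
    variance = vapply(solutions, `[[`, 0, "variance"),
    branch = vapply(solutions, `[[`, "", "branch"),
    efficiency = unname(eff),
    efficiency_pct = round_half_up(100 * unname(eff)),
    n1 = vapply(plans, `[[`, 0L, "n1"),
    n2 = vapply(plans, `[[`, 0L, "n2"),
    N = vapply(plans, `[[`, 0L, "N"),
    simulated_power = powers
  )
  report <- structure(list(config = config, table = tab,
                           solutions = solutions, plans = plans),
                      class = "design_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a design report to CSV and JSON
#'
#' @param report A `design_report` from [run_scenario].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "design_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  csv <- file.path(out_dir, "report.csv")
  json <- file.path(out_dir, "report.json")
  utils::write.csv(report$table, csv, row.names = FALSE)
  jsonlite::write_json(
    list(scenario = report$config$name,
         effect = report$config$effect,
         ES = report$config$spec$ES,
         alpha = report$config$spec$alpha,
         power = report$config$spec$power,
         designs = report$table),
    json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv = csv, json = json))
}

#' @export
print.design_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Design comparison '%s': %s effect, ES = %g, alpha = %g, power = %g\n",
              cfg$name, cfg$effect, cfg$spec$ES, cfg$spec$alpha,
              cfg$spec$power))
  print(cfg$rect)
  best <- x$table$design[x$table$efficiency >= 1 - 1e-9]
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("  %-17s N = %3d (%d + %d), maximin Var = %.4g, efficiency = %d%%%s\n",
                r$design, r$N, r$n1, r$n2, r$variance, r$efficiency_pct,
                if (!is.na(r$simulated_power))
                  sprintf(", simulated power = %.3f", r$simulated_power)
                else ""))
  }
  cat(sprintf("Most efficient: %s\n", paste(best, collapse = " and ")))
  invisible(x)
}
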