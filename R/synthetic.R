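#' Default generating truth for synthetic experiments
#'
#' A fully specified `emergence_params` fixture spanning three Drosophila
#' hosts (birchii, bipectinata, simulans) and three parasitoid wasps
#' (asobara, ganaspis, leptopilina). The magnitudes are chosen to be
#' realistic for this community while keeping every stage of the pipeline
#' testable:
#'
#' * baseline mortalities give 60--85% control survival over the 8-day
#'   window;
#' * heat mortality differentials are positive for *birchii* (largest for
#'   the "after" timing, the host the heat treatment stresses), and mildly
#'   negative for the other two hosts, emulating heat-accelerated
#'   development raising emergence;
#' * attack rates give 30--70% of surviving larvae parasitized by three
#'   foraging wasps; conversion probabilities lie in \[0.5, 0.9\];
#' * all higher-order terms are null (`gamma = 0`, `delta = 1`).
#'
#' These values are invented test fixtures for the generator; they are not
#' estimates from any real dataset.
#'
#' @return An `emergence_params` object.
#' @examples
#' truth <- default_truth()
#' exp(-8 * truth$m0$value) # control survival per host
#' @export
default_truth <- function() {
  hosts <- c("birchii", "bipectinata", "simulans")
  wasps <- c("asobara", "ganaspis", "leptopilina")
  emergence_params(
    m0 = c(birchii = 0.040, bipectinata = 0.025, simulans = 0.055),
    m_tau = tibble(
      host = rep(hosts, each = 3),
      heat_timing = rep(c("before", "during", "after"), times = 3),
      value = c(0.35, 0.55, 0.90,     # birchii: heat-stressed, worst when late
                -0.08, -0.08, -0.08,  # bipectinata: slight emergence boost
                -0.05, -0.05, -0.05)  # simulans: slight emergence boost
    ),
    a0 = tibble(
      host = rep(hosts, each = 3),
      parasitoid = rep(wasps, times = 3),
      value = c(0.30, 0.22, 0.26,
                0.14, 0.18, 0.12,
                0.25, 0.35, 0.20)
    ),
    epsilon = tibble(
      host = rep(hosts, each = 3),
      parasitoid = rep(wasps, times = 3),
      value = c(0.80, 0.70, 0.75,
                0.55, 0.60, 0.50,
                0.85, 0.65, 0.70)
    )
  )
}

#' Named synthetic-experiment scenarios
#'
#' A scenario bundles a generating truth, the design constants and a default
#' seed. Three presets cover the hypotheses the additivity test is meant to
#' separate:
#'
#' * `additive_null` -- the default truth unchanged: heat and parasitism
#'   mortalities combine additively (`gamma = 0`, `delta = 1` everywhere).
#' * `synergy_mortality` -- adds an extra mortality exponent
#'   (`gamma = 0.8`) in every cell where heat coincides with the parasitoid
#'   foraging window ("during"), emulating parasitism weakening hosts
#'   against heat: fewer flies than the additive model predicts.
#' * `antagonism_parasitism` -- multiplies the attack rate by
#'   `delta = 0.05` in combined "during" and "after" cells, emulating heat
#'   killing recently laid parasitoid eggs or larvae: far fewer wasps than
#'   the additive model predicts.
#'
#' @param name One of `"additive_null"`, `"synergy_mortality"`,
#'   `"antagonism_parasitism"`.
#' @param constants A [design_constants()] object.
#' @param seed Default seed carried by the scenario (overridable in
#'   [generate_vials()]).
#' @return An object of class `flywasp_scenario`: a list with `name`,
#'   `truth`, `constants`, `seed`.
#' @examples
#' scenario_preset("antagonism_parasitism")$name
#' @export
scenario_preset <- function(name, constants = design_constants(), seed = 1L) {
  presets <- c("additive_null", "synergy_mortality", "antagonism_parasitism")
  if (!is.character(name) || length(name) != 1 || !name %in% presets) {
    abort_validation(paste0("Unknown scenario `", paste(name, collapse = ","),
                            "`; available presets: ", comma(presets)))
  }
  truth <- default_truth()
  hosts <- unique(truth$m0$host)
  wasps <- unique(truth$a0$parasitoid)
  if (name == "synergy_mortality") {
    truth <- emergence_params(
      m0 = setNames(truth$m0$value, truth$m0$host),
      m_tau = truth$m_tau, a0 = truth$a0, epsilon = truth$epsilon,
      gamma = expand_grid(host = hosts, parasitoid = wasps,
                          heat_timing = "during") |>
        mutate(value = 0.8)
    )
  } else if (name == "antagonism_parasitism") {
    truth <- emergence_params(
      m0 = setNames(truth$m0$value, truth$m0$host),
      m_tau = truth$m_tau, a0 = truth$a0, epsilon = truth$epsilon,
      delta = expand_grid(host = hosts, parasitoid = wasps,
                          heat_timing = c("during", "after")) |>
        mutate(value = 0.05)
    )
  }
  structure(list(name = name, truth = truth, constants = constants,
                 seed = as.integer(seed)),
            class = "flywasp_scenario")
}

#' @export
print.flywasp_scenario <- function(x, ...) {
  cat("<flywasp_scenario>", x$name, "\n")
  cat("  seed:", x$seed, "\n")
  print(x$truth)
  invisible(x)
}

#' Generate a synthetic factorial vial dataset
#'
#' Simulates the full crossed design (every host by parasitoid-or-none by
#' timing-or-ambient cell) under a scenario's generating truth, drawing each
#' vial as one multinomial sample of its eggs over the fly/wasp/neither
#' fates. With the default design this yields 48 cells x 6 replicates = 288
#' vials and 14,400 eggs. Output passes [validate_vials()] by construction.
#'
#' @param scenario A `flywasp_scenario` from [scenario_preset()], or a
#'   preset name.
#' @param n_replicates Replicates per cell; defaults to the scenario
#'   design's `replicates_per_cell`.
#' @param seed Integer seed; defaults to the scenario's own.
#' @return A vial tibble (see [validate_vials()]).
#' @examples
#' vials <- generate_vials("additive_null", seed = 7)
#' nrow(vials)      # 288
#' sum(vials$eggs)  # 14400
#' @export
generate_vials <- function(scenario, n_replicates = NULL, seed = NULL) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  if (!inherits(scenario, "flywasp_scenario")) {
    abort_validation("`scenario` must be a flywasp_scenario or a preset name.")
  }
  constants <- scenario$constants
  n_replicates <- n_replicates %||% constants$replicates_per_cell
  seed <- seed %||% scenario$seed
  hosts <- sort(unique(scenario$truth$m0$host))
  wasps <- sort(unique(scenario$truth$a0$parasitoid))
  timings <- c("ambient", names(constants$heat_days))
  cells <- enumerate_design(hosts, c("none", wasps), timings)
  simulate_experiment(cells, scenario$truth, constants,
                      n_replicates = n_replicates, seed = seed)
}
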