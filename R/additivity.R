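#' Bootstrap interval for observed emergence in one treatment cell
#'
#' Summarizes the observed replicate vials of one treatment cell by a
#' percentile bootstrap of the replicate mean: resample the vials with
#' replacement, take the mean fly (and wasp) count of each resample, and
#' report the 2.5th and 97.5th percentiles. A single replicate yields a
#' degenerate point interval with a warning.
#'
#' @param vials Vial tibble for one treatment cell (>= 1 row).
#' @param n_boot Bootstrap resamples (default 10,000).
#' @param seed Optional integer seed.
#' @return A tibble with one row per channel (`"flies"`, `"wasps"`):
#'   `channel`, `mean`, `lower95`, `upper95`, `n` (replicates), `method`.
#' @examples
#' v <- tibble::tibble(host = "simulans", parasitoid = "asobara",
#'                     heat_timing = "ambient", replicate = paste0("r", 1:6),
#'                     eggs = 50, flies = c(18, 22, 20, 25, 17, 21),
#'                     wasps = c(10, 8, 12, 9, 11, 10))
#' observed_interval(v, n_boot = 1000, seed = 1)
#' @export
observed_interval <- function(vials, n_boot = 10000, seed = NULL) {
  if (nrow(vials) == 0) abort_validation("No vials supplied.")
  local_seed_if(seed)
  n <- nrow(vials)
  if (n == 1) {
    warn("Single replicate: observed interval is degenerate.")
  }
  one_channel <- function(x, channel) {
    if (n == 1 || n_boot == 0) {
      lo <- hi <- mean(x)
      method <- "point (single replicate)"
    } else {
      bm <- colMeans(matrix(sample(x, n * n_boot, replace = TRUE), nrow = n))
      qs <- quantile(bm, c(0.025, 0.975), names = FALSE)
      lo <- qs[1]; hi <- qs[2]
      method <- "percentile bootstrap of replicate mean"
    }
    tibble(channel = channel, mean = mean(x), lower95 = lo, upper95 = hi,
           n = n, method = method)
  }
  bind_rows(one_channel(vials$flies, "flies"),
            one_channel(vials$wasps, "wasps"))
}

#' Null (additive) projection of emergence for one treatment cell
#'
#' Simulates `n_sims` pseudo-experiments of `n_replicates` vials each under
#' the fitted additive-null parameters (`gamma = 0`, `delta = 1`) for the
#' requested cell, and summarizes the distribution of the per-experiment
#' mean fly and wasp counts by its 2.5th and 97.5th percentiles. This is the
#' distribution the observed cell means are compared against: if the
#' observed interval falls outside it, additivity of heat and parasitism
#' mortalities is rejected for that cell.
#'
#' @param fit An `emergence_fit` from [fit_all()] (or any list with a
#'   `params` component of class `emergence_params`).
#' @param cell One-row data frame (or named list) with `host`, `parasitoid`,
#'   `heat_timing`.
#' @param constants A [design_constants()] object; defaults to the one
#'   stored in `fit`.
#' @param n_sims Number of pseudo-experiments (>= 100; default 10,000).
#' @param n_replicates Vials per pseudo-experiment; defaults to the design's
#'   `replicates_per_cell`.
#' @param seed Optional integer seed.
#' @return A tibble like [observed_interval()]'s, with `n = n_sims` and
#'   method `"percentile of simulated replicate means"`.
#' @export
project_null <- function(fit, cell, constants = NULL, n_sims = 10000,
                         n_replicates = NULL, seed = NULL) {
  params <- if (inherits(fit, "emergence_params")) fit else fit$params
  if (!inherits(params, "emergence_params")) {
    abort_validation("`fit` must be an emergence_fit or emergence_params object.")
  }
  constants <- constants %||% fit$constants %||% design_constants()
  n_replicates <- n_replicates %||% constants$replicates_per_cell
  if (!is_count_vector(n_sims) || n_sims < 100) {
    abort_validation("`n_sims` must be an integer >= 100.")
  }
  local_seed_if(seed)
  cell <- as_tibble(cell)
  if (nrow(cell) != 1) abort_validation("`cell` must describe exactly one cell.")
  probs <- fate_probabilities(cell, params, constants)
  p <- c(probs$p_fly, probs$p_wasp, probs$p_none)
  draws <- rmultinom(n_sims * n_replicates, size = constants$eggs_per_vial,
                     prob = p)
  fly_means <- colMeans(matrix(draws[1, ], nrow = n_replicates))
  wasp_means <- colMeans(matrix(draws[2, ], nrow = n_replicates))
  one <- function(x, channel) {
    qs <- quantile(x, c(0.025, 0.975), names = FALSE)
    tibble(channel = channel, mean = mean(x), lower95 = qs[1], upper95 = qs[2],
           n = n_sims, method = "percentile of simulated replicate means")
  }
  bind_rows(one(fly_means, "flies"), one(wasp_means, "wasps"))
}

#' Overlap decision rule for observed vs simulated intervals
#'
#' Declares a higher-order (non-additive) effect exactly when the two 95%
#' intervals are disjoint; intervals that merely touch at an endpoint count
#' as overlapping, which is conservative toward the additive null. The rule
#' is symmetric in its arguments.
#'
#' @param observed,simulated One-row data frames (or named lists) with
#'   `lower95` and `upper95`; vectors of equal length are handled
#'   elementwise.
#' @return `"additive"` or `"higher_order"` (character, vectorized).
#' @examples
#' overlap_verdict(list(lower95 = 10, upper95 = 20),
#'                 list(lower95 = 15, upper95 = 25)) # "additive"
#' overlap_verdict(list(lower95 = 10, upper95 = 12),
#'                 list(lower95 = 20, upper95 = 25)) # "higher_order"
#' @export
overlap_verdict <- function(observed, simulated) {
  olo <- observed$lower95; ohi <- observed$upper95
  slo <- simulated$lower95; shi <- simulated$upper95
  if (any(olo > ohi) || any(slo > shi)) {
    abort_validation("Interval bounds must satisfy lower95 <= upper95.")
  }
  if_else(ohi < slo | shi < olo, "higher_order", "additive")
}

#' Run the additivity test over all combined heat-by-parasitoid cells
#'
#' For every treatment cell in the data where heat and parasitoids co-occur
#' (parasitoid not `"none"`, timing not `"ambient"`), compares the observed
#' bootstrap interval of mean emergence with the additive-null projection
#' from the fitted parameters, separately for the fly and wasp channels.
#' Cells whose intervals are disjoint are flagged `higher_order`; since
#' combined cells are never used in fitting, each comparison is an
#' out-of-sample test of the additive mortality model.
#'
#' @param vials Full vial tibble (observed or synthetic data).
#' @param fit An `emergence_fit` from [fit_all()] on the same data's control
#'   arms.
#' @param constants A [design_constants()] object; defaults to `fit$constants`.
#' @param n_sims Pseudo-experiments per cell for the null projection.
#' @param n_boot Bootstrap resamples per cell for the observed interval.
#' @param seed Optional integer seed covering the whole suite.
#' @return A tibble of class `additivity_verdicts`: one row per cell and
#'   channel with observed and simulated interval summaries and a `verdict`
#'   column. Plot it with [autoplot()].
#' @examples
#' vials <- generate_vials(scenario_preset("additive_null"), seed = 1)
#' fit <- fit_all(vials, n_bootstrap = 0)
#' verdicts <- run_additivity_suite(vials, fit, n_sims = 200, n_boot = 200,
#'                                  seed = 2)
#' dplyr::count(verdicts, channel, verdict)
#' @export
run_additivity_suite <- function(vials, fit, constants = NULL,
                                 n_sims = 10000, n_boot = 10000, seed = NULL) {
  constants <- constants %||% fit$constants %||% design_constants()
  vials <- as_tibble(vials)
  combined <- distinct(
    filter(vials, .data$parasitoid != "none", .data$heat_timing != "ambient"),
    .data$host, .data$parasitoid, .data$heat_timing)
  combined <- arrange(combined, .data$host, .data$parasitoid, .data$heat_timing)
  empty <- tibble(
    host = character(), parasitoid = character(), heat_timing = character(),
    channel = character(), n_replicates = integer(),
    obs_mean = numeric(), obs_lower = numeric(), obs_upper = numeric(),
    sim_mean = numeric(), sim_lower = numeric(), sim_upper = numeric(),
    verdict = character())
  if (nrow(combined) == 0) {
    warn("No combined heat x parasitoid cells in the data; nothing to test.")
    return(structure(empty, class = c("additivity_verdicts", class(empty))))
  }
  local_seed_if(seed)
  rows <- map(seq_len(nrow(combined)), function(i) {
    cell <- combined[i, ]
    cell_vials <- filter(vials, .data$host == cell$host,
                         .data$parasitoid == cell$parasitoid,
                         .data$heat_timing == cell$heat_timing)
    obs <- observed_interval(cell_vials, n_boot = n_boot)
    sim <- project_null(fit, cell, constants, n_sims = n_sims,
                        n_replicates = nrow(cell_vials))
    tibble(
      host = cell$host, parasitoid = cell$parasitoid,
      heat_timing = cell$heat_timing, channel = obs$channel,
      n_replicates = nrow(cell_vials),
      obs_mean = obs$mean, obs_lower = obs$lower95, obs_upper = obs$upper95,
      sim_mean = sim$mean, sim_lower = sim$lower95, sim_upper = sim$upper95,
      verdict = overlap_verdict(
        list(lower95 = obs$lower95, upper95 = obs$upper95),
        list(lower95 = sim$lower95, upper95 = sim$upper95))
    )
  })
  out <- bind_rows(rows)
  structure(out, class = c("additivity_verdicts", class(out)))
}

#' Write the verdict table to CSV
#'
#' @param verdicts An `additivity_verdicts` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_verdicts <- function(verdicts, path) {
  readr::write_csv(as_tibble(verdicts), path, progress = FALSE)
  invisible(path)
}

#' Plot observed vs simulated emergence intervals
#'
#' Draws, for each combined heat-by-parasitoid cell, the observed bootstrap
#' interval next to the additive-null simulated interval; cells whose
#' verdict is `higher_order` are marked with an asterisk.
#'
#' @param object An `additivity_verdicts` tibble from
#'   [run_additivity_suite()].
#' @param channel `"flies"` (default) or `"wasps"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot additivity_verdicts
#' @export
autoplot.additivity_verdicts <- function(object, channel = c("flies", "wasps"),
                                         ...) {
  channel <- match.arg(channel)
  df <- filter(as_tibble(object), .data$channel == !!channel)
  long <- bind_rows(
    mutate(select(df, all_of(c("host", "parasitoid", "heat_timing", "verdict"))),
           source = "observed", mean = df$obs_mean,
           lower = df$obs_lower, upper = df$obs_upper),
    mutate(select(df, all_of(c("host", "parasitoid", "heat_timing", "verdict"))),
           source = "simulated", mean = df$sim_mean,
           lower = df$sim_lower, upper = df$sim_upper)
  )
  flagged <- filter(df, .data$verdict == "higher_order")
  gg <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$heat_timing, y = .data$mean, colour = .data$source)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      position = ggplot2::position_dodge(width = 0.5), linewidth = 0.4,
      size = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$host),
                        cols = ggplot2::vars(.data$parasitoid)) +
    ggplot2::labs(
      x = "heat exposure timing",
      y = paste("mean", channel, "emerged per vial"),
      colour = NULL,
      title = "Observed vs additive-null simulated emergence (95% intervals)") +
    ggplot2::theme_bw()
  if (nrow(flagged) > 0) {
    star_y <- max(long$upper) * 1.05
    gg <- gg + ggplot2::geom_text(
      data = mutate(flagged, label = "*"),
      ggplot2::aes(x = .data$heat_timing, label = .data$label),
      y = star_y, colour = "black", size = 5, inherit.aes = FALSE)
  }
  gg
}

#' @rdname autoplot.additivity_verdicts
#' @param verdicts An `additivity_verdicts` tibble.
#' @export
plot_additivity <- function(verdicts, channel = c("flies", "wasps")) {
  autoplot.additivity_verdicts(verdicts, channel = channel)
}
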