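#' Per-egg emergence fate probabilities
#'
#' Evaluates the single-generation emergence model for each treatment cell.
#' An egg survives larval development with probability
#' `s = exp(-m0 * T - m_tau - gamma)`, capped at 1 when a strongly negative
#' `m_tau` would push it above (the `gamma` term only in cells where
#' heat and parasitoids co-occur), escapes all `P` foraging wasps with
#' probability `q = exp(-a0 * delta * P)` (`delta` likewise only in combined
#' cells; `q = 1` in no-parasitoid cells), and then:
#'
#' * emerges as a fly with probability `p_fly = s * q`;
#' * yields an adult wasp with probability `p_wasp = s * (1 - q) * epsilon`;
#' * otherwise emerges as neither (`p_none = 1 - p_fly - p_wasp`), pooling
#'   background death with infected hosts that produced no wasp.
#'
#' With `gamma = 0` and `delta = 1` the expectations `H0 * p_fly` and
#' `H0 * p_wasp` equal the additive-null Nicholson--Bailey emergence model
#' exactly, so mortalities combine as the summed exponent
#' `m0*T + m_tau + a0*P`.
#'
#' @param cells Data frame with columns `host`, `parasitoid`, `heat_timing`
#'   (one row per treatment cell; extra columns are carried through).
#' @param params An [emergence_params()] object covering every key the cells
#'   require.
#' @param constants A [design_constants()] object.
#'
#' @return The input tibble with columns `p_fly`, `p_wasp`, `p_none`
#'   appended.
#' @examples
#' pars <- emergence_params(
#'   m0 = c(birchii = 0.02),
#'   a0 = data.frame(host = "birchii", parasitoid = "asobara", value = 0.1),
#'   epsilon = data.frame(host = "birchii", parasitoid = "asobara", value = 0.8)
#' )
#' cell <- data.frame(host = "birchii", parasitoid = "asobara",
#'                    heat_timing = "ambient")
#' fate_probabilities(cell, pars, design_constants())
#' @export
fate_probabilities <- function(cells, params, constants = design_constants()) {
  stopifnot(inherits(params, "emergence_params"))
  need <- c("host", "parasitoid", "heat_timing")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("`cells` is missing columns: ", comma(missing_cols)))
  }
  cells <- as_tibble(cells)
  x <- select(cells, all_of(need))

  x <- left_join(x, rename(params$m0, .m0 = "value"), by = "host")
  if (anyNA(x$.m0)) {
    abort_config(paste0("Missing m0 for host(s): ",
                        comma(unique(x$host[is.na(x$.m0)]))))
  }

  x <- left_join(x, rename(params$m_tau, .m_tau = "value"),
                 by = c("host", "heat_timing"))
  x$.m_tau[is.na(x$.m_tau) & x$heat_timing == "ambient"] <- 0
  if (anyNA(x$.m_tau)) {
    bad <- unique(paste(x$host, x$heat_timing, sep = "/")[is.na(x$.m_tau)])
    abort_config(paste0("Missing m_tau for (host/heat_timing): ", comma(bad)))
  }

  x <- left_join(x, rename(params$a0, .a0 = "value"), by = c("host", "parasitoid"))
  x <- left_join(x, rename(params$epsilon, .eps = "value"),
                 by = c("host", "parasitoid"))
  has_wasps <- x$parasitoid != "none"
  if (any(has_wasps & (is.na(x$.a0) | is.na(x$.eps)))) {
    bad <- unique(paste(x$host, x$parasitoid, sep = "/")[
      has_wasps & (is.na(x$.a0) | is.na(x$.eps))])
    abort_config(paste0("Missing a0/epsilon for (host/parasitoid): ", comma(bad)))
  }
  x$.a0[!has_wasps] <- 0
  x$.eps[!has_wasps] <- 0

  triple <- c("host", "parasitoid", "heat_timing")
  x <- left_join(x, rename(params$gamma, .gamma = "value"), by = triple)
  x <- left_join(x, rename(params$delta, .delta = "value"), by = triple)
  x$.gamma[is.na(x$.gamma)] <- 0
  x$.delta[is.na(x$.delta)] <- 1
  combined <- has_wasps & x$heat_timing != "ambient"
  x$.gamma[!combined] <- 0
  x$.delta[!combined] <- 1

  p_eff <- ifelse(has_wasps, constants$wasp_count, 0)
  # A strongly negative m_tau can push the nominal surviving fraction above
  # 1; cap it so the fates remain a probability distribution. Fitted
  # parameters never trigger the cap (observed survival proportions are <= 1
  # by construction).
  s <- pmin(1, exp(-x$.m0 * constants$end_day - x$.m_tau - x$.gamma))
  q <- exp(-x$.a0 * x$.delta * p_eff)
  p_fly <- s * q
  p_wasp <- s * (1 - q) * x$.eps
  out <- mutate(cells,
                p_fly = p_fly,
                p_wasp = p_wasp,
                p_none = 1 - p_fly - p_wasp)
  out
}

#' Expected fly and wasp emergence per vial
#'
#' Scales the fate probabilities by the eggs seeded per vial:
#' `flies_expected = H0 * p_fly`, `wasps_expected = H0 * p_wasp`. Under the
#' additive null (`gamma = 0`, `delta = 1`) these equal the closed-form
#' model expectations.
#'
#' @inheritParams fate_probabilities
#' @return The input tibble with columns `flies_expected`, `wasps_expected`
#'   appended.
#' @export
expected_emergence <- function(cells, params, constants = design_constants()) {
  probs <- fate_probabilities(cells, params, constants)
  out <- mutate(cells,
                flies_expected = constants$eggs_per_vial * probs$p_fly,
                wasps_expected = constants$eggs_per_vial * probs$p_wasp)
  out
}

#' Simulate vial-level emergence counts
#'
#' Draws each vial as a single multinomial sample of its `H0` eggs over the
#' three fates (fly, wasp, neither), so simulated means converge to
#' [expected_emergence()] exactly. `simulate_experiment()` produces
#' `n_replicates` vials per cell with replicate labels `"r1" ... "rn"`;
#' `simulate_vial()` is the single-vial convenience form.
#'
#' @inheritParams fate_probabilities
#' @param n_replicates Replicate vials per cell; defaults to the design's
#'   `replicates_per_cell`.
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   exactly and the caller's RNG state is left untouched.
#'
#' @return A vial tibble with columns `host`, `parasitoid`, `heat_timing`,
#'   `replicate`, `eggs`, `flies`, `wasps` (rows ordered by cell then
#'   replicate).
#' @examples
#' pars <- emergence_params(m0 = c(birchii = 0.04))
#' cells <- data.frame(host = "birchii", parasitoid = "none",
#'                     heat_timing = "ambient")
#' simulate_experiment(cells, pars, design_constants(), n_replicates = 3,
#'                     seed = 1)
#' @export
simulate_experiment <- function(cells, params, constants = design_constants(),
                                n_replicates = constants$replicates_per_cell,
                                seed = NULL) {
  if (!is_count_vector(n_replicates) || n_replicates < 1) {
    abort_validation("`n_replicates` must be a positive integer.")
  }
  local_seed_if(seed)
  probs <- fate_probabilities(cells, params, constants)
  h0 <- constants$eggs_per_vial
  draws <- map(seq_len(nrow(probs)), function(i) {
    p <- c(probs$p_fly[i], probs$p_wasp[i], probs$p_none[i])
    m <- rmultinom(n_replicates, size = h0, prob = p)
    tibble(
      host = rep(probs$host[i], n_replicates),
      parasitoid = rep(probs$parasitoid[i], n_replicates),
      heat_timing = rep(probs$heat_timing[i], n_replicates),
      replicate = paste0("r", seq_len(n_replicates)),
      eggs = rep(h0, n_replicates),
      flies = m[1, ],
      wasps = m[2, ]
    )
  })
  bind_rows(draws)
}

#' @rdname simulate_experiment
#' @param cell A one-row data frame (or list) with `host`, `parasitoid`,
#'   `heat_timing`.
#' @export
simulate_vial <- function(cell, params, constants = design_constants(),
                          seed = NULL) {
  cell <- as_tibble(cell)
  if (nrow(cell) != 1) abort_validation("`cell` must describe exactly one cell.")
  simulate_experiment(cell, params, constants, n_replicates = 1, seed = seed)
}
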