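#' Closed-form stage estimators for the emergence model
#'
#' Each stage inverts the pooled emergence proportion of one fitting stratum
#' under the additive-null model; for binomial counts with a shared per-egg
#' probability this pooled inversion is the maximum-likelihood estimate.
#'
#' * `fit_baseline_mortality()` uses a host's no-parasitoid, ambient vials:
#'   `m0 = -log(sum(flies) / sum(eggs)) / T`.
#' * `fit_heat_mortality()` uses a host's no-parasitoid vials at one heat
#'   timing, given `m0`: `m_tau = -log(sum(flies) / sum(eggs)) - m0 * T`.
#'   Negative values (heat raising emergence) are kept, with a note.
#' * `fit_attack_rate()` uses a pair's ambient parasitoid vials, given
#'   `m0`: `a0 = -log(mean(flies) / (H0 * exp(-m0 * T))) / P`, clamped to 0
#'   with a warning when mean fly emergence exceeds the no-parasitoid
#'   expectation.
#' * `fit_conversion()` then inverts mean wasp emergence:
#'   `epsilon = mean(wasps) / (H0 * exp(-m0 * T) * (1 - exp(-a0 * P)))`,
#'   clamped to \[0, 1\] with a warning.
#'
#' @param vials Vial tibble restricted to the relevant fitting stratum
#'   (one host, or one host--parasitoid pair).
#' @param constants A [design_constants()] object.
#' @param m0 Baseline mortality previously fitted for the host.
#' @param a0 Attack rate previously fitted for the pair.
#'
#' @return A one-row tibble with columns `estimate`, `n_vials`, `warning`
#'   (`NA` when clean).
#' @examples
#' const <- design_constants()
#' ctrl <- tibble::tibble(host = "simulans", parasitoid = "none",
#'                        heat_timing = "ambient",
#'                        replicate = paste0("r", 1:6),
#'                        eggs = 50, flies = 34, wasps = 0)
#' fit_baseline_mortality(ctrl, const) # -log(0.68)/8
#' @name stage_fits
NULL

#' @rdname stage_fits
#' @export
fit_baseline_mortality <- function(vials, constants = design_constants()) {
  if (nrow(vials) < 1) abort_validation("At least one vial is required.")
  total_flies <- sum(vials$flies)
  total_eggs <- sum(vials$eggs)
  if (total_flies > total_eggs) {
    abort_validation("Total flies exceed total eggs in the baseline stratum.")
  }
  if (total_flies == 0) {
    abort_degenerate("No flies emerged in the baseline stratum; m0 is infinite.")
  }
  est <- -log(total_flies / total_eggs) / constants$end_day
  warning_msg <- if (nrow(vials) == 1) "single vial; SE unavailable" else NA_character_
  tibble(estimate = est, n_vials = nrow(vials), warning = warning_msg)
}

#' @rdname stage_fits
#' @export
fit_heat_mortality <- function(vials, m0, constants = design_constants()) {
  if (nrow(vials) < 1) abort_validation("At least one vial is required.")
  total_flies <- sum(vials$flies)
  total_eggs <- sum(vials$eggs)
  if (total_flies == 0) {
    abort_degenerate("No flies emerged in the heat stratum; m_tau is infinite.")
  }
  est <- -log(total_flies / total_eggs) - m0 * constants$end_day
  warning_msg <- if (est < 0) {
    "m_tau < 0: emergence higher under heat than ambient (survival benefit)"
  } else {
    NA_character_
  }
  tibble(estimate = est, n_vials = nrow(vials), warning = warning_msg)
}

#' @rdname stage_fits
#' @export
fit_attack_rate <- function(vials, m0, constants = design_constants()) {
  if (nrow(vials) < 1) abort_validation("At least one vial is required.")
  if (constants$wasp_count <= 0) {
    abort_validation("Attack rates require a design with wasp_count > 0.")
  }
  fbar <- mean(vials$flies)
  base <- constants$eggs_per_vial * exp(-m0 * constants$end_day)
  if (fbar == 0) {
    abort_degenerate(paste0(
      "No flies emerged in the parasitoid stratum; a0 is infinite. ",
      "Consider a joint-likelihood fit using wasp counts."))
  }
  if (fbar > base) {
    return(tibble(
      estimate = 0,
      n_vials = nrow(vials),
      warning = paste0("a0 clamped to 0: mean flies (", round(fbar, 2),
                       ") exceed the no-parasitoid expectation (",
                       round(base, 2), ")")))
  }
  est <- -log(fbar / base) / constants$wasp_count
  tibble(estimate = est, n_vials = nrow(vials), warning = NA_character_)
}

#' @rdname stage_fits
#' @export
fit_conversion <- function(vials, m0, a0, constants = design_constants()) {
  if (nrow(vials) < 1) abort_validation("At least one vial is required.")
  wbar <- mean(vials$wasps)
  if (a0 == 0) {
    if (wbar > 0) {
      abort_degenerate("Wasps emerged although the fitted attack rate is 0.")
    }
    return(tibble(estimate = 0, n_vials = nrow(vials), warning = NA_character_))
  }
  denom <- constants$eggs_per_vial * exp(-m0 * constants$end_day) *
    (1 - exp(-a0 * constants$wasp_count))
  est <- wbar / denom
  warning_msg <- NA_character_
  if (est > 1) {
    warning_msg <- paste0("epsilon clamped to 1 (raw estimate ", round(est, 4), ")")
    est <- 1
  }
  tibble(estimate = est, n_vials = nrow(vials), warning = warning_msg)
}

fit_key_cols <- c("param", "host", "parasitoid", "heat_timing")

#' Fit all emergence-model parameters from control arms
#'
#' Estimates `m0` per host from no-parasitoid ambient vials, `m_tau` per
#' host and heat timing from no-parasitoid heat vials, and `a0` and
#' `epsilon` per host--parasitoid pair from ambient parasitoid vials, using
#' the closed forms of [fit_baseline_mortality()] and friends. The
#' higher-order terms are fixed at their null values (`gamma = 0`,
#' `delta = 1`): combined heat-by-parasitoid cells are never used for
#' fitting, so they remain available as out-of-sample tests of additivity.
#'
#' Uncertainty comes from a stratified nonparametric bootstrap: vials are
#' resampled with replacement within each fitting stratum and the whole
#' estimation chain is re-run, so the uncertainty in `m0` propagates into
#' `m_tau`, `a0` and `epsilon`. Standard errors are the standard deviation
#' across resamples; strata with a single vial get `NA` with a note.
#'
#' @param vials Full vial tibble containing the control arms (validated with
#'   [validate_vials()]).
#' @param constants A [design_constants()] object.
#' @param n_bootstrap Bootstrap resamples for standard errors; 0 skips the
#'   bootstrap (point estimates only).
#' @param seed Optional integer seed for the bootstrap.
#' @param epsilon_by `"pair"` (default) fits `epsilon` per host--parasitoid
#'   pair; `"parasitoid"` pools hosts and fits one `epsilon` per parasitoid
#'   species.
#'
#' @return An object of class `emergence_fit`, with [tidy()] and [glance()]
#'   methods. Components: `params` (an [emergence_params()] object),
#'   `estimates` (long tibble of estimate, SE, stratum size, warnings),
#'   `n_bootstrap`, `epsilon_by`, `constants`.
#' @examples
#' vials <- generate_vials(scenario_preset("additive_null"), seed = 1)
#' fit <- fit_all(vials, n_bootstrap = 50, seed = 2)
#' tidy(fit)
#' @export
fit_all <- function(vials, constants = design_constants(), n_bootstrap = 1000,
                    seed = NULL, epsilon_by = c("pair", "parasitoid")) {
  epsilon_by <- match.arg(epsilon_by)
  if (!is_count_vector(n_bootstrap)) {
    abort_validation("`n_bootstrap` must be a non-negative integer.")
  }
  missing_cols <- setdiff(c("host", "parasitoid", "heat_timing", "eggs",
                            "flies", "wasps"), names(vials))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("Vial table is missing columns: ", comma(missing_cols)))
  }
  vials <- as_tibble(vials)
  local_seed_if(seed)
  B <- as.integer(n_bootstrap)
  h0 <- constants$eggs_per_vial
  t_end <- constants$end_day
  p_wasps <- constants$wasp_count

  hosts <- sort(unique(vials$host))
  timings_by_host <- distinct(
    filter(vials, .data$heat_timing != "ambient"),
    .data$host, .data$heat_timing)
  pairs <- distinct(filter(vials, .data$parasitoid != "none"),
                    .data$host, .data$parasitoid)

  # Verify every fitting stratum is present before estimating anything.
  stratum <- function(h, p, tm) {
    filter(vials, .data$host == h, .data$parasitoid == p, .data$heat_timing == tm)
  }
  missing_strata <- character()
  for (h in hosts) {
    if (nrow(stratum(h, "none", "ambient")) == 0) {
      missing_strata <- c(missing_strata,
                          paste0("(", h, ", none, ambient)"))
    }
  }
  for (i in seq_len(nrow(timings_by_host))) {
    h <- timings_by_host$host[i]; tm <- timings_by_host$heat_timing[i]
    if (nrow(stratum(h, "none", tm)) == 0) {
      missing_strata <- c(missing_strata, paste0("(", h, ", none, ", tm, ")"))
    }
  }
  for (i in seq_len(nrow(pairs))) {
    h <- pairs$host[i]; p <- pairs$parasitoid[i]
    if (nrow(stratum(h, p, "ambient")) == 0) {
      missing_strata <- c(missing_strata, paste0("(", h, ", ", p, ", ambient)"))
    }
  }
  if (length(missing_strata) > 0) {
    abort_validation(paste0(
      "Required control strata absent from the data: ", comma(missing_strata)))
  }

  # Resample vial rows within a stratum: list of column matrices (n x B).
  resample <- function(df, cols) {
    n <- nrow(df)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    lapply(setNames(cols, cols), function(cl) matrix(df[[cl]][idx], nrow = n))
  }
  boot_se <- function(x, n_stratum) {
    if (B == 0) return(NA_real_)
    if (n_stratum < 2) return(NA_real_)
    x <- x[is.finite(x)]
    if (length(x) < 2) return(NA_real_)
    sd(x)
  }
  se_note <- function(n_stratum) {
    if (B == 0) return("bootstrap skipped")
    if (n_stratum < 2) return("SE unavailable (single vial)")
    NA_character_
  }
  add_row_est <- function(acc, param, host, parasitoid, heat_timing,
                          estimate, se, n_vials, warning) {
    bind_rows(acc, tibble(
      param = param, host = host, parasitoid = parasitoid,
      heat_timing = heat_timing, estimate = estimate, se = se,
      n_vials = n_vials, warning = warning))
  }
  merge_notes <- function(...) {
    notes <- c(...)
    notes <- notes[!is.na(notes)]
    if (length(notes) == 0) NA_character_ else paste(notes, collapse = "; ")
  }

  est <- tibble(param = character(), host = character(),
                parasitoid = character(), heat_timing = character(),
                estimate = numeric(), se = numeric(), n_vials = integer(),
                warning = character())
  m0_hat <- setNames(numeric(length(hosts)), hosts)
  m0_boot <- list()

  for (h in hosts) {
    amb <- stratum(h, "none", "ambient")
    stage <- fit_baseline_mortality(amb, constants)
    m0_hat[[h]] <- stage$estimate
    m0_b <- if (B > 0 && nrow(amb) >= 1) {
      rs <- resample(amb, c("flies", "eggs"))
      -log(colSums(rs$flies) / colSums(rs$eggs)) / t_end
    } else {
      numeric()
    }
    m0_boot[[h]] <- m0_b
    est <- add_row_est(est, "m0", h, NA_character_, NA_character_,
                       stage$estimate, boot_se(m0_b, nrow(amb)), nrow(amb),
                       merge_notes(stage$warning, se_note(nrow(amb))))
  }

  for (i in seq_len(nrow(timings_by_host))) {
    h <- timings_by_host$host[i]; tm <- timings_by_host$heat_timing[i]
    heat <- stratum(h, "none", tm)
    stage <- fit_heat_mortality(heat, m0_hat[[h]], constants)
    mt_b <- if (B > 0) {
      rs <- resample(heat, c("flies", "eggs"))
      -log(colSums(rs$flies) / colSums(rs$eggs)) - m0_boot[[h]] * t_end
    } else {
      numeric()
    }
    est <- add_row_est(est, "m_tau", h, NA_character_, tm,
                       stage$estimate, boot_se(mt_b, nrow(heat)), nrow(heat),
                       merge_notes(stage$warning, se_note(nrow(heat))))
  }

  pair_boot <- list()
  for (i in seq_len(nrow(pairs))) {
    h <- pairs$host[i]; p <- pairs$parasitoid[i]
    amb <- stratum(h, p, "ambient")
    a_stage <- fit_attack_rate(amb, m0_hat[[h]], constants)
    e_stage <- fit_conversion(amb, m0_hat[[h]], a_stage$estimate, constants)
    low_wasps <- if (sum(amb$wasps) < 10) {
      paste0("fewer than 10 wasps reared in stratum (", sum(amb$wasps), ")")
    } else {
      NA_character_
    }
    key <- paste(h, p, sep = "\r")
    if (B > 0) {
      rs <- resample(amb, c("flies", "wasps"))
      fbar_b <- colMeans(rs$flies)
      wbar_b <- colMeans(rs$wasps)
      base_b <- h0 * exp(-m0_boot[[h]] * t_end)
      a0_b <- pmax(0, -log(fbar_b / base_b) / p_wasps)
      denom_b <- base_b * (1 - exp(-a0_b * p_wasps))
      eps_b <- ifelse(denom_b > 0, pmin(1, wbar_b / denom_b), NA_real_)
      pair_boot[[key]] <- list(wtot_b = colSums(rs$wasps),
                               denomtot_b = nrow(amb) * denom_b,
                               a0_b = a0_b, eps_b = eps_b)
    } else {
      pair_boot[[key]] <- list(a0_b = numeric(), eps_b = numeric())
    }
    est <- add_row_est(est, "a0", h, p, NA_character_,
                       a_stage$estimate,
                       boot_se(pair_boot[[key]]$a0_b, nrow(amb)), nrow(amb),
                       merge_notes(a_stage$warning, se_note(nrow(amb))))
    est <- add_row_est(est, "epsilon", h, p, NA_character_,
                       e_stage$estimate,
                       boot_se(pair_boot[[key]]$eps_b, nrow(amb)), nrow(amb),
                       merge_notes(e_stage$warning, low_wasps, se_note(nrow(amb))))
  }

  if (epsilon_by == "parasitoid" && nrow(pairs) > 0) {
    # One epsilon per parasitoid: observed wasps over expected infections at
    # epsilon = 1, summed across host strata; reduces to the per-pair form
    # for a single host.
    for (p in sort(unique(pairs$parasitoid))) {
      hp <- filter(pairs, .data$parasitoid == p)
      wtot <- 0; denomtot <- 0
      wtot_b <- if (B > 0) numeric(B) else numeric()
      denomtot_b <- if (B > 0) numeric(B) else numeric()
      n_tot <- 0L
      for (h in hp$host) {
        amb <- stratum(h, p, "ambient")
        a0_hp <- est$estimate[est$param == "a0" & est$host == h &
                                est$parasitoid == p]
        denom <- h0 * exp(-m0_hat[[h]] * t_end) * (1 - exp(-a0_hp * p_wasps))
        wtot <- wtot + sum(amb$wasps)
        denomtot <- denomtot + nrow(amb) * denom
        n_tot <- n_tot + nrow(amb)
        if (B > 0) {
          key <- paste(h, p, sep = "\r")
          wtot_b <- wtot_b + pair_boot[[key]]$wtot_b
          denomtot_b <- denomtot_b + pair_boot[[key]]$denomtot_b
        }
      }
      eps_pool <- if (denomtot > 0) min(1, wtot / denomtot) else 0
      eps_pool_b <- ifelse(denomtot_b > 0, pmin(1, wtot_b / denomtot_b), NA_real_)
      pooled_note <- merge_notes(
        "epsilon pooled across hosts",
        if (wtot < 10) paste0("fewer than 10 wasps reared in stratum (", wtot, ")") else NA_character_,
        se_note(n_tot))
      est$estimate[est$param == "epsilon" & est$parasitoid == p] <- eps_pool
      est$se[est$param == "epsilon" & est$parasitoid == p] <-
        boot_se(eps_pool_b, n_tot)
      est$warning[est$param == "epsilon" & est$parasitoid == p] <- pooled_note
    }
  }

  params <- emergence_params(
    m0 = setNames(est$estimate[est$param == "m0"], est$host[est$param == "m0"]),
    m_tau = if (any(est$param == "m_tau")) {
      tibble(host = est$host[est$param == "m_tau"],
             heat_timing = est$heat_timing[est$param == "m_tau"],
             value = est$estimate[est$param == "m_tau"])
    },
    a0 = if (any(est$param == "a0")) {
      tibble(host = est$host[est$param == "a0"],
             parasitoid = est$parasitoid[est$param == "a0"],
             value = est$estimate[est$param == "a0"])
    },
    epsilon = if (any(est$param == "epsilon")) {
      tibble(host = est$host[est$param == "epsilon"],
             parasitoid = est$parasitoid[est$param == "epsilon"],
             value = est$estimate[est$param == "epsilon"])
    }
  )
  structure(
    list(params = params, estimates = est, n_bootstrap = B,
         epsilon_by = epsilon_by, constants = constants),
    class = "emergence_fit"
  )
}

#' @export
print.emergence_fit <- function(x, ...) {
  cat("<emergence_fit>\n")
  cat("  parameters fitted: ", nrow(x$estimates), "\n")
  cat("  bootstrap resamples: ", x$n_bootstrap, "\n")
  n_warn <- sum(!is.na(x$estimates$warning))
  cat("  keys with notes: ", n_warn, "\n")
  print(tidy(x), n = 12)
  invisible(x)
}

#' Tidy an emergence-model fit
#'
#' @param x An `emergence_fit` from [fit_all()].
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter key: `param`, `host`,
#'   `parasitoid`, `heat_timing`, `estimate`, `std.error`, `n_vials`,
#'   `warning`.
#' @method tidy emergence_fit
#' @export
tidy.emergence_fit <- function(x, ...) {
  rename(x$estimates, std.error = "se")
}

#' Glance at an emergence-model fit
#'
#' @param x An `emergence_fit` from [fit_all()].
#' @param ... Unused.
#' @return A one-row tibble: number of fitted keys, hosts, pairs, keys with
#'   warnings, and bootstrap resamples used.
#' @method glance emergence_fit
#' @export
glance.emergence_fit <- function(x, ...) {
  tibble(
    n_parameters = nrow(x$estimates),
    n_hosts = length(unique(x$estimates$host[x$estimates$param == "m0"])),
    n_pairs = sum(x$estimates$param == "a0"),
    n_warnings = sum(!is.na(x$estimates$warning)),
    n_bootstrap = x$n_bootstrap
  )
}

#' Write / read a fit as JSON, or flatten it to CSV
#'
#' `write_fit()` serializes the estimates table together with the design
#' constants so a fit can be reloaded with `read_fit()` in a later session
#' (e.g. between pipeline stages). `write_fit_csv()` writes the flat
#' key/estimate/SE table for spreadsheets.
#'
#' @param fit An `emergence_fit`.
#' @param path Output path (`.json` for write/read, `.csv` for the flat table).
#' @return `path`, invisibly (`read_fit()` returns the `emergence_fit`).
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "emergence_fit"))
  consts <- unclass(fit$constants)
  consts$heat_days <- as.list(consts$heat_days)
  obj <- list(
    estimates = fit$estimates,
    n_bootstrap = fit$n_bootstrap,
    epsilon_by = fit$epsilon_by,
    constants = consts
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("Fit file not found: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  est <- as_tibble(obj$estimates)
  for (cl in fit_key_cols) {
    if (!cl %in% names(est)) est[[cl]] <- NA_character_
    est[[cl]] <- as.character(est[[cl]])
  }
  if (!"warning" %in% names(est)) est$warning <- NA_character_
  est$warning <- as.character(est$warning)
  if (!"se" %in% names(est)) est$se <- NA_real_
  est$se <- as.numeric(est$se)
  consts <- obj$constants
  consts$heat_days <- unlist(consts$heat_days)
  constants <- do.call(design_constants, consts)
  params <- emergence_params(
    m0 = setNames(est$estimate[est$param == "m0"], est$host[est$param == "m0"]),
    m_tau = if (any(est$param == "m_tau")) {
      tibble(host = est$host[est$param == "m_tau"],
             heat_timing = est$heat_timing[est$param == "m_tau"],
             value = est$estimate[est$param == "m_tau"])
    },
    a0 = if (any(est$param == "a0")) {
      tibble(host = est$host[est$param == "a0"],
             parasitoid = est$parasitoid[est$param == "a0"],
             value = est$estimate[est$param == "a0"])
    },
    epsilon = if (any(est$param == "epsilon")) {
      tibble(host = est$host[est$param == "epsilon"],
             parasitoid = est$parasitoid[est$param == "epsilon"],
             value = est$estimate[est$param == "epsilon"])
    }
  )
  structure(
    list(params = params, estimates = est,
         n_bootstrap = as.integer(obj$n_bootstrap),
         epsilon_by = obj$epsilon_by, constants = constants),
    class = "emergence_fit"
  )
}

#' @rdname write_fit
#' @export
write_fit_csv <- function(fit, path) {
  readr::write_csv(tidy(fit), path, progress = FALSE)
  invisible(path)
}
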