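#' Control-emergence denominator for the response metrics
#'
#' The host-survival and parasitism-rate metrics are scaled by the mean
#' number of adult flies reared without parasitoids for the same host
#' species and heat-timing treatment, so differences in the metrics reflect
#' parasitism (or its interaction with heat), not host availability.
#'
#' @param vials Full vial tibble.
#' @param host Host species label.
#' @param heat_timing Heat-timing label.
#' @return The mean fly count over the matching no-parasitoid vials.
#' @export
control_denominator <- function(vials, host, heat_timing) {
  ctrl <- filter(as_tibble(vials), .data$parasitoid == "none",
                 .data$host == !!host, .data$heat_timing == !!heat_timing)
  if (nrow(ctrl) == 0) {
    abort_validation(paste0("No no-parasitoid control vials for (",
                            host, ", ", heat_timing, ")."))
  }
  d <- mean(ctrl$flies)
  if (d == 0) {
    abort_degenerate(paste0("Control emergence is zero for (", host, ", ",
                            heat_timing, "); rates are undefined."))
  }
  d
}

#' Host survival and parasitism rate for single vials
#'
#' `host_survival()` is the fly count of a parasitoid-exposed vial divided
#' by the matching control denominator, capped at 1 (values above 1 mean
#' more flies emerged with parasitoids than without). `parasitism_rate()`
#' is the wasp count over the same denominator, likewise capped at 1. Both
#' are vectorized.
#'
#' @param flies,wasps Non-negative counts.
#' @param denominator Mean control fly emergence (> 0); see
#'   [control_denominator()].
#' @return Proportions in \[0, 1\].
#' @examples
#' host_survival(30, 40)    # 0.75
#' host_survival(45, 40)    # capped at 1
#' parasitism_rate(17, 34)  # 0.5
#' @export
host_survival <- function(flies, denominator) {
  if (any(denominator <= 0)) abort_validation("`denominator` must be positive.")
  if (any(flies < 0)) abort_validation("`flies` must be non-negative.")
  pmin(flies / denominator, 1)
}

#' @rdname host_survival
#' @export
parasitism_rate <- function(wasps, denominator) {
  if (any(denominator <= 0)) abort_validation("`denominator` must be positive.")
  if (any(wasps < 0)) abort_validation("`wasps` must be non-negative.")
  pmin(wasps / denominator, 1)
}

#' Per-vial response-metric table
#'
#' Computes host survival (`hs`) and parasitism rate (`pr`) for every
#' parasitoid-exposed vial, with denominators matched on host species and
#' heat timing. No-parasitoid vials supply the denominators and are excluded
#' from the output. Flags note denominators built from fewer than three
#' control vials and host--parasitoid strata that reared fewer than ten
#' wasps in total (where `pr` is uninformative).
#'
#' @param vials Full vial tibble (validated).
#' @return A tibble with one row per parasitoid-exposed vial: the cell
#'   labels, `replicate`, `flies`, `wasps`, `denominator`, `hs`, `pr`,
#'   `flags` (`NA` when clean).
#' @examples
#' vials <- generate_vials(scenario_preset("additive_null"), seed = 1)
#' rates <- summarize_rates(vials)
#' dplyr::summarise(dplyr::group_by(rates, parasitoid),
#'                  mean_hs = mean(hs), mean_pr = mean(pr))
#' @export
summarize_rates <- function(vials) {
  vials <- validate_vials(vials)
  exposed <- filter(vials, .data$parasitoid != "none")
  if (nrow(exposed) == 0) {
    warn("No parasitoid-exposed vials; rate table is empty.")
  }
  controls <- filter(vials, .data$parasitoid == "none")
  denom_tbl <- summarise(group_by(controls, .data$host, .data$heat_timing),
                         denominator = mean(.data$flies),
                         n_control = n(), .groups = "drop")
  needed <- distinct(exposed, .data$host, .data$heat_timing)
  absent <- anti_join(needed, denom_tbl, by = c("host", "heat_timing"))
  if (nrow(absent) > 0) {
    abort_validation(paste0(
      "No no-parasitoid control vials for (host, heat_timing): ",
      comma(paste0("(", absent$host, ", ", absent$heat_timing, ")"))))
  }
  zero_denom <- filter(denom_tbl, .data$denominator == 0)
  zero_denom <- inner_join(zero_denom, needed, by = c("host", "heat_timing"))
  if (nrow(zero_denom) > 0) {
    abort_degenerate(paste0(
      "Control emergence is zero for (host, heat_timing): ",
      comma(paste0("(", zero_denom$host, ", ", zero_denom$heat_timing, ")"))))
  }
  wasp_totals <- summarise(group_by(exposed, .data$host, .data$parasitoid),
                           total_wasps = sum(.data$wasps), .groups = "drop")
  out <- left_join(exposed, denom_tbl, by = c("host", "heat_timing"))
  out <- left_join(out, wasp_totals, by = c("host", "parasitoid"))
  out <- mutate(
    out,
    hs = host_survival(.data$flies, .data$denominator),
    pr = parasitism_rate(.data$wasps, .data$denominator),
    flags = {
      f1 <- if_else(.data$n_control < 3, "few_control_vials", NA_character_)
      f2 <- if_else(.data$total_wasps < 10, "low_wasp_emergence", NA_character_)
      both <- paste(dplyr::coalesce(f1, ""), dplyr::coalesce(f2, ""))
      both <- trimws(gsub("  +", " ", both))
      if_else(both == "", NA_character_, gsub(" ", ";", both))
    }
  )
  select(out, all_of(c("host", "parasitoid", "heat_timing", "replicate",
                       "flies", "wasps", "denominator", "hs", "pr", "flags")))
}

#' Write the per-vial rate table to CSV
#'
#' @param rates Output of [summarize_rates()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path) {
  readr::write_csv(rates, path, progress = FALSE)
  invisible(path)
}
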