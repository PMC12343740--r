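#' Emergence model parameters
#'
#' Container for the parameter set of the single-generation emergence model:
#'
#' * `m0` -- baseline daily larval mortality per host (units: 1/day);
#' * `m_tau` -- cumulative differential mortality added by a 24-h heat
#'   exposure, indexed by host and heat-timing category (dimensionless
#'   exponent; 0 for ambient; may be negative when heat accelerates
#'   development and raises emergence);
#' * `a0` -- attack rate per female wasp over the foraging window, indexed
#'   by host--parasitoid pair (dimensionless per wasp);
#' * `epsilon` -- probability that an infected host yields an adult wasp,
#'   per pair, in \[0, 1\];
#' * `gamma` -- optional extra mortality exponent applied only when heat and
#'   parasitoids co-occur (default 0 everywhere: the additive null);
#' * `delta` -- optional multiplier on `a0` applied only when heat and
#'   parasitoids co-occur (default 1 everywhere).
#'
#' `gamma` and `delta` exist to inject known higher-order (synergistic or
#' antagonistic) effects into synthetic data; the additive null model has
#' `gamma = 0`, `delta = 1`.
#'
#' @param m0 Named numeric vector (host -> rate) or data frame with columns
#'   `host`, `value`.
#' @param m_tau Data frame with columns `host`, `heat_timing`, `value`, or
#'   `NULL` for no heat effect. Ambient entries default to 0 and need not be
#'   listed.
#' @param a0 Data frame with columns `host`, `parasitoid`, `value`, or
#'   `NULL` when the design has no parasitoids.
#' @param epsilon Data frame with columns `host`, `parasitoid`, `value`;
#'   required whenever `a0` is given.
#' @param gamma Optional data frame with columns `host`, `parasitoid`,
#'   `heat_timing`, `value`; unlisted combinations default to 0.
#' @param delta Optional data frame with the same columns; unlisted
#'   combinations default to 1.
#'
#' @return An object of class `emergence_params`.
#' @examples
#' emergence_params(
#'   m0 = c(birchii = 0.04),
#'   m_tau = data.frame(host = "birchii", heat_timing = "during", value = 0.5),
#'   a0 = data.frame(host = "birchii", parasitoid = "asobara", value = 0.25),
#'   epsilon = data.frame(host = "birchii", parasitoid = "asobara", value = 0.8)
#' )
#' @export
emergence_params <- function(m0, m_tau = NULL, a0 = NULL, epsilon = NULL,
                             gamma = NULL, delta = NULL) {
  m0 <- normalize_keyed(m0, "m0", key_cols = "host")
  m_tau <- normalize_keyed(m_tau, "m_tau", key_cols = c("host", "heat_timing"),
                           empty_ok = TRUE)
  a0 <- normalize_keyed(a0, "a0", key_cols = c("host", "parasitoid"),
                        empty_ok = TRUE)
  epsilon <- normalize_keyed(epsilon, "epsilon",
                             key_cols = c("host", "parasitoid"), empty_ok = TRUE)
  triple <- c("host", "parasitoid", "heat_timing")
  gamma <- normalize_keyed(gamma, "gamma", key_cols = triple, empty_ok = TRUE)
  delta <- normalize_keyed(delta, "delta", key_cols = triple, empty_ok = TRUE)

  if (any(m0$value < 0)) abort_validation("m0 must be non-negative.")
  if (any(a0$value < 0)) abort_validation("a0 must be non-negative.")
  if (any(epsilon$value < 0 | epsilon$value > 1)) {
    abort_validation("epsilon must lie in [0, 1].")
  }
  if (any(delta$value < 0)) abort_validation("delta must be non-negative.")
  if (nrow(a0) > 0 && nrow(epsilon) == 0) {
    abort_validation("epsilon must be supplied when a0 is.")
  }
  structure(
    list(m0 = m0, m_tau = m_tau, a0 = a0, epsilon = epsilon,
         gamma = gamma, delta = delta),
    class = "emergence_params"
  )
}

# Coerce a named vector or keyed data frame to tibble(key..., value).
normalize_keyed <- function(x, what, key_cols, empty_ok = FALSE) {
  if (is.null(x)) {
    if (!empty_ok) abort_validation(paste0("`", what, "` is required."))
    out <- tibble(!!!setNames(rep(list(character()), length(key_cols)), key_cols),
                  value = numeric())
    return(out)
  }
  if (is.numeric(x) && length(key_cols) == 1) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      abort_validation(paste0("`", what, "` vector must be named by ", key_cols, "."))
    }
    x <- tibble(!!key_cols := names(x), value = unname(x))
  }
  if (!is.data.frame(x)) {
    abort_validation(paste0("`", what, "` must be a named vector or data frame."))
  }
  missing_cols <- setdiff(c(key_cols, "value"), names(x))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("`", what, "` is missing columns: ", comma(missing_cols)))
  }
  x <- as_tibble(x)[, c(key_cols, "value")]
  if (anyDuplicated(x[key_cols])) {
    abort_validation(paste0("`", what, "` has duplicate keys."))
  }
  if (!is.numeric(x$value) || any(!is.finite(x$value))) {
    abort_validation(paste0("`", what, "` values must be finite numbers."))
  }
  x
}

#' @export
print.emergence_params <- function(x, ...) {
  cat("<emergence_params>\n")
  cat("  hosts:       ", comma(sort(unique(x$m0$host))), "\n")
  if (nrow(x$a0) > 0) {
    cat("  parasitoids: ", comma(sort(unique(x$a0$parasitoid))), "\n")
  }
  n_syn <- sum(x$gamma$value != 0) + sum(x$delta$value != 1)
  cat("  keys: m0 =", nrow(x$m0), "| m_tau =", nrow(x$m_tau),
      "| a0 =", nrow(x$a0), "| epsilon =", nrow(x$epsilon), "\n")
  cat("  higher-order terms:",
      if (n_syn == 0) "none (additive null)" else paste(n_syn, "non-null"), "\n")
  invisible(x)
}

#' @describeIn emergence_params Long tidy view: one row per parameter key
#'   with columns `param`, `host`, `parasitoid`, `heat_timing`, `value`.
#' @param x An `emergence_params` object.
#' @param ... Unused.
#' @method tidy emergence_params
#' @export
tidy.emergence_params <- function(x, ...) {
  pad <- function(df, param) {
    out <- tibble(
      param = rep(param, nrow(df)),
      host = df$host %||% rep(NA_character_, nrow(df)),
      parasitoid = if ("parasitoid" %in% names(df)) df$parasitoid else NA_character_,
      heat_timing = if ("heat_timing" %in% names(df)) df$heat_timing else NA_character_,
      value = df$value
    )
    out
  }
  bind_rows(
    pad(x$m0, "m0"), pad(x$m_tau, "m_tau"), pad(x$a0, "a0"),
    pad(x$epsilon, "epsilon"), pad(x$gamma, "gamma"), pad(x$delta, "delta")
  )
}

params_components <- c("m0", "m_tau", "a0", "epsilon", "gamma", "delta")

#' Write model parameters to JSON or YAML
#'
#' Serializes an `emergence_params` object as nested mappings keyed by level
#' labels (`m0` by host; `m_tau` by host then timing; `a0`/`epsilon` by host
#' then parasitoid; `gamma`/`delta` by host, parasitoid, then timing).
#' The format follows the file extension.
#'
#' @param params An `emergence_params` object.
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "emergence_params"))
  nest_one <- function(df, key_cols) {
    if (nrow(df) == 0) return(stats::setNames(list(), character()))
    if (length(key_cols) == 1) {
      return(as.list(setNames(df$value, df[[key_cols]])))
    }
    split_keys <- split(df[, -1, drop = FALSE], df[[key_cols[1]]])
    lapply(split_keys, nest_one, key_cols = key_cols[-1])
  }
  keys <- list(m0 = "host", m_tau = c("host", "heat_timing"),
               a0 = c("host", "parasitoid"), epsilon = c("host", "parasitoid"),
               gamma = c("host", "parasitoid", "heat_timing"),
               delta = c("host", "parasitoid", "heat_timing"))
  obj <- lapply(params_components, function(p) nest_one(params[[p]], keys[[p]]))
  names(obj) <- params_components
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read model parameters from JSON or YAML
#'
#' @param path Path written by [write_params()] (or hand-authored in the
#'   same nested-mapping layout).
#' @return An `emergence_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) {
    abort_validation(paste0("Parameter file not found: ", path))
  }
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  flatten_one <- function(node, key_cols) {
    if (length(node) == 0) return(NULL)
    if (length(key_cols) == 1) {
      return(tibble(!!key_cols[1] := names(node), value = as.numeric(unlist(node))))
    }
    rows <- map(names(node), function(k) {
      inner <- flatten_one(node[[k]], key_cols[-1])
      if (is.null(inner)) return(NULL)
      bind_cols(tibble(!!key_cols[1] := rep(k, nrow(inner))), inner)
    })
    out <- bind_rows(compact(rows))
    if (nrow(out) == 0) NULL else out
  }
  emergence_params(
    m0 = flatten_one(obj$m0, "host") %||%
      abort_validation("Parameter file lacks an m0 block."),
    m_tau = flatten_one(obj$m_tau, c("host", "heat_timing")),
    a0 = flatten_one(obj$a0, c("host", "parasitoid")),
    epsilon = flatten_one(obj$epsilon, c("host", "parasitoid")),
    gamma = flatten_one(obj$gamma, c("host", "parasitoid", "heat_timing")),
    delta = flatten_one(obj$delta, c("host", "parasitoid", "heat_timing"))
  )
}
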