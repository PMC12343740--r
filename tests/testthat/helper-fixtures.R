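# Shared fixtures: small vial tables and parameter sets built in code.

make_vials <- function(flies, wasps = 0, host = "simulans",
                       parasitoid = "none", heat_timing = "ambient",
                       eggs = 50) {
  n <- length(flies)
  tibble::tibble(
    host = rep_len(host, n),
    parasitoid = rep_len(parasitoid, n),
    heat_timing = rep_len(heat_timing, n),
    replicate = paste0("r", seq_len(n)),
    eggs = rep_len(eggs, n),
    flies = flies,
    wasps = rep_len(wasps, n)
  )
}

one_pair_params <- function(m0 = 0.02, m_tau = NULL, a0 = 0.1, epsilon = 0.8,
                            gamma = NULL, delta = NULL,
                            host = "simulans", parasitoid = "asobara") {
  emergence_params(
    m0 = stats::setNames(m0, host),
    m_tau = m_tau,
    a0 = data.frame(host = host, parasitoid = parasitoid, value = a0),
    epsilon = data.frame(host = host, parasitoid = parasitoid, value = epsilon),
    gamma = gamma,
    delta = delta
  )
}

one_cell <- function(host = "simulans", parasitoid = "asobara",
                     heat_timing = "ambient") {
  tibble::tibble(host = host, parasitoid = parasitoid,
                 heat_timing = heat_timing)
}

# Random single-pair parameter draws for property tests. m_tau is drawn so
# the total mortality exponent m0*T + m_tau stays non-negative, the domain
# on which the fates are probabilities (fitted values satisfy this by
# construction).
random_pair_params <- function(t_end = 8) {
  m0 <- stats::runif(1, 0, 0.2)
  one_pair_params(
    m0 = m0,
    m_tau = data.frame(host = "simulans",
                       heat_timing = c("before", "during", "after"),
                       value = stats::runif(3, -m0 * t_end, 1)),
    a0 = stats::runif(1, 0, 1),
    epsilon = stats::runif(1, 0, 1)
  )
}

# Literal evaluation of the additive-null emergence expectations, written
# independently of fate_probabilities() as the test oracle.
literal_null_expectation <- function(h0, m0, t_end, m_tau, a0, p, eps) {
  f <- h0 * exp(-m0 * t_end - m_tau) * exp(-a0 * p)
  w <- eps * h0 * exp(-m0 * t_end - m_tau) * (1 - exp(-a0 * p))
  c(flies = f, wasps = w)
}
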