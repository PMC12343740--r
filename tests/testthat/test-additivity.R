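const <- design_constants()

test_that("overlap rule flags exactly the disjoint intervals, symmetrically", {
  iv <- function(lo, hi) list(lower95 = lo, upper95 = hi)
  expect_equal(overlap_verdict(iv(10, 20), iv(15, 25)), "additive")
  expect_equal(overlap_verdict(iv(10, 12), iv(20, 25)), "higher_order")
  # boundary touching counts as overlap (conservative toward the null)
  expect_equal(overlap_verdict(iv(10, 20), iv(20, 25)), "additive")
  # nested intervals overlap
  expect_equal(overlap_verdict(iv(10, 30), iv(15, 20)), "additive")
  # symmetry over random interval pairs
  withr::local_seed(51)
  for (i in 1:100) {
    a <- sort(runif(2, 0, 50)); b <- sort(runif(2, 0, 50))
    expect_identical(overlap_verdict(iv(a[1], a[2]), iv(b[1], b[2])),
                     overlap_verdict(iv(b[1], b[2]), iv(a[1], a[2])))
  }
  expect_error(overlap_verdict(iv(20, 10), iv(0, 5)),
               class = "flywasp_validation_error")
})

test_that("observed intervals are seeded bootstrap summaries of replicate means", {
  flat <- make_vials(flies = rep(30, 6), wasps = rep(4, 6),
                     parasitoid = "asobara")
  iv <- observed_interval(flat, n_boot = 500, seed = 1)
  expect_equal(iv$lower95, c(30, 4))
  expect_equal(iv$upper95, c(30, 4))

  two <- make_vials(flies = c(20, 40), parasitoid = "asobara")
  iv2 <- observed_interval(two, n_boot = 2000, seed = 2)
  fl <- iv2[iv2$channel == "flies", ]
  expect_equal(fl$mean, 30)
  expect_gte(fl$lower95, 20)
  expect_lte(fl$upper95, 40)

  a <- observed_interval(two, n_boot = 1000, seed = 3)
  b <- observed_interval(two, n_boot = 1000, seed = 3)
  expect_identical(a, b)

  expect_warning(one <- observed_interval(make_vials(flies = 25)),
                 "degenerate")
  expect_equal(one$lower95[1], 25)
  expect_equal(one$upper95[1], 25)
})

test_that("null projection collapses to a point in the deterministic limit", {
  fit <- list(params = one_pair_params(m0 = 0, a0 = 0), constants = const)
  iv <- project_null(fit, one_cell(parasitoid = "none"), const,
                     n_sims = 200, seed = 4)
  expect_equal(iv$lower95, c(50, 0))
  expect_equal(iv$upper95, c(50, 0))
  expect_equal(iv$mean, c(50, 0))
})

test_that("null projection is seeded and stable in n_sims", {
  fit <- list(params = one_pair_params(), constants = const)
  a <- project_null(fit, one_cell(), const, n_sims = 2000, seed = 5)
  b <- project_null(fit, one_cell(), const, n_sims = 2000, seed = 5)
  expect_identical(a, b)
  big <- project_null(fit, one_cell(), const, n_sims = 20000, seed = 6)
  # Monte-Carlo convergence: interval endpoints agree across sizes to
  # within the sampling noise of a 6-vial mean of multinomial counts
  expect_equal(a$lower95, big$lower95, tolerance = 0.05)
  expect_equal(a$upper95, big$upper95, tolerance = 0.05)
  expect_error(project_null(fit, one_cell(), const, n_sims = 50),
               class = "flywasp_validation_error")
  expect_error(project_null(fit, one_cell(host = "unknown"), const,
                            n_sims = 200),
               class = "flywasp_config_error")
})

test_that("observed means fall inside their own null projection when the null is true", {
  # calibration at the single-cell level: data generated from the projected
  # model should rarely escape the simulated interval
  params <- one_pair_params()
  inside <- purrr::map_lgl(1:100, function(i) {
    obs <- simulate_experiment(one_cell(), params, const, n_replicates = 6,
                               seed = 1000 + i)
    iv <- project_null(list(params = params), one_cell(), const,
                       n_sims = 1000, seed = 2000 + i)
    fl <- iv[iv$channel == "flies", ]
    m <- mean(obs$flies)
    m >= fl$lower95 && m <= fl$upper95
  })
  expect_gte(mean(inside), 0.90)
})

test_that("the suite tests every combined cell on both channels", {
  vials <- generate_vials("additive_null", seed = 61)
  fit <- fit_all(vials, const, n_bootstrap = 0)
  verdicts <- run_additivity_suite(vials, fit, const, n_sims = 500,
                                   n_boot = 500, seed = 62)
  expect_s3_class(verdicts, "additivity_verdicts")
  expect_equal(nrow(verdicts), 27 * 2) # 9 pairs x 3 timings x 2 channels
  expect_setequal(unique(verdicts$channel), c("flies", "wasps"))
  expect_true(all(verdicts$verdict %in% c("additive", "higher_order")))
  expect_true(all(verdicts$obs_lower <= verdicts$obs_mean + 1e-9))
  expect_true(all(verdicts$sim_lower <= verdicts$sim_upper))
  # no combined cells at all -> empty result with a warning
  controls <- dplyr::filter(vials, parasitoid == "none" |
                              heat_timing == "ambient")
  expect_warning(empty <- run_additivity_suite(controls, fit, const,
                                               n_sims = 500, n_boot = 500),
                 "No combined")
  expect_equal(nrow(empty), 0)
})

test_that("injected antagonism is detected on the wasp channel it targets", {
  vials <- generate_vials("antagonism_parasitism", seed = 63)
  fit <- fit_all(vials, const, n_bootstrap = 0)
  verdicts <- run_additivity_suite(vials, fit, const, n_sims = 1000,
                                   n_boot = 1000, seed = 64)
  wasps <- dplyr::filter(dplyr::as_tibble(verdicts), channel == "wasps")
  affected <- dplyr::filter(wasps, heat_timing %in% c("during", "after"))
  unaffected <- dplyr::filter(wasps, heat_timing == "before")
  expect_gt(mean(affected$verdict == "higher_order"), 0.5)
  expect_lt(mean(unaffected$verdict == "higher_order"), 0.3)
})

test_that("detection rate grows with the size of the injected effect", {
  # power monotonicity over a 3-point antagonism grid, averaged over seeds
  rate_for_delta <- function(delta_val, seeds) {
    mean(purrr::map_dbl(seeds, function(s) {
      sc <- scenario_preset("additive_null")
      truth <- emergence_params(
        m0 = stats::setNames(sc$truth$m0$value, sc$truth$m0$host),
        m_tau = sc$truth$m_tau, a0 = sc$truth$a0, epsilon = sc$truth$epsilon,
        delta = dplyr::mutate(
          tidyr::expand_grid(host = unique(sc$truth$m0$host),
                             parasitoid = unique(sc$truth$a0$parasitoid),
                             heat_timing = "during"),
          value = delta_val))
      sc$truth <- truth
      vials <- generate_vials(sc, seed = s)
      fit <- fit_all(vials, const, n_bootstrap = 0)
      v <- run_additivity_suite(vials, fit, const, n_sims = 500,
                                n_boot = 500, seed = s + 1)
      v <- dplyr::filter(dplyr::as_tibble(v), channel == "wasps",
                         heat_timing == "during")
      mean(v$verdict == "higher_order")
    }))
  }
  seeds <- 70 + 1:5
  r_null <- rate_for_delta(1, seeds)
  r_mid <- rate_for_delta(0.4, seeds)
  r_strong <- rate_for_delta(0.05, seeds)
  expect_lte(r_null, r_mid)
  expect_lte(r_mid, r_strong)
  expect_gt(r_strong, 0.9)
})

test_that("verdict tables write to CSV and plot on both channels", {
  vials <- generate_vials("antagonism_parasitism", seed = 65)
  fit <- fit_all(vials, const, n_bootstrap = 0)
  verdicts <- run_additivity_suite(vials, fit, const, n_sims = 500,
                                   n_boot = 500, seed = 66)
  path <- withr::local_tempfile(fileext = ".csv")
  write_verdicts(verdicts, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(verdicts))
  gg <- autoplot(verdicts)
  expect_s3_class(gg, "ggplot")
  gg2 <- plot_additivity(verdicts, channel = "wasps")
  expect_s3_class(gg2, "ggplot")
})
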