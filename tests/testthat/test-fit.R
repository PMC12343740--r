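const <- design_constants()

test_that("baseline mortality inverts the pooled control proportion", {
  # full survival sits on the m0 = 0 boundary
  full <- fit_baseline_mortality(make_vials(flies = rep(50, 6)), const)
  expect_equal(full$estimate, 0)
  # frozen hand evaluation: 204 flies from 300 eggs over 8 days
  est <- fit_baseline_mortality(make_vials(flies = c(34, 30, 38, 33, 35, 34)),
                                const)
  expect_equal(est$estimate, 0.0482078101015, tolerance = 1e-10)
  expect_equal(est$estimate, -log(0.68) / 8, tolerance = 1e-12)
  # single-vial stratum is fitted but marked
  one <- fit_baseline_mortality(make_vials(flies = 50), const)
  expect_equal(one$estimate, 0)
  expect_match(one$warning, "SE unavailable")
  # degenerate and impossible inputs
  expect_error(fit_baseline_mortality(make_vials(flies = rep(0, 6)), const),
               class = "flywasp_degenerate_error")
  expect_error(fit_baseline_mortality(make_vials(flies = rep(60, 6)), const),
               class = "flywasp_validation_error")
})

test_that("heat mortality differential is the survival log-ratio to ambient", {
  m0 <- -log(0.68) / 8
  same <- fit_heat_mortality(make_vials(flies = rep(34, 6),
                                        heat_timing = "during"), m0, const)
  expect_equal(same$estimate, 0, tolerance = 1e-12)
  # frozen: ambient mean 34, heat mean 25
  harmed <- fit_heat_mortality(make_vials(flies = rep(25, 6),
                                          heat_timing = "during"), m0, const)
  expect_equal(harmed$estimate, 0.307484699748, tolerance = 1e-10)
  # emergence above ambient: negative m_tau kept, with a note
  helped <- fit_heat_mortality(make_vials(flies = rep(40, 6),
                                          heat_timing = "during"), m0, const)
  expect_lt(helped$estimate, 0)
  expect_match(helped$warning, "survival benefit")
  expect_error(fit_heat_mortality(make_vials(flies = rep(0, 6),
                                             heat_timing = "during"),
                                  m0, const),
               class = "flywasp_degenerate_error")
})

test_that("attack rate inverts mean fly escape, clamped at zero", {
  m0 <- -log(0.68) / 8 # no-parasitoid expectation 34 flies
  none <- fit_attack_rate(make_vials(flies = rep(34, 6),
                                     parasitoid = "asobara"), m0, const)
  expect_equal(none$estimate, 0, tolerance = 1e-12)
  est <- fit_attack_rate(make_vials(flies = rep(20, 6),
                                    parasitoid = "asobara"), m0, const)
  expect_equal(est$estimate, 0.176876083687, tolerance = 1e-10)
  expect_equal(est$estimate, log(34 / 20) / 3, tolerance = 1e-12)
  over <- fit_attack_rate(make_vials(flies = rep(40, 6),
                                     parasitoid = "asobara"), m0, const)
  expect_equal(over$estimate, 0)
  expect_match(over$warning, "clamped to 0")
  expect_error(fit_attack_rate(make_vials(flies = rep(0, 6),
                                          parasitoid = "asobara"), m0, const),
               class = "flywasp_degenerate_error")
})

test_that("conversion probability inverts mean wasp emergence with [0,1] clamp", {
  m0 <- -log(0.68) / 8
  a0 <- log(34 / 20) / 3
  vials <- make_vials(flies = rep(20, 6), wasps = rep(11.2, 6),
                      parasitoid = "asobara")
  est <- fit_conversion(vials, m0, a0, const)
  expect_equal(est$estimate, 0.8, tolerance = 1e-10) # 11.2 / (34 - 20)
  zero <- fit_conversion(make_vials(flies = rep(20, 6), wasps = 0,
                                    parasitoid = "asobara"), m0, a0, const)
  expect_equal(zero$estimate, 0)
  over <- fit_conversion(make_vials(flies = rep(20, 6), wasps = rep(15, 6),
                                    parasitoid = "asobara"), m0, a0, const)
  expect_equal(over$estimate, 1)
  expect_match(over$warning, "clamped to 1")
  expect_error(fit_conversion(make_vials(flies = rep(20, 6), wasps = rep(5, 6),
                                         parasitoid = "asobara"),
                              m0, 0, const),
               class = "flywasp_degenerate_error")
})

test_that("fit_all reproduces each fitting stratum's mean emergence exactly", {
  vials <- generate_vials("additive_null", seed = 31)
  fit <- fit_all(vials, const, n_bootstrap = 0)
  expect_true(all(is.na(fit$estimates$se)))
  # self-consistency: the closed forms are exact moment inversions
  strata <- dplyr::filter(
    vials, parasitoid == "none" | heat_timing == "ambient")
  obs <- dplyr::summarise(
    dplyr::group_by(strata, host, parasitoid, heat_timing),
    flies = mean(flies), wasps = mean(wasps), .groups = "drop")
  pred <- expected_emergence(obs[, 1:3], fit$params, const)
  clamped <- any(grepl("clamp", fit$estimates$warning))
  expect_false(clamped)
  expect_equal(pred$flies_expected, obs$flies, tolerance = 1e-9)
  expect_equal(pred$wasps_expected, obs$wasps, tolerance = 1e-9)
})

test_that("fit_all recovers the generating truth from noiseless means", {
  truth <- default_truth()
  cells <- enumerate_design()
  ctrl <- dplyr::filter(cells, parasitoid == "none" | heat_timing == "ambient")
  exp_counts <- expected_emergence(ctrl, truth, const)
  noiseless <- dplyr::mutate(
    exp_counts, replicate = "r1", eggs = 50,
    flies = flies_expected, wasps = wasps_expected)
  fit <- fit_all(noiseless, const, n_bootstrap = 0)
  want <- tidy(truth)
  got <- dplyr::left_join(
    want[want$param %in% c("m0", "m_tau", "a0", "epsilon"), ],
    tidy(fit), by = c("param", "host", "parasitoid", "heat_timing"))
  expect_equal(got$estimate, got$value, tolerance = 1e-9)
})

test_that("fit_all errors when a required control stratum is absent", {
  vials <- generate_vials("additive_null", seed = 32)
  broken <- dplyr::filter(vials, !(host == "birchii" & parasitoid == "none" &
                                     heat_timing == "ambient"))
  expect_error(fit_all(broken, const, n_bootstrap = 0),
               "birchii, none, ambient", class = "flywasp_validation_error")
})

test_that("bootstrap SEs are reproducible, positive, and shrink with replication", {
  vials6 <- generate_vials("additive_null", seed = 33)
  f1 <- fit_all(vials6, const, n_bootstrap = 200, seed = 7)
  f2 <- fit_all(vials6, const, n_bootstrap = 200, seed = 7)
  expect_equal(f1$estimates, f2$estimates)
  expect_true(all(f1$estimates$se > 0))
  vials60 <- generate_vials("additive_null", n_replicates = 60, seed = 33)
  f3 <- fit_all(vials60, const, n_bootstrap = 200, seed = 7)
  expect_lt(median(f3$estimates$se / f1$estimates$se), 0.6)
})

test_that("parameter recovery improves as replicates per cell grow", {
  rel_err_median <- function(n_rep, seed) {
    errs <- purrr::map_dbl(seq_len(8), function(i) {
      vials <- generate_vials("additive_null", n_replicates = n_rep,
                              seed = seed + i)
      fit <- fit_all(vials, const, n_bootstrap = 0)
      truth <- tidy(default_truth())
      truth <- truth[truth$param %in% c("m0", "a0", "epsilon"), ]
      got <- dplyr::left_join(truth, tidy(fit),
                              by = c("param", "host", "parasitoid",
                                     "heat_timing"))
      median(abs(got$estimate - got$value) / abs(got$value))
    })
    median(errs)
  }
  e6 <- rel_err_median(6, 400)
  e60 <- rel_err_median(60, 500)
  e600 <- rel_err_median(600, 600)
  expect_lt(e60, e6)
  expect_lt(e600, e60)
})

test_that("epsilon can be pooled per parasitoid species", {
  vials <- generate_vials("additive_null", seed = 35)
  fit <- fit_all(vials, const, n_bootstrap = 0, epsilon_by = "parasitoid")
  eps <- dplyr::filter(fit$estimates, param == "epsilon")
  per_species <- split(eps$estimate, eps$parasitoid)
  for (v in per_species) expect_equal(max(v) - min(v), 0, tolerance = 1e-12)
  expect_true(all(grepl("pooled", eps$warning)))
})

test_that("fits round-trip through JSON and flatten to CSV", {
  vials <- generate_vials("additive_null", seed = 36)
  fit <- fit_all(vials, const, n_bootstrap = 50, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  back <- read_fit(path)
  expect_equal(back$estimates$estimate, fit$estimates$estimate)
  expect_equal(back$constants$eggs_per_vial, 50L)
  pred1 <- expected_emergence(one_cell(host = "birchii",
                                       heat_timing = "during"),
                              fit$params, const)
  pred2 <- expected_emergence(one_cell(host = "birchii",
                                       heat_timing = "during"),
                              back$params, const)
  expect_equal(pred1$flies_expected, pred2$flies_expected)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_fit_csv(fit, csv)
  flat <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(flat), nrow(fit$estimates))
  expect_true(all(c("param", "estimate", "std.error") %in% names(flat)))
})

test_that("tidy and glance summarise the fit object", {
  vials <- generate_vials("additive_null", seed = 37)
  fit <- fit_all(vials, const, n_bootstrap = 0)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$param == "m0"), 3)
  expect_equal(sum(td$param == "m_tau"), 9)
  expect_equal(sum(td$param == "a0"), 9)
  gl <- glance(fit)
  expect_equal(gl$n_parameters, 30)
  expect_equal(gl$n_pairs, 9)
})
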