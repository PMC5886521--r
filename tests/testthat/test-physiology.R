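test_that("theoretical yield coefficients follow formula-mass arithmetic", {
  expect_equal(round(theoretical_yield_coeff("cellobiose"), 2), 0.54)
  expect_equal(theoretical_yield_coeff("cellobiose"), 4 * 46.069 / 342.297)
  expect_equal(theoretical_yield_coeff("glucose"), 2 * 46.069 / 180.156)
  expect_equal(ethanol_stoichiometry("glucose"), 2)
  expect_equal(ethanol_stoichiometry("cellobiose"), 4)
  expect_error(theoretical_yield_coeff("sucrose"), regexp = "cellobiose",
               class = "rex_input_error")
})

test_that("percent theoretical yield divides by the stoichiometric maximum", {
  rec <- tibble::tibble(
    strain = "wt", substrate = "cellobiose",
    substrate_initial = 5, substrate_final = 0, ethanol = 1.077
  )
  y <- percent_theoretical_yield(rec)
  expect_equal(y$percent_theoretical, 40, tolerance = 0.005)
  expect_false(y$flag_over_100)

  zero <- percent_theoretical_yield(dplyr::mutate(rec, ethanol = 0))
  expect_equal(zero$percent_theoretical, 0)

  over <- percent_theoretical_yield(dplyr::mutate(rec, ethanol = 3.0))
  expect_true(over$flag_over_100)

  expect_error(percent_theoretical_yield(
    dplyr::mutate(rec, substrate_final = 5)), class = "rex_input_error")
})

test_that("growth fitting recovers exponential and logistic dynamics", {
  t <- seq(0, 10, by = 0.05)
  exp_series <- tibble::tibble(time_h = t, od600 = 0.05 * exp(0.31 * t))
  fit <- fit_growth(exp_series)
  expect_equal(fit$mu_max, 0.31, tolerance = 0.01)

  flat <- fit_growth(tibble::tibble(time_h = t, od600 = rep(0.2, length(t))))
  expect_equal(flat$mu_max, 0)

  lg <- gen_od_curves(c(s = 0.31), K = 0.43, t_max = 100, seed = 1)
  lfit <- fit_growth(lg$od_table[, c("time_h", "od600")])
  expect_equal(lfit$max_od, 0.43, tolerance = 0.005)
  expect_equal(lfit$mu_max, 0.31, tolerance = 0.01)

  expect_error(fit_growth(tibble::tibble(time_h = t, od600 = 0)),
               class = "rex_input_error")
  expect_error(fit_growth(exp_series[1:3, ], window = 5),
               class = "rex_input_error")
  expect_error(fit_growth(tibble::tibble(time_h = c(1, 1, 2, 3, 4),
                                         od600 = 1:5)),
               class = "rex_input_error")
})

test_that("growth recovery holds across the observed rate range", {
  mus <- c(0.06, 0.10, 0.16, 0.31, 0.38)
  for (mu in mus) {
    g <- gen_od_curves(setNames(mu, "s"), t_max = 60, seed = 1)
    fit <- fit_growth(g$od_table[, c("time_h", "od600")])
    expect_equal(fit$mu_max, mu, tolerance = 0.01)
  }
  # 2% multiplicative noise: wider windows and a relaxed guard keep the
  # estimate within 10%
  for (mu in c(0.06, 0.38)) {
    g <- gen_od_curves(setNames(mu, "s"), t_max = 60, noise_sd = 0.02,
                       seed = 17)
    fit <- fit_growth(g$od_table[, c("time_h", "od600")],
                      window = 80, min_r2 = 0.8)
    expect_equal(fit$mu_max, mu, tolerance = 0.10)
  }
})

test_that("growth fits expose tidy, glance and autoplot views", {
  t <- seq(0, 5, by = 0.1)
  fit <- fit_growth(tibble::tibble(time_h = t, od600 = 0.02 * exp(0.3 * t)))
  expect_named(glance(fit),
               c("mu_max", "max_od", "window_start", "r_squared", "window"))
  expect_true(all(c("window_start", "slope", "r_squared") %in%
                    names(tidy(fit))))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("ADH specific activity follows Beer-Lambert proportionality", {
  assay <- tibble::tibble(slope = 0.622, extinction_coeff = 6.22,
                          path_length = 1, reaction_volume = 1,
                          protein_mass = 0.1)
  expect_equal(adh_specific_activity(assay)$specific_activity, 1.0)
  expect_equal(adh_specific_activity(
    dplyr::mutate(assay, slope = 0))$specific_activity, 0)

  withr::with_seed(2, {
    rand <- tibble::tibble(
      slope = runif(20, 0.01, 2), extinction_coeff = runif(20, 1, 10),
      path_length = runif(20, 0.2, 2), reaction_volume = runif(20, 0.5, 2),
      protein_mass = runif(20, 0.01, 1)
    )
  })
  base <- adh_specific_activity(rand)$specific_activity
  doubled_slope <- adh_specific_activity(
    dplyr::mutate(rand, slope = slope * 2))$specific_activity
  doubled_protein <- adh_specific_activity(
    dplyr::mutate(rand, protein_mass = protein_mass * 2))$specific_activity
  expect_equal(doubled_slope, 2 * base)
  expect_equal(doubled_protein, base / 2)

  expect_error(adh_specific_activity(
    dplyr::mutate(assay, protein_mass = 0)), class = "rex_input_error")
})

test_that("standard curves convert slope to amplification efficiency", {
  copies <- 10^(3:8)
  perfect <- tibble::tibble(copies = copies,
                            cq = 40 - 3.32193 * log10(copies))
  sc <- fit_standard_curve(perfect)
  expect_equal(sc$slope, -3.32193, tolerance = 1e-6)
  expect_equal(sc$efficiency, 1.0, tolerance = 1e-3)
  expect_equal(sc$r_squared, 1.0, tolerance = 1e-9)

  two <- fit_standard_curve(tibble::tibble(copies = c(1e4, 1e5),
                                           cq = c(25, 21.6)))
  expect_equal(two$slope, -3.4)

  sc36 <- fit_standard_curve(tibble::tibble(copies = copies,
                                            cq = 40 - 3.6 * log10(copies)))
  expect_equal(sc36$efficiency, 10^(1 / 3.6) - 1, tolerance = 1e-9)
  expect_equal(sc36$efficiency, 0.895, tolerance = 1e-3)

  expect_error(fit_standard_curve(tibble::tibble(copies = rep(1e4, 3),
                                                 cq = c(25, 25.1, 24.9))),
               class = "rex_input_error")
  expect_error(fit_standard_curve(tibble::tibble(copies = c(1e3, 1e4),
                                                 cq = c(NA, 25))),
               class = "rex_input_error")
  expect_named(glance(sc),
               c("slope", "intercept", "efficiency", "r_squared", "n"))
  expect_s3_class(autoplot(sc), "ggplot")
})

test_that("qPCR quantification normalizes copies to the reference", {
  curve <- fit_standard_curve(tibble::tibble(
    copies = 10^(2:7), cq = 38 - log(10, 2) * log10(10^(2:7))))

  same <- tibble::tibble(target = c("adhE", "recA"), cq = c(24, 24))
  out <- quantify_and_normalize(same, curve)
  expect_equal(out$ratio[out$target == "adhE"], 1)

  ten <- gen_qpcr(c(adhE = 10), noise_sd = 0, seed = 1)
  out10 <- quantify_and_normalize(ten$samples, fit_standard_curve(ten$standards))
  expect_equal(out10$ratio[out10$target == "adhE"], 10, tolerance = 1e-9)

  # replicates are averaged on the copy scale
  reps <- tibble::tibble(target = c("adhE", "adhE", "recA"),
                         cq = c(23, 25, 24))
  outr <- quantify_and_normalize(reps, curve)
  copies_of <- function(cq) 10^((cq - curve$intercept) / curve$slope)
  expect_equal(outr$copies[outr$target == "adhE"],
               mean(copies_of(c(23, 25))))

  expect_error(quantify_and_normalize(
    tibble::tibble(target = "adhE", cq = 24), curve),
    regexp = "recA", class = "rex_input_error")
})
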