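# AIC selection, elimination rules and Monte-Carlo error calibration.

# A minimal hand-built fit object for selection/elimination tests.
fake_fit <- function(model, chi2, k, pv = NULL, converged = TRUE) {
  if (is.null(pv)) {
    pv <- data.frame(symbol = "r20", spin_id = "A:N", field = 600,
                     lower = 0.1, upper = 200, grid = "seed", value = 10,
                     stringsAsFactors = FALSE)
  }
  structure(list(model = model, pv = pv, chi2 = chi2, k = k, n = 30,
                 aic = aic(chi2, k), converged = converged,
                 eliminated = FALSE, elim_reason = NA_character_,
                 mc_errors = NULL, mc_removed = NA_integer_,
                 warm_start_source = "test"), class = "fit_result")
}

test_that("AIC is chi2 + 2k with the optional small-sample correction", {
  expect_identical(aic(10, 3), 16)
  expect_identical(aic(0, 0), 0)
  # equal chi2: fewer parameters wins
  expect_lt(aic(20, 2), aic(20, 4))
  expect_equal(aic(10, 3, n = 30, corrected = TRUE), 16 + 24 / 26)
  expect_error(aic(10, -1), "k must be")
})

test_that("elimination rules fire on boundary-pinned and failed fits", {
  pv <- data.frame(symbol = c("pA", "kex", "dw", "r20"),
                   spin_id = c(NA, NA, "A:N", "A:N"),
                   field = c(NA, NA, NA, 600),
                   lower = c(0.5, 1, 0, 0.1),
                   upper = c(1 - 1e-6, 1e6, 30, 200),
                   grid = c("linear", "log", "linear", "seed"),
                   value = c(0.95, 1500, 3, 10), stringsAsFactors = FALSE)
  ok <- eliminate(fake_fit("CR72", 30, 4, pv))
  expect_false(ok$eliminated)
  # (a) kex pinned to its upper bound
  pv_a <- pv; pv_a$value[2] <- 0.999e6
  el_a <- eliminate(fake_fit("CR72", 30, 4, pv_a))
  expect_true(el_a$eliminated)
  expect_match(el_a$elim_reason, "kex")
  # (b) pA at 1 with dw at its upper bound
  pv_b <- pv; pv_b$value[1] <- 1 - 1e-6; pv_b$value[3] <- 29.9
  el_b <- eliminate(fake_fit("CR72", 30, 4, pv_b))
  expect_true(el_b$eliminated)
  expect_match(el_b$elim_reason, "pA")
  # pA at 1 alone (dw interior) is not eliminated
  pv_b2 <- pv; pv_b2$value[1] <- 1 - 1e-6
  expect_false(eliminate(fake_fit("CR72", 30, 4, pv_b2))$eliminated)
  # (c) non-convergence and (d) non-finite parameters
  expect_true(eliminate(fake_fit("CR72", 30, 4, pv,
                                 converged = FALSE))$eliminated)
  pv_d <- pv; pv_d$value[3] <- NaN
  expect_true(eliminate(fake_fit("CR72", 30, 4, pv_d))$eliminated)
})

test_that("tightening bounds only grows the eliminated set", {
  pv <- data.frame(symbol = "kex", spin_id = NA, field = NA, lower = 1,
                   upper = 1e6, grid = "log", value = 5e5,
                   stringsAsFactors = FALSE)
  fits <- lapply(c(1e4, 1e5, 5e5, 9e5), function(v) {
    p <- pv; p$value <- v
    fake_fit("CR72", 10, 1, p)
  })
  for (frac in c(0.01, 0.1, 0.5)) {
    loose <- vapply(fits, function(f) {
      eliminate(f, elimination_rules(kex_upper_frac = frac))$eliminated
    }, logical(1))
    tight <- vapply(fits, function(f) {
      eliminate(f, elimination_rules(kex_upper_frac = frac * 2))$eliminated
    }, logical(1))
    expect_true(all(loose <= tight))
  }
})

test_that("AIC selection picks minimal AIC with NoRex always a candidate", {
  sel <- select_model(list(NoRex = fake_fit("NoRex", 50, 1),
                           CR72 = fake_fit("CR72", 10, 4)))
  expect_equal(sel$chosen, "CR72")  # 18 < 52
  sel2 <- select_model(list(NoRex = fake_fit("NoRex", 12, 1),
                            CR72 = fake_fit("CR72", 11.9, 4)))
  expect_equal(sel2$chosen, "NoRex")  # 14 < 19.9
  # an eliminated better-chi2 model is not a candidate
  worse <- fake_fit("CR72", 1, 4)
  worse$eliminated <- TRUE
  worse$elim_reason <- "kex within 1% of its upper bound"
  sel3 <- select_model(list(NoRex = fake_fit("NoRex", 12, 1), CR72 = worse))
  expect_equal(sel3$chosen, "NoRex")
  # ties: equal AIC resolves to fewer parameters
  sel4 <- select_model(list(LM63 = fake_fit("LM63", 12, 3),
                            NoRex = fake_fit("NoRex", 16, 1)))
  expect_equal(sel4$chosen, "NoRex")
  # an eliminated NoRex remains a candidate by decree
  nr <- fake_fit("NoRex", 12, 1, converged = FALSE)
  nr <- eliminate(nr)
  sel5 <- select_model(list(NoRex = nr))
  expect_equal(sel5$chosen, "NoRex")
  expect_error(select_model(list()), "no fits")
})

test_that("MC errors are seed-deterministic and vanish with the noise", {
  ds <- simulate_dataset(cr72_design(seed = 8))
  fit <- minimise("CR72", ds, start = grid_search("CR72", ds))
  m1 <- monte_carlo_errors(fit, ds, n_sims = 20, seed = 5)
  m2 <- monte_carlo_errors(fit, ds, n_sims = 20, seed = 5)
  expect_identical(m1$mc_errors, m2$mc_errors)
  # vanishing stored errors give vanishing parameter errors (1-parameter
  # fixture, where the refit is exact)
  pts <- experiment_points("CPMG_SQ", 600, seq(100, 1000, by = 100), 0.04)
  vals <- data.frame(spin_id = "A:N", point_id = pts$point_id, value = 10,
                     error = 1e-9)
  ds0 <- dispersion_dataset(spin_systems("A:N"), pts, vals)
  fit0 <- minimise("NoRex", ds0)
  m0 <- monte_carlo_errors(fit0, ds0, n_sims = 10, seed = 5)
  expect_true(all(m0$mc_errors < 1e-6))
  expect_error(monte_carlo_errors(fit, ds, n_sims = 1, seed = 1), "n_sims")
})

test_that("MC parameter errors scale linearly with the data noise", {
  # a 1-parameter weighted-mean fit (NoRex, one field) has a closed-form
  # standard error; doubling sigma must double the MC spread
  sd_for <- function(sigma, seed) {
    pts <- experiment_points("CPMG_SQ", 600, seq(100, 1000, by = 100), 0.04)
    vals <- data.frame(spin_id = "A:N", point_id = pts$point_id, value = 10,
                       error = sigma)
    ds <- dispersion_dataset(spin_systems("A:N"), pts, vals)
    fit <- minimise("NoRex", ds)
    monte_carlo_errors(fit, ds, n_sims = 400, seed = seed)$mc_errors
  }
  s1 <- sd_for(0.5, 3)
  s2 <- sd_for(1.0, 3)
  expect_equal(unname(s2 / s1), 2, tolerance = 0.15)
  # and the MC spread matches the closed form 1/sqrt(sum(1/sigma^2))
  expect_equal(unname(s1), 0.5 / sqrt(10), tolerance = 0.1 * 0.5 / sqrt(10))
})
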