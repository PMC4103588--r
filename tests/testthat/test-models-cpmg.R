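# Closed-form CPMG models: frozen examples, vanishing-exchange identities,
# and cross-validation against the numeric Bloch-McConnell reference.

nu_grid <- seq(50, 1000, by = 50)

test_that("NoRex is flat and field-aware", {
  expect_equal(r2eff_norex(10, nu_grid), rep(10, length(nu_grid)))
  expect_identical(r2eff_norex(10, 50), r2eff_norex(10, 1000))
})

test_that("LM63 matches its closed-form limits and frozen value", {
  expect_equal(r2eff_lm63(10, 0, 2000, nu_grid), rep(10, length(nu_grid)))
  # nu -> 0 limit R20 + phi_ex/kex
  expect_equal(r2eff_lm63(10, 57600, 2000, 1e-3), 38.8, tolerance = 1e-4)
  expect_equal(r2eff_lm63(10, 57600, 2000, 100), 33.04, tolerance = 0.01)
  expect_error(r2eff_lm63(10, 100, 0, 50), "kex")
})

test_that("LM63 dispersion is monotonically non-increasing in nu_cpmg", {
  set.seed(11)
  for (i in 1:25) {
    phi <- runif(1, 1, 1e6)
    kex <- runif(1, 10, 1e5)
    r <- r2eff_lm63(10, phi, kex, nu_grid)
    expect_true(all(diff(r) <= 1e-12))
    expect_equal(r2eff_lm63(10, phi, kex, 1e7), 10, tolerance = 1e-3)
  }
})

test_that("every CPMG model returns the baseline exactly when exchange vanishes", {
  dw <- ppm_to_rad_per_s(2, 600, "15N")
  for (nu in c(50, 333, 1000)) {
    expect_identical(r2eff_cr72(10, 10, 1, 1500, dw, nu), 10)
    expect_identical(r2eff_cr72(10, 10, 0.95, 1500, 0, nu), 10)
    expect_identical(r2eff_cr72(10, 10, 0.95, 0, dw, nu), 10)
    expect_identical(r2eff_it99(10, 1, 1500, dw, nu), 10)
    expect_identical(r2eff_it99(10, 0.95, 1500, 0, nu), 10)
    expect_identical(r2eff_tsmfk01(10, 0, dw, nu), 10)
    expect_identical(r2eff_lm63(10, 0, 2000, nu), 10)
    expect_identical(ns_cpmg_2site(10, 10, 1, 1500, dw, nu, 0.04), 10)
    expect_identical(ns_cpmg_2site(10, 10, 0.95, 0, dw, nu, 0.04), 10)
    expect_identical(r2eff_mmq_cr72(10, 10, 1, 1500, dw, dw, nu, 0.04,
                                    "CPMG_MQ"), 10)
  }
})

test_that("CR72 agrees with the numeric solution in its validity regime", {
  # kex >= 4*dw: the fast side of intermediate exchange (agreement with the
  # equilibrium-start numeric reference degrades towards slow exchange)
  for (pA in c(0.9, 0.95, 0.99)) {
    for (dwppm in c(1, 3)) {
      for (field in c(600, 800)) {
        dw <- ppm_to_rad_per_s(dwppm, field, "15N")
        for (kex in c(4 * dw, 8 * dw, 2e4)) {
          cr <- r2eff_cr72(10, 10, pA, kex, dw, nu_grid)
          ns <- ns_cpmg_2site(10, 10, pA, kex, dw, nu_grid, 0.04)
          expect_lt(max_rel_err(cr, ns), 0.02)
        }
      }
    }
  }
})

test_that("CR72 stays within 6% of the numeric solution across the broad sweep", {
  for (pA in c(0.9, 0.95, 0.99)) {
    for (kex in c(500, 2000, 1e4)) {
      for (dwppm in c(1, 3)) {
        dw <- ppm_to_rad_per_s(dwppm, 800, "15N")
        cr <- r2eff_cr72(10, 10, pA, kex, dw, nu_grid)
        ns <- ns_cpmg_2site(10, 10, pA, kex, dw, nu_grid, 0.04)
        expect_lt(max_rel_err(cr, ns), 0.06)
      }
    }
  }
})

test_that("CR72 survives overflow-prone parameters (large kex, slow pulsing)", {
  dw <- ppm_to_rad_per_s(5, 800, "15N")
  r <- r2eff_cr72(10, 10, 0.9, 9e5, dw, c(25, 50, 1000))
  expect_true(all(is.finite(r)))
  expect_true(all(r >= 10 - 1e-9))
})

test_that("IT99 reduces to the baseline at fast pulsing and tracks the NS when skewed", {
  dw <- ppm_to_rad_per_s(3, 600, "15N")
  expect_equal(r2eff_it99(10, 0.95, 1e4, dw, 1e6), 10, tolerance = 1e-4)
  it <- r2eff_it99(10, 0.95, 1e4, dw, nu_grid[nu_grid >= 100])
  ns <- ns_cpmg_2site(10, 10, 0.95, 1e4, dw, nu_grid[nu_grid >= 100], 0.04)
  expect_lt(max_rel_err(it, ns), 0.10)
})

test_that("TSMFK01 matches its sinc form and the slow-exchange NS", {
  dw <- ppm_to_rad_per_s(4, 600, "15N")
  # sinc -> 1 as tau_cp -> 0
  expect_equal(r2eff_tsmfk01(10, 5, dw, 1e8), 10, tolerance = 1e-6)
  expect_identical(r2eff_tsmfk01(10, 0, dw, 100), 10)
  pA <- 0.99
  kex <- 30
  ts <- r2eff_tsmfk01(10, (1 - pA) * kex, dw, nu_grid)
  ns <- ns_cpmg_2site(10, 10, pA, kex, dw, nu_grid, 0.04)
  expect_lt(max_rel_err(ts, ns), 0.10)
})

test_that("fast-exchange consistency: CR72 collapses onto LM63", {
  for (field in c(600, 800)) {
    dw <- ppm_to_rad_per_s(1, field, "15N")
    kex <- 25 * dw
    pA <- 0.95
    cr <- r2eff_cr72(10, 10, pA, kex, dw, nu_grid)
    lm <- r2eff_lm63(10, pA * (1 - pA) * dw^2, kex, nu_grid)
    rex <- max(cr) - 10
    expect_lt(max(abs(cr - lm)) / rex, 0.05)
  }
})

test_that("MMQ-CR72 coherence identities hold", {
  dw <- ppm_to_rad_per_s(1.5, 600, "15N")
  dwH <- ppm_to_rad_per_s(0.5, 600, "1H")
  sq <- r2eff_mmq_cr72(10, 10, 0.95, 2000, dw, 0, nu_grid, 0.04, "CPMG_SQ")
  expect_identical(sq, r2eff_cr72(10, 10, 0.95, 2000, dw, nu_grid))
  # ZQ with dwH = 0 equals the SQ output
  expect_identical(r2eff_mmq_cr72(10, 10, 0.95, 2000, dw, 0, nu_grid, 0.04,
                                  "CPMG_ZQ"), sq)
  # DQ is CR72 at the summed shift
  expect_identical(r2eff_mmq_cr72(10, 10, 0.95, 2000, dw, dwH, nu_grid, 0.04,
                                  "CPMG_DQ"),
                   r2eff_cr72(10, 10, 0.95, 2000, dw + dwH, nu_grid))
  expect_error(r2eff_mmq_cr72(10, 10, 0.95, 2000, dw, NULL, nu_grid, 0.04,
                              "CPMG_ZQ"), "dwH")
  # MQ agrees with the numeric MMQ propagation in the CR72 validity regime
  mq <- r2eff_mmq_cr72(10, 10, 0.95, 3000, dw, dwH, nu_grid, 0.04, "CPMG_MQ")
  nsq <- ns_mmq_2site(10, 10, 0.95, 3000, dw, dwH, nu_grid, 0.04, "CPMG_MQ")
  expect_lt(max_rel_err(mq, nsq), 0.05)
})

test_that("analytic models have finite central-difference parameter gradients", {
  dw0 <- ppm_to_rad_per_s(2, 600, "15N")
  h <- 1e-6
  fdiff <- function(f, x) (f(x * (1 + h)) - f(x * (1 - h))) / (2 * x * h)
  g1 <- fdiff(function(k) r2eff_cr72(10, 10, 0.95, k, dw0, 200), 1500)
  g2 <- fdiff(function(d) r2eff_cr72(10, 10, 0.95, 1500, d, 200), dw0)
  g3 <- fdiff(function(p) r2eff_it99(10, p, 1500, dw0, 200), 0.95)
  g4 <- fdiff(function(k) r2eff_lm63(10, 5e4, k, 200), 1500)
  expect_true(all(is.finite(c(g1, g2, g3, g4))))
})
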