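# Shared fixtures, built in code.

# The frozen CR72 study conditions: intermediate 2-site exchange measured at
# two fields, 15 CPMG frequencies each, 0.5 1/s Gaussian noise on R2eff.
cr72_truth <- function() {
  list(r20 = c("600" = 10, "800" = 12), pA = 0.95, kex = 1000, dw = 3)
}

cr72_design <- function(seed, sigma = 0.5, truth = cr72_truth()) {
  sim_design("CR72", truth, fields = c(600, 800),
             nu_cpmg = seq(66.67, 1000, length.out = 15),
             relax_time_T = 0.03, sigma = sigma, seed = seed)
}

flat_design <- function(seed, sigma = 0.5) {
  sim_design("NoRex", list(r20 = c("600" = 10, "800" = 12)),
             fields = c(600, 800), nu_cpmg = seq(66.67, 1000, length.out = 15),
             relax_time_T = 0.03, sigma = sigma, seed = seed)
}

r1rho_design <- function(seed, sigma = 0.3,
                         truth = list(r20 = c("600" = 10), pA = 0.95,
                                      kex = 1000, dw = 2)) {
  sim_design("NS_R1rho_2site", truth, fields = 600,
             omega1 = seq(150, 2000, length.out = 12),
             offset_ppm = c(-1.5, 1.5), r1 = 1.5, relax_time_T = 0.12,
             sigma = sigma, seed = seed)
}

# A dataset with exact (noiseless) rates but usable errors for chi2.
noiseless_dataset <- function(design, error = 0.01) {
  stopifnot(design$sigma == 0)
  ds <- simulate_dataset(design)
  ds$values$error <- error
  ds
}

# Relative deviation of two curves.
max_rel_err <- function(a, b) max(abs(a - b) / abs(b))
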