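# AIC model selection, fixed elimination rules and Monte-Carlo error
# propagation.

#' Akaike's Information Criterion for a chi-squared fit
#'
#' `AIC = chi2 + 2k` (chi-squared is -2 log-likelihood up to a constant for
#' Gaussian errors). The small-sample corrected variant is available via
#' `corrected = TRUE`: `AICc = AIC + 2k(k+1)/(n-k-1)`.
#'
#' @param chi2 Chi-squared of the fit.
#' @param k Number of free parameters.
#' @param n Number of data points (needed for `corrected = TRUE`).
#' @param corrected Use the small-sample correction.
#' @return The criterion value.
#' @export
aic <- function(chi2, k, n = NULL, corrected = FALSE) {
  if (any(k < 0)) stop("k must be >= 0", call. = FALSE)
  out <- chi2 + 2 * k
  if (corrected) {
    if (is.null(n)) stop("n is required for AICc", call. = FALSE)
    out <- out + 2 * k * (k + 1) / (n - k - 1)
  }
  out
}

#' Default model-elimination rules
#'
#' @param kex_upper_frac A kinetic rate (kex or kAB) within this fraction of
#'   its upper bound eliminates the fit (exchange pushed out of the
#'   observable window).
#' @param pA_tol `pA` within this distance of 1 while `dw` sits at its upper
#'   bound eliminates the fit.
#' @param dw_upper_frac Fraction of the `dw` upper bound counting as "at the
#'   bound" for the previous rule.
#' @return A named list of thresholds.
#' @export
elimination_rules <- function(kex_upper_frac = 0.01, pA_tol = 1e-4,
                              dw_upper_frac = 0.01) {
  list(kex_upper_frac = kex_upper_frac, pA_tol = pA_tol,
       dw_upper_frac = dw_upper_frac)
}

#' Apply the fixed elimination rules to a fit
#'
#' A fit is eliminated when (a) a kinetic rate (kex, kAB) lies within 1
#' percent of its upper bound, (b) `pA` lies within `1e-4` of 1 while `dw`
#' sits at its upper bound, (c) the optimiser did not converge, or (d) any
#' parameter is non-finite. The triggering rule is recorded as the reason.
#'
#' @param fit A `fit_result`.
#' @param rules Output of [elimination_rules()].
#' @return The fit with `eliminated` and `elim_reason` filled in.
#' @export
eliminate <- function(fit, rules = elimination_rules()) {
  pv <- fit$pv
  reason <- NA_character_
  if (any(!is.finite(pv$value))) {
    reason <- "non-finite parameter"
  } else if (!fit$converged) {
    reason <- "optimisation did not converge"
  } else {
    for (i in which(pv$symbol %in% c("kex", "kAB"))) {
      if (pv$value[i] >= (1 - rules$kex_upper_frac) * pv$upper[i]) {
        reason <- paste0(pv$symbol[i], " within ",
                         rules$kex_upper_frac * 100,
                         "% of its upper bound")
        break
      }
    }
    if (is.na(reason)) {
      ipa <- which(pv$symbol == "pA")
      if (length(ipa) && pv$value[ipa[1]] >= 1 - rules$pA_tol) {
        idw <- which(pv$symbol == "dw")
        if (length(idw) &&
            any(pv$value[idw] >= (1 - rules$dw_upper_frac) * pv$upper[idw])) {
          reason <- "pA at 1 with dw at its upper bound"
        }
      }
    }
  }
  fit$eliminated <- !is.na(reason)
  fit$elim_reason <- reason
  fit
}

#' Monte-Carlo error propagation for a fit
#'
#' Back-calculates the data from the fitted parameters, adds Gaussian noise
#' with each point's measured standard deviation, refits starting from the
#' point estimate, applies the elimination rules to every simulation, and
#' reports the standard deviation of each parameter over the surviving
#' simulations together with the number removed.
#'
#' @param fit A `fit_result`.
#' @param dataset The fitted [dispersion_dataset()].
#' @param spin_ids Spins of the fitted cluster.
#' @param n_sims Number of simulations (`>= 2`).
#' @param seed Seed; simulation `i` uses `seed + i`.
#' @param maxit Simplex iteration cap per refit.
#' @return The fit with `mc_errors` (named s.d. per parameter) and
#'   `mc_removed` filled in.
#' @export
monte_carlo_errors <- function(fit, dataset, spin_ids = dataset$spins$spin_id,
                               n_sims = 500, seed = 1, maxit = 500) {
  if (n_sims < 2) stop("n_sims must be >= 2", call. = FALSE)
  ctx <- cluster_context(dataset, spin_ids)
  calc <- dataset$values
  for (cx in ctx) {
    p <- pv_to_params(fit$pv, cx$spin_id)
    idx <- which(calc$spin_id == cx$spin_id &
                   calc$point_id %in% cx$data$point_id)
    calc$value[idx] <- backcalc_rates(fit$model, p, cx$data, cx$isotope,
                                      cx$shift_ppm)
  }
  draws <- matrix(NA_real_, nrow = n_sims, ncol = nrow(fit$pv))
  removed <- 0L
  for (i in seq_len(n_sims)) {
    set.seed((seed + i) %% 2147483647L)
    ds_i <- dataset
    ds_i$values <- calc
    ds_i$values$value <- calc$value + rnorm(nrow(calc)) * calc$error
    # refits start at the optimum and only need error-estimation accuracy,
    # so they run a single barrier stage at a looser simplex tolerance
    fit_i <- minimise(fit$model, ds_i, spin_ids, start = fit$pv,
                      maxit = maxit, reltol = 1e-8, stages = c(1e-6, 1e-9),
                      restart = FALSE, warm_start_source = "mc")
    fit_i <- eliminate(fit_i)
    if (fit_i$eliminated) {
      removed <- removed + 1L
    } else {
      draws[i, ] <- fit_i$pv$value
    }
  }
  if (removed == n_sims) {
    stop("error estimation failed: all MC simulations eliminated",
         call. = FALSE)
  }
  fit$mc_errors <- setNames(apply(draws, 2, sd, na.rm = TRUE),
                            param_names(fit$pv))
  fit$mc_removed <- removed
  fit
}

#' AIC model selection over the fits of one spin cluster
#'
#' Ranks all fits by AIC, drops eliminated fits (NoRex is never eliminated
#' as a candidate), and chooses the minimal-AIC survivor. Ties go to the
#' model with fewer parameters, then to catalogue order.
#'
#' @param results Named list (by model) of `fit_result` objects for one
#'   spin or cluster.
#' @return A list with `ranked` (a `data.frame` of model, chi2, k, aic,
#'   eliminated, reason, candidate flag) and `chosen` (the winning model
#'   name).
#' @export
select_model <- function(results) {
  if (!length(results)) stop("no fits to select from", call. = FALSE)
  df <- do.call(rbind, lapply(results, function(f) {
    data.frame(model = f$model, chi2 = f$chi2, k = f$k, aic = f$aic,
               eliminated = f$eliminated,
               reason = if (is.na(f$elim_reason)) "" else f$elim_reason,
               stringsAsFactors = FALSE)
  }))
  df$candidate <- !df$eliminated | df$model == "NoRex"
  if (!any(df$candidate)) stop("no candidate model survives", call. = FALSE)
  cat_order <- match(df$model, model_names())
  ord <- order(!df$candidate, df$aic, df$k, cat_order)
  df <- df[ord, ]
  rownames(df) <- NULL
  list(ranked = df, chosen = df$model[df$candidate][1])
}
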