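# The automated analysis protocol: sequential warm-started optimisation,
# elimination, optional clustered pass, Monte-Carlo errors and a final AIC
# selection, plus the parallel-execution contract and result writers.

#' Configuration of the automated protocol
#'
#' @param models Ordered model list; must be non-empty and start with
#'   `NoRex`. Defaults to the full catalogue.
#' @param grid_n Grid points per dimension for the initial grid searches.
#' @param n_sims Monte-Carlo simulations per fit (0 disables MC errors).
#' @param seed Mandatory master seed; per-unit seeds are derived from it by
#'   a fixed counter scheme so serial and parallel runs are identical.
#' @param workers Worker processes for cluster-level and MC parallelism.
#' @param maxit Simplex iteration cap per optimisation.
#' @param mc_maxit Simplex iteration cap per Monte-Carlo refit.
#' @param rules [elimination_rules()] to apply.
#' @return A `protocol_config` list.
#' @export
protocol_config <- function(models = model_names(), grid_n = 11, n_sims = 500,
                            seed, workers = 1, maxit = 10000, mc_maxit = 2000,
                            rules = elimination_rules()) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (!length(models) || models[1] != "NoRex") {
    stop("the model list must be non-empty and start with NoRex",
         call. = FALSE)
  }
  bad <- setdiff(models, model_names())
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(models = models, grid_n = grid_n, n_sims = n_sims,
                 seed = as.integer(seed), workers = workers, maxit = maxit,
                 mc_maxit = mc_maxit, rules = rules),
            class = "protocol_config")
}

#' Order-preserving parallel map with per-unit seeds
#'
#' Applies `f(unit, unit_seed)` to every work unit. Unit `i` receives the
#' derived seed `(seed + i) mod (2^31 - 1)` regardless of the worker count
#' or unit order, so results are identical to serial execution. With
#' `workers > 1`, units run in forked processes ([parallel::mclapply()]); a
#' failed unit is retried serially and, if it fails again, its condition is
#' returned in place of a result.
#'
#' @param units List of work units.
#' @param f Function of `(unit, unit_seed)`.
#' @param workers Number of workers.
#' @param seed Master seed.
#' @return A list of results, in the order of `units`.
#' @export
parallel_map <- function(units, f, workers = 1, seed = 1) {
  seeds <- (as.numeric(seed) + seq_along(units)) %% 2147483647
  run1 <- function(i) f(units[[i]], as.integer(seeds[i]))
  idx <- seq_along(units)
  if (workers > 1 && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(idx, function(i) {
      tryCatch(run1(i), error = function(e) structure(list(error = e),
                                                      class = "unit_error"))
    }, mc.cores = workers)
    # retry failures serially; keep the condition if it persists
    for (i in idx) {
      if (inherits(res[[i]], "unit_error") || inherits(res[[i]], "try-error")) {
        res[[i]] <- tryCatch(run1(i), error = function(e) {
          structure(list(error = e), class = "unit_error")
        })
      }
    }
    res
  } else {
    lapply(idx, function(i) {
      tryCatch(run1(i), error = function(e) structure(list(error = e),
                                                      class = "unit_error"))
    })
  }
}

# Fit all applicable models for one spin (non-clustered pass), warm-started
# per the nesting map, then apply the elimination rules.
fit_spin_models <- function(dataset, spin_id, config) {
  srow <- dataset$spins[dataset$spins$spin_id == spin_id, ]
  pts <- spin_data(dataset, spin_id)
  fits <- list()
  skipped <- list()
  for (m in config$models) {
    if (!model_applicable(m, pts, srow$shift_ppm, srow$isotope)) {
      skipped[[m]] <- "not applicable to this spin's experiment types"
      next
    }
    nm <- nesting_map(m)
    start <- NULL
    src_label <- nm$source
    if (nm$source == "mean") {
      start <- norex_mean_start(dataset, spin_id)
    } else if (nm$source != "grid" && !is.null(fits[[nm$source]]) &&
               !fits[[nm$source]]$eliminated) {
      start <- nm$translate(param_table(m, dataset, spin_id),
                            fits[[nm$source]])
    }
    if (is.null(start)) {
      start <- grid_search(m, dataset, spin_id, grid_n = config$grid_n)
      src_label <- "grid"
    }
    fit <- minimise(m, dataset, spin_id, start = start, maxit = config$maxit,
                    warm_start_source = src_label)
    fits[[m]] <- eliminate(fit, config$rules)
  }
  list(fits = fits, skipped = skipped)
}

#' Run the automated dispersion analysis protocol
#'
#' Stages: (1) non-clustered pass, fitting the configured models in
#' catalogue order for every spin with warm starts from the nesting /
#' equivalence map (grid search only where the map says so); (2) fixed-rule
#' elimination; (3) for clusters of two or more spins, a clustered pass
#' seeded by the averaged non-clustered estimates, sharing the
#' cluster-global parameters; (4) Monte-Carlo error propagation for the
#' surviving fits; (5) a final AIC model-selection run over the stored fits
#' (no refit). Failures in any unit are recorded and the protocol continues.
#'
#' @param dataset A [dispersion_dataset()].
#' @param config A [protocol_config()].
#' @return A `protocol_report`: per-unit fits, selection outcomes, skip log
#'   and the config snapshot.
#' @export
run_protocol <- function(dataset, config) {
  stopifnot(inherits(dataset, "dispersion_dataset"),
            inherits(config, "protocol_config"))
  spin_ids <- sort(dataset$spins$spin_id)
  # stage 1+2: non-clustered, parallel over spins
  nc <- parallel_map(as.list(spin_ids),
                     function(s, s_seed) fit_spin_models(dataset, s, config),
                     workers = config$workers, seed = config$seed)
  names(nc) <- spin_ids
  failures <- list()
  for (s in spin_ids) {
    if (inherits(nc[[s]], "unit_error")) {
      failures[[paste0("spin:", s)]] <- conditionMessage(nc[[s]]$error)
      nc[[s]] <- list(fits = list(), skipped = list())
    }
  }
  # stage 3: clustered pass
  clusters <- split(dataset$spins$spin_id, dataset$spins$cluster_id)
  clusters <- clusters[vapply(clusters, length, integer(1)) >= 2]
  cl <- list()
  if (length(clusters)) {
    cl <- parallel_map(unname(clusters), function(members, s_seed) {
      fits <- list()
      for (m in config$models) {
        ncs <- lapply(nc[members], function(x) x$fits[[m]])
        names(ncs) <- members
        if (any(vapply(ncs, is.null, logical(1)))) next
        start <- cluster_average_start(ncs, param_table(m, dataset, members))
        fit <- minimise(m, dataset, members, start = start,
                        maxit = config$maxit,
                        warm_start_source = "cluster-average")
        fits[[m]] <- eliminate(fit, config$rules)
      }
      fits
    }, workers = config$workers, seed = config$seed + 7919)
    names(cl) <- names(clusters)
    for (cname in names(cl)) {
      if (inherits(cl[[cname]], "unit_error")) {
        failures[[paste0("cluster:", cname)]] <-
          conditionMessage(cl[[cname]]$error)
        cl[[cname]] <- list()
      }
    }
  }
  # final units: clusters where defined, single spins otherwise
  clustered_spins <- unlist(clusters, use.names = FALSE)
  units <- c(lapply(names(clusters), function(cn) {
               list(name = cn, spins = clusters[[cn]], fits = cl[[cn]])
             }),
             lapply(setdiff(spin_ids, clustered_spins), function(s) {
               list(name = s, spins = s, fits = nc[[s]]$fits)
             }))
  units <- units[order(vapply(units, `[[`, character(1), "name"))]
  # stage 4: MC errors, parallel over (unit, model)
  if (config$n_sims > 0) {
    tasks <- list()
    for (ui in seq_along(units)) {
      for (m in names(units[[ui]]$fits)) {
        if (!units[[ui]]$fits[[m]]$eliminated) {
          tasks[[length(tasks) + 1L]] <- list(ui = ui, model = m)
        }
      }
    }
    mc_res <- parallel_map(tasks, function(task, s_seed) {
      u <- units[[task$ui]]
      monte_carlo_errors(u$fits[[task$model]], dataset, u$spins,
                         n_sims = config$n_sims, seed = s_seed,
                         maxit = config$mc_maxit)
    }, workers = config$workers, seed = config$seed + 104729)
    for (ti in seq_along(tasks)) {
      t <- tasks[[ti]]
      if (inherits(mc_res[[ti]], "unit_error")) {
        failures[[paste0("mc:", units[[t$ui]]$name, ":", t$model)]] <-
          conditionMessage(mc_res[[ti]]$error)
      } else {
        units[[t$ui]]$fits[[t$model]] <- mc_res[[ti]]
      }
    }
  }
  # stage 5: AIC selection over the stored fits
  selection <- lapply(units, function(u) {
    if (!length(u$fits)) return(NULL)
    select_model(u$fits)
  })
  names(selection) <- vapply(units, `[[`, character(1), "name")
  names(units) <- names(selection)
  structure(list(config = config, dataset = dataset, units = units,
                 non_clustered = nc, selection = selection,
                 failures = failures),
            class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  cat("<protocol_report> ", length(x$units), " unit(s)\n", sep = "")
  for (nm in names(x$units)) {
    sel <- x$selection[[nm]]
    cat("  ", nm, ": ",
        if (is.null(sel)) "no fits" else paste0("chosen ", sel$chosen),
        "\n", sep = "")
  }
  if (length(x$failures)) {
    cat("  failures: ", paste(names(x$failures), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

# Back-calculated curve of a unit's chosen model for one spin.
unit_curves <- function(report, unit_name) {
  u <- report$units[[unit_name]]
  sel <- report$selection[[unit_name]]
  if (is.null(sel)) return(NULL)
  fit <- u$fits[[sel$chosen]]
  out <- list()
  for (s in u$spins) {
    srow <- report$dataset$spins[report$dataset$spins$spin_id == s, ]
    d <- spin_data(report$dataset, s)
    p <- pv_to_params(fit$pv, s)
    d$calc <- backcalc_rates(sel$chosen, p, d, srow$isotope, srow$shift_ppm)
    d$spin_id <- s
    d$model <- sel$chosen
    out[[s]] <- d
  }
  do.call(rbind, out)
}

#' Write the protocol report to disk
#'
#' Produces, under `outdir`: one observed-versus-back-calculated curve CSV
#' and one xmgrace `.agr` plot per spin, a `summary.csv` of the selected
#' model and parameters (with MC errors where computed) per unit, and a
#' plain-text run log with the selection ranking and elimination reasons.
#'
#' @param report A `protocol_report`.
#' @param outdir Output directory (created if missing).
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  summary_rows <- list()
  log_lines <- c("rexfit protocol report",
                 paste0("seed: ", report$config$seed),
                 paste0("models: ", paste(report$config$models,
                                          collapse = ", ")), "")
  for (nm in names(report$units)) {
    u <- report$units[[nm]]
    sel <- report$selection[[nm]]
    if (is.null(sel)) {
      log_lines <- c(log_lines, paste0(nm, ": no fits"))
      next
    }
    fit <- u$fits[[sel$chosen]]
    curves <- unit_curves(report, nm)
    for (s in u$spins) {
      cs <- curves[curves$spin_id == s, ]
      safe <- gsub("[^A-Za-z0-9_.-]", "_", s)
      cpath <- file.path(outdir, paste0("curve_", safe, ".csv"))
      write.csv(cs, cpath, row.names = FALSE, na = "")
      apath <- file.path(outdir, paste0("disp_", safe, ".agr"))
      write_agr(cs, apath, title = paste0(s, " (", sel$chosen, ")"))
      paths <- c(paths, cpath, apath)
    }
    errs <- if (is.null(fit$mc_errors)) rep(NA_real_, nrow(fit$pv)) else
      fit$mc_errors
    summary_rows[[nm]] <- data.frame(
      unit = nm, spin_id = paste(u$spins, collapse = ";"),
      model = sel$chosen,
      parameter = param_names(fit$pv), value = fit$pv$value, error = errs,
      chi2 = fit$chi2, aic = fit$aic, stringsAsFactors = FALSE)
    log_lines <- c(log_lines, paste0(nm, ": chosen ", sel$chosen),
                   utils::capture.output(print(sel$ranked)), "")
  }
  spath <- file.path(outdir, "summary.csv")
  write.csv(do.call(rbind, summary_rows), spath, row.names = FALSE, na = "")
  lpath <- file.path(outdir, "run.log")
  if (length(report$failures)) {
    log_lines <- c(log_lines, "failures:",
                   paste0("  ", names(report$failures), ": ",
                          unlist(report$failures)))
  }
  writeLines(log_lines, lpath)
  invisible(c(paths, spath, lpath))
}

# Minimal xmgrace writer: observed points with error bars (set 0) and the
# back-calculated curve (set 1).
write_agr <- function(curve, path, title = "") {
  is_cpmg <- curve$exp_type[1] != "R1RHO"
  x <- if (is_cpmg) curve$nu_cpmg else curve$omega1
  xlab <- if (is_cpmg) "\\xn\\f{}\\sCPMG\\N (Hz)" else
    "\\xw\\f{}\\s1\\N/2\\xp\\f{} (Hz)"
  ylab <- if (is_cpmg) "R\\s2,eff\\N (s\\S-1\\N)" else "R\\s1\\xr\\f{}\\N (s\\S-1\\N)"
  ord <- order(curve$field_h1_mhz, x)
  lines <- c("@version 50125",
             paste0("@    title \"", title, "\""),
             paste0("@    xaxis  label \"", xlab, "\""),
             paste0("@    yaxis  label \"", ylab, "\""),
             "@    s0 symbol 1",
             "@    s0 line type 0",
             "@    s0 legend \"observed\"",
             "@    s1 symbol 0",
             "@    s1 line type 1",
             "@    s1 legend \"back-calculated\"",
             "@target G0.S0", "@type xydy",
             sprintf("%.6g %.6g %.6g", x[ord], curve$value[ord],
                     curve$error[ord]),
             "&",
             "@target G0.S1", "@type xy",
             sprintf("%.6g %.6g", x[ord], curve$calc[ord]),
             "&")
  writeLines(lines, path)
  invisible(path)
}
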