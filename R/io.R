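# Peak-list and dispersion-table readers/writers.

#' Read a Sparky peak list
#'
#' Parses a whitespace-delimited Sparky `.list` file (header line such as
#' `"Assignment w1 w2 Data Height"` tolerated) and returns the peak intensity
#' per assignment. The intensity is taken from the last numeric column of each
#' row. Rows whose assignment cannot be parsed (first token not starting with
#' a letter or digit, or no numeric columns) are skipped with a warning; a
#' duplicated assignment keeps the last occurrence and warns.
#'
#' @param path Path to the `.list` file.
#' @return Named numeric vector of intensities, keyed by assignment string.
#' @export
read_sparky_peak_list <- function(path) {
  if (!file.exists(path)) stop("peak list not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- numeric(0)
  skipped <- character(0)
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 2) { skipped <- c(skipped, ln); next }
    if (grepl("^Assignment$", tok[1], ignore.case = TRUE)) next  # header
    vals <- suppressWarnings(as.numeric(tok[-1]))
    if (all(is.na(vals)) || !grepl("^[[:alnum:]]", tok[1])) {
      skipped <- c(skipped, ln); next
    }
    intensity <- vals[max(which(!is.na(vals)))]
    if (tok[1] %in% names(out)) {
      warning("duplicate assignment '", tok[1], "': keeping the last row",
              call. = FALSE)
    }
    out[tok[1]] <- intensity
  }
  if (length(skipped)) {
    warning(length(skipped), " unparseable row(s) skipped", call. = FALSE)
  }
  if (!length(out)) stop("no peaks parsed from ", path, call. = FALSE)
  out
}

.csv_cols <- c("spin_id", "exp_type", "field_h1_mhz", "nu_cpmg", "relax_time_T",
               "omega1", "offset_ppm", "r1", "r2eff", "r2eff_err")

#' Read a generic dispersion CSV table
#'
#' One row per (spin, condition) with the mandatory header
#' `spin_id, exp_type, field_h1_mhz, nu_cpmg, relax_time_T, omega1,
#' offset_ppm, r1, r2eff, r2eff_err`; cells not applicable to the experiment
#' type are left empty. Optional columns `isotope`, `cluster_id` and
#' `shift_ppm` annotate the spins.
#'
#' @param path Path to the CSV file.
#' @return A [dispersion_dataset()].
#' @export
read_dispersion_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.csv_cols, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  iso <- if ("isotope" %in% names(df)) df$isotope else "15N"
  clu <- if ("cluster_id" %in% names(df)) df$cluster_id else NA_character_
  sh <- if ("shift_ppm" %in% names(df)) df$shift_ppm else 0
  spin_rows <- !duplicated(df$spin_id)
  spins <- spin_systems(df$spin_id[spin_rows],
                        isotope = rep_len(iso, nrow(df))[spin_rows],
                        cluster_id = rep_len(as.character(clu), nrow(df))[spin_rows],
                        shift_ppm = rep_len(sh, nrow(df))[spin_rows])
  # unique conditions become points
  cond_cols <- c("exp_type", "field_h1_mhz", "nu_cpmg", "relax_time_T",
                 "omega1", "offset_ppm", "r1")
  key <- do.call(paste, c(df[cond_cols], sep = "|"))
  uidx <- !duplicated(key)
  points <- experiment_points(df$exp_type[uidx], df$field_h1_mhz[uidx],
                              df$nu_cpmg[uidx], df$relax_time_T[uidx],
                              df$omega1[uidx], df$offset_ppm[uidx], df$r1[uidx])
  values <- data.frame(spin_id = df$spin_id,
                       point_id = match(key, key[uidx]),
                       value = df$r2eff, error = df$r2eff_err,
                       stringsAsFactors = FALSE)
  dispersion_dataset(spins, points, values)
}

#' Write a dispersion dataset to the generic CSV dialect
#'
#' @param dataset A [dispersion_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dispersion_csv <- function(dataset, path) {
  v <- dataset$values
  p <- dataset$points[match(v$point_id, dataset$points$point_id), ]
  s <- dataset$spins[match(v$spin_id, dataset$spins$spin_id), ]
  df <- data.frame(spin_id = v$spin_id, exp_type = p$exp_type,
                   field_h1_mhz = p$field_h1_mhz, nu_cpmg = p$nu_cpmg,
                   relax_time_T = p$relax_time_T, omega1 = p$omega1,
                   offset_ppm = p$offset_ppm, r1 = p$r1,
                   r2eff = v$value, r2eff_err = v$error,
                   isotope = s$isotope, cluster_id = s$cluster_id,
                   shift_ppm = s$shift_ppm, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
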