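#' Serial dilution series
#'
#' Geometric 1:`factor` dilution from `top`, optionally followed by an
#' equal-volume mix with a second component (`post_mix = 2`), which halves
#' every concentration — the standard plate workflow where a pre-diluted
#' series is mixed 1:1 with the assay master mix.
#'
#' @param top Pre-mix top concentration (molar), > 0.
#' @param n_points Number of points, >= 1.
#' @param factor Dilution factor between consecutive points, > 1.
#' @param post_mix 1 (no mix) or 2 (equal-volume mix halves concentrations).
#' @return Strictly decreasing molar concentration vector of length
#'   `n_points`.
#' @examples
#' # 16-point series, 2 mM pre-dilution mixed 1:1: 1 mM down to 30.52 nM
#' range(dilution_series(2e-3, 16, post_mix = 2))
#' @export
dilution_series <- function(top, n_points, factor = 2, post_mix = 1) {
  assert_positive(top, "top")
  stopifnot(n_points >= 1L, factor > 1, post_mix %in% c(1, 2))
  top / post_mix / factor^(seq_len(n_points) - 1L)
}

#' Protein-consumption fold ratios between methods
#'
#' Given the target-protein mass consumed per affinity determination by each
#' method, returns each method's consumption as a fold ratio to a reference
#' method, rounded to one decimal.
#'
#' @param mass_per_assay Named numeric vector of masses (micrograms), > 0.
#' @param reference_method Name of the reference method.
#' @return Named numeric vector of fold ratios (method / reference).
#' @examples
#' protein_consumption(c(FPS = 0.64, BLI = 18.25), "FPS")  # BLI = 28.5
#' @export
protein_consumption <- function(mass_per_assay, reference_method) {
  assert_positive(mass_per_assay, "mass_per_assay")
  if (is.null(names(mass_per_assay)) || any(!nzchar(names(mass_per_assay)))) {
    stop_multikin("mass_per_assay must be a fully named vector")
  }
  if (!reference_method %in% names(mass_per_assay)) {
    stop_multikin("reference method '", reference_method,
                  "' not present in mass_per_assay")
  }
  round(mass_per_assay / mass_per_assay[[reference_method]], 1)
}

# ---- CSV dialects -----------------------------------------------------------
# All on-disk concentrations are nanomolar (column suffix _nM); everything in
# memory is molar.

read_checked_csv <- function(path, needed) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_multikin(path, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  df
}

check_numeric_col <- function(df, col, path) {
  bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
  if (length(bad)) {
    stop_multikin(path, ": non-numeric '", col, "' at data row(s) ",
                  paste(utils::head(bad, 5L), collapse = ", "))
  }
  as.numeric(df[[col]])
}

#' Write / read a peptide library CSV
#'
#' Columns: `id, valency, epitope_seq, e, o1, o2, o3, tokens`.
#'
#' @param library List of [peptide_architecture]s.
#' @param path File path.
#' @return `read_library_csv()` returns a list of `peptide_architecture`s.
#' @export
write_library_csv <- function(library, path) {
  df <- do.call(rbind, lapply(library, function(a) {
    data.frame(id = a$id, valency = a$valency, epitope_seq = a$epitope_seq,
               e = a$epitope_length, o1 = a$o1, o2 = a$o2, o3 = a$o3,
               tokens = a$tokens, stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_csv
#' @export
read_library_csv <- function(path) {
  df <- read_checked_csv(path, c("id", "valency", "epitope_seq", "tokens"))
  lapply(seq_len(nrow(df)), function(i) {
    peptide_architecture(df$id[i], df$valency[i], df$epitope_seq[i],
                         df$tokens[i])
  })
}

#' Write / read sensor traces in long CSV format
#'
#' Columns: `trace_id, spot_role, phase, time_s, signal, conc_nM`.
#'
#' @param traces List of [sensor_trace]s (or one channel set from
#'   [simulate_fps_trace()]).
#' @param path File path.
#' @return `read_trace_csv()` returns a named list of `sensor_trace`s.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "sensor_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(trace_id = attr(tr, "trace_id"),
               spot_role = attr(tr, "spot_role"),
               phase = tr$phase, time_s = tr$time, signal = tr$signal,
               conc_nM = M_to_nM(attr(tr, "analyte_conc")),
               stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read_checked_csv(path, c("trace_id", "spot_role", "phase", "time_s",
                                 "signal", "conc_nM"))
  for (col in c("time_s", "signal", "conc_nM")) {
    df[[col]] <- check_numeric_col(df, col, path)
  }
  out <- lapply(split(df, df$trace_id), function(sub) {
    sub <- sub[order(sub$time_s), , drop = FALSE]
    sensor_trace(time = sub$time_s, signal = sub$signal, phase = sub$phase,
                 analyte_conc = nM_to_M(sub$conc_nM[1L]),
                 spot_role = sub$spot_role[1L], trace_id = sub$trace_id[1L])
  })
  out[unique(df$trace_id)]
}

#' Write / read a dose-response CSV
#'
#' Columns: `conc_nM, f_norm, replicate`.
#'
#' @param dr Data frame with molar `conc`, `f_norm`, `replicate`.
#' @param path File path.
#' @return `read_dose_response_csv()` returns a data frame with molar `conc`.
#' @export
write_dose_response_csv <- function(dr, path) {
  out <- data.frame(conc_nM = M_to_nM(dr$conc), f_norm = dr$f_norm,
                    replicate = dr$replicate)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_response_csv
#' @export
read_dose_response_csv <- function(path) {
  df <- read_checked_csv(path, c("conc_nM", "f_norm", "replicate"))
  for (col in c("conc_nM", "f_norm")) {
    df[[col]] <- check_numeric_col(df, col, path)
  }
  data.frame(conc = nM_to_M(df$conc_nM), f_norm = df$f_norm,
             replicate = df$replicate)
}

#' Write / read a microarray spot CSV
#'
#' Columns: `spot_id, side, condition_id, conc_nM, intensity, background`.
#'
#' @param table Spot table with molar `conc`.
#' @param path File path.
#' @return `read_spot_csv()` returns a spot table with molar `conc`.
#' @export
write_spot_csv <- function(table, path) {
  out <- table
  out$conc_nM <- M_to_nM(out$conc)
  out$conc <- NULL
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_csv
#' @export
read_spot_csv <- function(path) {
  df <- read_checked_csv(path, c("spot_id", "side", "condition_id", "conc_nM",
                                 "intensity", "background"))
  for (col in c("conc_nM", "intensity", "background")) {
    df[[col]] <- check_numeric_col(df, col, path)
  }
  df$conc <- nM_to_M(df$conc_nM)
  df$conc_nM <- NULL
  class(df) <- c("spot_table", "data.frame")
  check_spot_table(df)
  df
}

# ---- run configuration ------------------------------------------------------

#' Run configuration
#'
#' Bundles the seed and per-module parameter blocks of one simulation /
#' analysis run. Configurations round-trip losslessly through JSON, so every
#' output artefact can record exactly how it was produced.
#'
#' @param seed Integer master seed.
#' @param units I/O concentration unit (fixed to `"nM"`).
#' @param ... Named module parameter blocks (lists).
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1L, units = "nM", ...) {
  stopifnot(identical(units, "nM"))
  blocks <- list(...)
  if (length(blocks) && (is.null(names(blocks)) || any(!nzchar(names(blocks))))) {
    stop_multikin("all configuration blocks must be named")
  }
  structure(c(list(seed = as.integer(seed), units = units), blocks),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, c(list(seed = x$seed, units = x$units),
                        x[setdiff(names(x), c("seed", "units"))]))
}

#' One-line structured stage log
#'
#' @param stage Stage name.
#' @param seed Seed in effect.
#' @param params Named list of the stage's resolved parameters.
#' @return The log line, invisibly (also emitted via [message()]).
#' @export
log_stage <- function(stage, seed, params = list()) {
  line <- paste0("[", stage, "] seed=", seed,
                 if (length(params)) paste0(" ", jsonlite::toJSON(params, auto_unbox = TRUE)) else "")
  message(line)
  invisible(line)
}
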