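#' Double referencing of biosensor traces
#'
#' Removes spot-independent and run-independent artefacts by subtracting both
#' the real-time reference spot and a blank (buffer-only) run:
#' `corrected = (measurement - reference) - (blank_measurement - blank_reference)`.
#' All four traces must share the exact time grid and phase structure; no
#' silent interpolation is performed.
#'
#' @param meas,ref,blank_meas,blank_ref [sensor_trace]s on a common grid.
#' @return A [sensor_trace] with the corrected signal, inheriting the
#'   measurement trace's concentration and phase labels.
#' @export
double_reference <- function(meas, ref, blank_meas, blank_ref) {
  traces <- list(meas, ref, blank_meas, blank_ref)
  for (tr in traces) stopifnot(inherits(tr, "sensor_trace"))
  for (tr in traces[-1L]) {
    if (nrow(tr) != nrow(meas) || !isTRUE(all.equal(tr$time, meas$time)) ||
        !identical(tr$phase, meas$phase)) {
      stop_multikin("trace time grids / phase structures are not aligned; ",
                    "double referencing requires identical grids",
                    class = "multikin_alignment_error")
    }
  }
  corrected <- (meas$signal - ref$signal) - (blank_meas$signal - blank_ref$signal)
  sensor_trace(time = meas$time, signal = corrected, phase = meas$phase,
               analyte_conc = attr(meas, "analyte_conc"),
               spot_role = "measurement",
               trace_id = paste0(attr(meas, "trace_id"), "_corrected"))
}

# Log-spaced multi-start grid for observed association rates (1/s).
KOBS_START_GRID <- 10^seq(-4, 1, length.out = 11)

# Exponential association fit on one phase slice: S = A (1 - exp(-k t)).
# Multi-start over KOBS_START_GRID, best RSS, ties broken by smaller k.
fit_association_exp <- function(tt, ss) {
  a0 <- max(abs(ss))
  if (a0 == 0) a0 <- 1
  best <- NULL
  for (k0 in KOBS_START_GRID) {
    fit <- tryCatch(
      minpack.lm::nlsLM(ss ~ A * (1 - exp(-exp(lk) * tt)),
                        start = list(A = a0, lk = log(k0)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    k <- exp(coef(fit)[["lk"]])
    if (is.null(best) || rss < best$rss * (1 - 1e-12) ||
        (abs(rss - best$rss) <= 1e-12 * max(rss, 1) && k < best$k_obs)) {
      se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(A = NA, lk = NA))
      best <- list(k_obs = k, A = coef(fit)[["A"]], rss = rss,
                   se_A = se[["A"]], se_k_obs = k * se[["lk"]])
    }
  }
  best
}

# Exponential decay fit: S = S0 exp(-k t); start from log-linear regression.
fit_dissociation_exp <- function(tt, ss) {
  pos <- ss > 0
  k0 <- 1e-3
  s0 <- max(abs(ss))
  if (sum(pos) >= 3L) {
    cf <- coef(lm(log(ss[pos]) ~ tt[pos]))
    if (is.finite(cf[[2L]]) && cf[[2L]] < 0) k0 <- -cf[[2L]]
    if (is.finite(cf[[1L]])) s0 <- exp(cf[[1L]])
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(ss ~ S0 * exp(-exp(lk) * tt),
                      start = list(S0 = s0, lk = log(max(k0, 1e-8))),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(S0 = NA, lk = NA))
  k <- exp(coef(fit)[["lk"]])
  list(k_off = k, S0 = coef(fit)[["S0"]], rss = sum(stats::resid(fit)^2),
       se_k_off = k * se[["lk"]])
}

#' Fit a single double-referenced trace with the 1:1 exponential model
#'
#' Association phase: \eqn{S(t) = A (1 - e^{-k_{obs} t})}; dissociation
#' phase: \eqn{S(t) = S_0 e^{-k_{off} t}} (local phase clocks). Exponential
#' fits are initialisation-sensitive, so the association fit is multi-started
#' on a log-spaced k_obs grid over \eqn{[10^{-4}, 10]} 1/s and the best start
#' by residual sum of squares wins (ties to the smaller rate).
#'
#' A fit is flagged `"not_determinable"` when the fitted amplitude is below
#' three times the residual noise SD or a relative standard error exceeds
#' 100%; such compounds are excluded from rate maps.
#'
#' @param trace A double-referenced [sensor_trace] whose association phase has
#'   at least 10 points.
#' @param conc Analyte concentration (molar); defaults to the trace attribute.
#' @return List with `k_obs`, `A`, `k_off`, standard errors, `rss`, and
#'   `flag` (`"ok"` or `"not_determinable"`). `k_obs < k_off` triggers a
#'   warning, not an error.
#' @export
fit_single_curve <- function(trace, conc = attr(trace, "analyte_conc")) {
  stopifnot(inherits(trace, "sensor_trace"))
  assoc <- trace_phase(trace, "association")
  if (nrow(assoc) < 10L) {
    stop_multikin("association phase has ", nrow(assoc), " points; >= 10 required")
  }
  fa <- fit_association_exp(phase_time(assoc), assoc$signal)
  dis <- trace_phase(trace, "dissociation")
  fd <- if (nrow(dis) >= 5L) fit_dissociation_exp(phase_time(dis), dis$signal) else NULL

  if (is.null(fa)) {
    return(list(k_obs = NA_real_, A = NA_real_, k_off = NA_real_,
                se_k_obs = NA_real_, se_A = NA_real_, se_k_off = NA_real_,
                rss = NA_real_, flag = "not_determinable"))
  }
  n_a <- nrow(assoc)
  noise_sd <- sqrt(fa$rss / max(n_a - 2L, 1L))
  flag <- "ok"
  if (abs(fa$A) <= 3 * noise_sd) flag <- "not_determinable"
  if (diff(range(assoc$signal)) == 0) flag <- "not_determinable"  # no transient at all
  rel_se <- c(fa$se_k_obs / abs(fa$k_obs), fa$se_A / abs(fa$A))
  if (any(is.finite(rel_se) & rel_se > 1)) flag <- "not_determinable"
  k_off <- if (!is.null(fd)) fd$k_off else NA_real_
  if (is.finite(k_off) && fa$k_obs < k_off) {
    warning("fitted k_obs (", signif(fa$k_obs, 3), ") < k_off (",
            signif(k_off, 3), "); check concentration assignment")
  }
  list(k_obs = fa$k_obs, A = fa$A, k_off = k_off,
       se_k_obs = fa$se_k_obs, se_A = fa$se_A,
       se_k_off = if (!is.null(fd)) fd$se_k_off else NA_real_,
       rss = fa$rss + if (!is.null(fd)) fd$rss else 0,
       flag = flag)
}

# Stacked residuals for the global model. par = c(lkon, lkoff, B_1..B_m).
global_model_resid <- function(par, curves) {
  k_on <- exp(par[[1L]]); k_off <- exp(par[[2L]])
  unlist(lapply(seq_along(curves), function(j) {
    cv <- curves[[j]]
    B <- par[[2L + j]]
    k_obs <- k_on * cv$conc + k_off
    pred_a <- B * (1 - exp(-k_obs * cv$ta))
    s_end <- B * (1 - exp(-k_obs * cv$t_assoc_end))
    pred_d <- s_end * exp(-k_off * cv$td)
    c(cv$sa - pred_a, cv$sd_ - pred_d)
  }), use.names = FALSE)
}

#' Global 1:1 kinetic fit across concentrations
#'
#' Fits all curves jointly with shared `k_on` and `k_off` and one free
#' amplitude per curve. Association follows
#' \eqn{S(t) = B_j (1 - e^{-(k_{on} C_j + k_{off}) t})} and dissociation
#' continues from the association end level with rate `k_off`, so the
#' dissociation data constrain `k_off` directly. `K_D = k_off / k_on` by
#' construction. Standard errors come from the fit covariance (delta method
#' on the log-rate parameters).
#'
#' When the standard error of `k_off` exceeds its estimate the dissociation
#' rate is not resolved and `K_D` is reported as an upper bound
#' (`flag = "kd_upper_bound"`) rather than a point estimate.
#'
#' @param traces List of double-referenced [sensor_trace]s.
#' @param concs Molar concentrations, one per trace; defaults to the trace
#'   attributes.
#' @param id Optional compound identifier carried into rate maps.
#' @return Object of class `kinetic_fit`: list with `k_on`, `k_off`, `K_D`,
#'   `amplitudes`, `association_levels`, `se_k_on`, `se_k_off`, `rss`,
#'   `n_curves`, `flag`, `id`.
#' @examples
#' gt <- ground_truth_kinetics(1e5, 1e-3)
#' trs <- lapply(c(2.5e-7, 1e-6, 4e-6), function(C)
#'   double_reference_set(simulate_fps_trace(gt, C)))
#' fit <- fit_global(trs)
#' @export
fit_global <- function(traces, concs = vapply(traces, attr, numeric(1L), "analyte_conc"),
                       id = NA_character_) {
  stopifnot(length(traces) >= 1L, length(concs) == length(traces))
  assert_non_negative(concs, "concs")
  curves <- lapply(seq_along(traces), function(j) {
    tr <- traces[[j]]
    stopifnot(inherits(tr, "sensor_trace"))
    assoc <- trace_phase(tr, "association")
    if (nrow(assoc) < 10L) {
      stop_multikin("curve ", j, ": association phase has fewer than 10 points")
    }
    dis <- trace_phase(tr, "dissociation")
    ta <- phase_time(assoc)
    dt <- if (nrow(assoc) > 1L) ta[2L] - ta[1L] else 1
    list(conc = concs[[j]], ta = ta, sa = assoc$signal,
         t_assoc_end = ta[length(ta)] + dt,
         td = if (nrow(dis)) phase_time(dis) else numeric(0),
         sd_ = if (nrow(dis)) dis$signal else numeric(0))
  })
  n_dissoc <- sum(vapply(curves, function(cv) length(cv$td), integer(1L)))
  if (length(unique(concs)) == 1L && n_dissoc == 0L) {
    stop_multikin("a single concentration with no dissociation phase cannot ",
                  "separate k_on from k_off; provide dissociation data")
  }

  # initial values: k_off from pooled dissociation decay, k_obs from
  # single-curve association fits, amplitudes from plateau levels
  k_off0 <- 1e-3
  dis_t <- unlist(lapply(curves, function(cv) cv$td))
  dis_s <- unlist(lapply(curves, function(cv) cv$sd_))
  if (length(dis_t) >= 3L && any(dis_s > 0)) {
    keep <- dis_s > 0
    sl <- coef(lm(log(dis_s[keep]) ~ dis_t[keep]))[[2L]]
    if (is.finite(sl) && sl < 0) k_off0 <- -sl
  }
  B0 <- vapply(curves, function(cv) {
    tail_n <- max(1L, ceiling(0.1 * length(cv$sa)))
    mean(cv$sa[(length(cv$sa) - tail_n + 1L):length(cv$sa)])
  }, numeric(1L))
  B0[!is.finite(B0) | B0 == 0] <- max(abs(unlist(lapply(curves, `[[`, "sa"))), 1e-6)
  cmax <- max(concs[concs > 0], 1e-9)
  kobs0 <- vapply(curves, function(cv) {
    fa <- fit_association_exp(cv$ta, cv$sa)
    if (is.null(fa)) NA_real_ else fa$k_obs
  }, numeric(1L))
  k_on0 <- max((max(kobs0, na.rm = TRUE) - k_off0) / cmax, 1e-2)

  starts <- list(c(log(k_on0), log(k_off0), B0))
  for (ko in c(1e-4, 1e-2, 1)) {
    starts <- c(starts, list(c(log(max((max(kobs0, na.rm = TRUE)) / cmax, 1e-2)),
                               log(ko), B0)))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = global_model_resid, curves = curves,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$deviance * (1 - 1e-12) ||
        (abs(rss - best$deviance) <= 1e-12 * max(rss, 1) &&
         fit$par[[1L]] < best$par[[1L]])) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop_multikin("global kinetic fit did not converge from any start",
                  class = "multikin_fit_error")
  }
  p <- best$par
  k_on <- exp(p[[1L]]); k_off <- exp(p[[2L]])
  np <- length(p)
  n_obs <- sum(vapply(curves, function(cv) length(cv$sa) + length(cv$sd_), integer(1L)))
  s2 <- best$deviance / max(n_obs - np, 1L)
  cov <- tryCatch(s2 * solve(best$hessian), error = function(e) NULL)
  se_log <- if (!is.null(cov)) sqrt(pmax(diag(cov), 0)) else rep(NA_real_, np)
  se_k_on <- k_on * se_log[[1L]]
  se_k_off <- k_off * se_log[[2L]]
  flag <- "ok"
  if (is.finite(se_k_off) && se_k_off > k_off) flag <- "kd_upper_bound"
  amps <- p[-(1:2)]
  noise_sd <- sqrt(s2)
  if (all(abs(amps) < 3 * noise_sd)) flag <- "not_determinable"
  levels <- vapply(curves, function(cv) {
    tail_n <- max(1L, ceiling(0.1 * length(cv$sa)))
    mean(cv$sa[(length(cv$sa) - tail_n + 1L):length(cv$sa)])
  }, numeric(1L))
  structure(list(k_on = k_on, k_off = k_off, K_D = k_off / k_on,
                 amplitudes = stats::setNames(amps, signif(concs, 4)),
                 association_levels = stats::setNames(levels, signif(concs, 4)),
                 se_k_on = se_k_on, se_k_off = se_k_off,
                 rss = best$deviance, n_curves = length(curves),
                 flag = flag, id = id),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(paste0("<kinetic_fit>%s k_on = %.4g /M/s (se %.2g), ",
                     "k_off = %.4g /s (se %.2g), K_D = %.4g M [%s, %d curves]\n"),
              if (is.na(x$id)) "" else paste0(" ", x$id),
              x$k_on, x$se_k_on, x$k_off, x$se_k_off, x$K_D, x$flag, x$n_curves))
  invisible(x)
}

#' Convenience: double-reference a simulated four-channel set
#'
#' @param channel_set Named list as returned by [simulate_fps_trace()].
#' @return The corrected [sensor_trace].
#' @export
double_reference_set <- function(channel_set) {
  double_reference(channel_set$measurement, channel_set$reference,
                   channel_set$blank_measurement, channel_set$blank_reference)
}

#' Association level of a trace
#'
#' The plateau signal reached during the association phase. The primary
#' definition is the mean of the final 10% of association-phase points; the
#' fitted exponential plateau amplitude is reported alongside for comparison.
#'
#' @param trace A [sensor_trace] whose association phase has >= 10 points.
#' @param tail_fraction Fraction of trailing association points averaged.
#' @return List with `level` (tail mean) and `fitted_amplitude`.
#' @export
association_level <- function(trace, tail_fraction = 0.1) {
  stopifnot(inherits(trace, "sensor_trace"))
  assoc <- trace_phase(trace, "association")
  if (nrow(assoc) < 10L) {
    stop_multikin("association phase has ", nrow(assoc), " points; >= 10 required")
  }
  n <- nrow(assoc)
  tail_n <- max(1L, ceiling(tail_fraction * n))
  level <- mean(assoc$signal[(n - tail_n + 1L):n])
  fa <- fit_association_exp(phase_time(assoc), assoc$signal)
  list(level = level, fitted_amplitude = if (is.null(fa)) NA_real_ else fa$A)
}

#' Assemble a rate map from fits and a peptide library
#'
#' Joins kinetic fits to their architectures and drops compounds without a
#' determinable fit, giving the table behind an on-rate vs off-rate scatter
#' ("rate map"). Iso-affinity diagonals at K_D = 10 uM, 1 uM and 100 nM are
#' attached as the `iso_affinity_M` attribute for plotting.
#'
#' @param fits List of [fit_global()] results carrying `id`s.
#' @param library List of [peptide_architecture]s with matching ids.
#' @return Data frame with columns id, k_on, k_off, K_D, valency,
#'   epitope_length, tokens, flag; attribute `iso_affinity_M`.
#' @export
build_rate_map <- function(fits, library) {
  fit_ids <- vapply(fits, `[[`, character(1L), "id")
  if (anyNA(fit_ids)) stop_multikin("every fit must carry an id")
  if (anyDuplicated(fit_ids)) {
    stop_multikin("duplicate fit ids: ",
                  paste(unique(fit_ids[duplicated(fit_ids)]), collapse = ", "))
  }
  lib_ids <- vapply(library, `[[`, character(1L), "id")
  if (anyDuplicated(lib_ids)) {
    stop_multikin("duplicate library ids: ",
                  paste(unique(lib_ids[duplicated(lib_ids)]), collapse = ", "))
  }
  keep <- vapply(fits, function(f) f$flag != "not_determinable", logical(1L))
  rows <- lapply(fits[keep], function(f) {
    a <- library[[match(f$id, lib_ids)]]
    if (is.null(a)) stop_multikin("fit id '", f$id, "' not present in library")
    data.frame(id = f$id, k_on = f$k_on, k_off = f$k_off, K_D = f$K_D,
               valency = a$valency, epitope_length = a$epitope_length,
               tokens = a$tokens, flag = f$flag, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), k_on = numeric(0), k_off = numeric(0),
               K_D = numeric(0), valency = integer(0),
               epitope_length = integer(0), tokens = character(0),
               flag = character(0), stringsAsFactors = FALSE)
  attr(out, "iso_affinity_M") <- c(1e-5, 1e-6, 1e-7)
  out
}
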