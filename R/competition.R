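#' Competition assay setup
#'
#' Total concentrations of target and fluorescent tracer plus the tracer's
#' dissociation constant, as used by the K_i conversion of displacement EC50
#' values.
#'
#' @param T_t Total target concentration (molar), > 0.
#' @param C_t Total tracer concentration (molar), > 0.
#' @param K_D_tracer Tracer-target dissociation constant (molar), > 0.
#' @return Object of class `competition_setup`.
#' @export
competition_setup <- function(T_t, C_t, K_D_tracer) {
  assert_positive(T_t, "T_t")
  assert_positive(C_t, "C_t")
  assert_positive(K_D_tracer, "K_D_tracer")
  structure(list(T_t = T_t, C_t = C_t, K_D_tracer = K_D_tracer),
            class = "competition_setup")
}

#' Equilibrium bound-tracer fraction (gamma)
#'
#' Closed-form fraction of tracer bound to target in the absence of
#' competitor, from the two-species binding quadratic:
#' \deqn{\gamma = \frac{[T]_t + [C]_t + K_D -
#'   \sqrt{([T]_t + [C]_t + K_D)^2 - 4 [T]_t [C]_t}}{2 [C]_t}}
#' Always lies in \eqn{(0, \min(1, [T]_t/[C]_t)]}.
#'
#' @param setup A [competition_setup].
#' @return Dimensionless bound fraction.
#' @examples
#' tracer_bound_fraction(competition_setup(20e-9, 10e-9, 10e-9))  # ~0.586
#' @export
tracer_bound_fraction <- function(setup) {
  stopifnot(inherits(setup, "competition_setup"))
  Tt <- setup$T_t; Ct <- setup$C_t; KD <- setup$K_D_tracer
  S <- Tt + Ct + KD
  disc <- S^2 - 4 * Tt * Ct
  if (disc < 0) stop_multikin("negative discriminant in bound-fraction quadratic")
  # algebraically equal to (S - sqrt(disc)) / (2 Ct) but immune to the
  # catastrophic cancellation that form suffers when C_t << T_t, K_D
  2 * Tt / (S + sqrt(disc))
}

#' Convert a displacement EC50 to K_i
#'
#' Exact correction of a competition-assay EC50 for tracer and target
#' concentrations:
#' \deqn{K_i = \frac{K_D}{2-\gamma}\left(
#'   \frac{EC_{50}}{[T]_t/\gamma - K_D/(2-\gamma) - [C]_t/2} - \gamma\right)}
#' with \eqn{\gamma} the no-competitor bound-tracer fraction
#' ([tracer_bound_fraction()]). The denominator term must be positive; when
#' it is not, the tracer/target concentrations are too high relative to the
#' measured EC50 and no K_i can be assigned (assay window violated).
#'
#' @param ec50 Fitted EC50 (molar), > 0.
#' @param setup A [competition_setup].
#' @return K_i (molar).
#' @export
ki_from_ec50 <- function(ec50, setup) {
  stopifnot(inherits(setup, "competition_setup"))
  assert_positive(ec50, "ec50")
  g <- tracer_bound_fraction(setup)
  denom <- setup$T_t / g - setup$K_D_tracer / (2 - g) - setup$C_t / 2
  if (denom <= 0) {
    stop_multikin("assay window violated: T_t/gamma - K_D/(2-gamma) - C_t/2 <= 0; ",
                  "tracer/target too concentrated relative to the EC50",
                  class = "multikin_assay_window_error")
  }
  setup$K_D_tracer / (2 - g) * (ec50 / denom - g)
}

#' Exact three-species competitive equilibrium
#'
#' Solves the ternary equilibrium target + tracer + competitor by monotone
#' root bracketing on the free-target concentration (numerically robust for
#' extreme constants; no cubic closed form). Mass balance and both
#' mass-action laws hold to a relative tolerance of 1e-10.
#'
#' @param T_t,C_t,L_t Total target, tracer, competitor concentrations
#'   (molar), >= 0.
#' @param K_D Tracer-target dissociation constant (molar), > 0.
#' @param K_i Competitor-target dissociation constant (molar), > 0.
#' @return Named list: `T_free`, `TC` (target-tracer complex), `TL`
#'   (target-competitor complex), all molar.
#' @export
solve_competitive_equilibrium <- function(T_t, C_t, L_t, K_D, K_i) {
  assert_non_negative(c(T_t, C_t, L_t), "total concentrations")
  assert_positive(K_D, "K_D")
  assert_positive(K_i, "K_i")
  if (T_t == 0) return(list(T_free = 0, TC = 0, TL = 0))
  # T (1 + C_t/(K_D+T) + L_t/(K_i+T)) - T_t is strictly increasing in T
  f <- function(T) T * (1 + C_t / (K_D + T) + L_t / (K_i + T)) - T_t
  sol <- uniroot(f, lower = 0, upper = T_t, tol = 1e-14 * T_t,
                 f.lower = -T_t, maxiter = 200L)
  T_free <- sol$root
  list(T_free = T_free,
       TC = T_free * C_t / (K_D + T_free),
       TL = T_free * L_t / (K_i + T_free))
}

#' Direct tracer K_D fit (tight-binding quadratic isotherm)
#'
#' Fits a target titration of a fixed low tracer concentration with the
#' quadratic (ligand-depletion) isotherm: the bound fraction at titrated
#' target `T` is [tracer_bound_fraction()] evaluated at `(T, tracer_conc,
#' K_D)`, mapped affinely to the signal with free `bottom` and `top`. The
#' quadratic form remains unbiased when `K_D` is comparable to the tracer
#' concentration, where a hyperbolic fit fails.
#'
#' @param concs Titrated target concentrations (molar), >= 6 values spanning
#'   the transition.
#' @param signal Measured signal at each concentration.
#' @param tracer_conc Fixed tracer concentration (molar).
#' @return List with `K_D`, `bottom`, `top`, `se_K_D`, `rss`.
#' @export
fit_direct_kd <- function(concs, signal, tracer_conc = 1e-9) {
  stopifnot(length(concs) == length(signal))
  if (length(concs) < 6L) stop_multikin("at least 6 concentrations required")
  assert_non_negative(concs, "concs")
  assert_positive(tracer_conc, "tracer_conc")
  if (stats::sd(signal) < 1e-12 * max(abs(signal), 1)) {
    stop_multikin("signal is constant; K_D not identifiable",
                  class = "multikin_identifiability_error")
  }
  bound_frac <- function(T, KD) {
    s <- T + tracer_conc + KD
    (s - sqrt(s^2 - 4 * T * tracer_conc)) / (2 * tracer_conc)
  }
  # start K_D near the half-signal crossing
  mid <- (max(signal) + min(signal)) / 2
  kd0 <- concs[which.min(abs(signal - mid))]
  if (kd0 <= 0) kd0 <- median(concs[concs > 0])
  fit <- minpack.lm::nlsLM(
    signal ~ bottom + (top - bottom) * bound_frac(concs, exp(lkd)),
    start = list(bottom = min(signal), top = max(signal), lkd = log(kd0)),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3L))
  kd <- exp(coef(fit)[["lkd"]])
  list(K_D = kd, bottom = coef(fit)[["bottom"]], top = coef(fit)[["top"]],
       se_K_D = kd * se[[3L]], rss = sum(stats::resid(fit)^2))
}

# Core 4PL evaluation: decreasing in conc for h > 0; handles conc = 0 (-> top).
hill4pl <- function(conc, top, bottom, ec50, h) {
  bottom + (top - bottom) / (1 + (conc / ec50)^h)
}

#' Four-parameter Hill fit of a dose-response curve
#'
#' Fits \eqn{y = bottom + (top - bottom) / (1 + (c/EC_{50})^h)} with the
#' EC50 parameterised on the log10 scale. A zero-concentration (no
#' competitor) condition may be included and anchors the top plateau. To keep
#' 16-point fits stable, the Hill slope is bounded to [0.3, 5] and the bottom
#' to [0, 1.5 x min(signal)]. Both orientations (displacement and
#' activation) are handled: an increasing curve is fitted on its reflection,
#' which leaves the EC50 unchanged.
#'
#' Because an exact competitive-displacement curve is not a logistic, a
#' one-stage 4PL midpoint is slightly biased when the transition touches a
#' grid edge. The fit therefore runs in two stages: a full-grid 4PL, then a
#' refit restricted to the transition window - points where the *fitted*
#' curve lies between 10% and 90% of its span (a smooth criterion that does
#' not react to per-point noise) - plus the zero-concentration and
#' top-concentration anchor points.
#'
#' @param concs Concentrations (molar), non-negative; at least 5 points.
#' @param response Signal at each concentration (e.g. F_norm).
#' @return Object of class `hill_fit`: list with `EC50`, `hill_slope`,
#'   `top`, `bottom`, `se_log10_EC50`, `se_hill_slope`, `rss`, `flag`
#'   (`"ok"`, `"ec50_below_grid"`, `"ec50_above_grid"`, or
#'   `"no_transition"`) and `orientation` (`"decreasing"`/`"increasing"`).
#' @export
fit_hill <- function(concs, response) {
  stopifnot(length(concs) == length(response))
  if (length(concs) < 5L) stop_multikin("at least 5 points required for a Hill fit")
  assert_non_negative(concs, "concs")
  if (sum(concs > 0) < 4L) stop_multikin("at least 4 positive concentrations required")

  span <- max(response) - min(response)
  if (span < 1e-12 * max(abs(response), 1)) {
    return(structure(list(EC50 = max(concs), hill_slope = NA_real_,
                          top = mean(response), bottom = mean(response),
                          se_log10_EC50 = NA_real_, se_hill_slope = NA_real_,
                          rss = 0, flag = "no_transition",
                          orientation = "decreasing"),
                     class = "hill_fit"))
  }
  # orientation: fit the decreasing form, reflecting increasing data
  pos <- concs > 0
  increasing <- stats::cor(log10(concs[pos]), response[pos]) > 0
  y <- if (increasing) max(response) + min(response) - response else response

  do_fit <- function(x, yy, start) {
    minpack.lm::nlsLM(
      yy ~ hill4pl(x, top, bottom, 10^lec, h),
      data = list(x = x, yy = yy),
      start = start,
      lower = c(top = -Inf, bottom = 0, lec = log10(min(concs[pos]) / 1e4),
                h = 0.3),
      upper = c(top = Inf, bottom = 1.5 * min(yy), lec = log10(max(concs) * 1e4),
                h = 5),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  mid <- (max(y) + min(y)) / 2
  ec0 <- concs[pos][which.min(abs(y[pos] - mid))]
  start <- list(top = max(y), bottom = max(min(y), 0), lec = log10(ec0), h = 1)
  fit1 <- do_fit(concs, y, start)
  cf <- as.list(coef(fit1))

  # stage 2: transition-window refit with plateau anchors; the window is
  # judged on the fitted curve, not the noisy data
  pfit <- 1 / (1 + (concs / 10^cf$lec)^cf$h)
  keep <- concs == 0 | concs == max(concs) | (pfit > 0.1 & pfit < 0.9)
  fit <- if (sum(keep) >= 5L && sum(keep) < length(concs)) {
    tryCatch(do_fit(concs[keep], y[keep], cf), error = function(e) fit1)
  } else fit1
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, 4L), names(cf)))
  ec50 <- 10^cf[["lec"]]
  flag <- "ok"
  if (ec50 < min(concs[pos])) flag <- "ec50_below_grid"
  if (ec50 > max(concs)) flag <- "ec50_above_grid"
  top <- cf[["top"]]; bottom <- cf[["bottom"]]
  if (increasing) {
    t2 <- max(response) + min(response) - bottom
    bottom <- max(response) + min(response) - top
    top <- t2
  }
  structure(list(EC50 = ec50, hill_slope = cf[["h"]], top = top,
                 bottom = bottom, se_log10_EC50 = se[["lec"]],
                 se_hill_slope = se[["h"]],
                 rss = sum(stats::resid(fit)^2), flag = flag,
                 orientation = if (increasing) "increasing" else "decreasing"),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> EC50 = %.4g M, slope = %.3g, top = %.4g, bottom = %.4g [%s]\n",
              x$EC50, x$hill_slope, x$top, x$bottom, x$flag))
  invisible(x)
}

#' Full displacement analysis: Hill fit plus K_i conversion
#'
#' @param concs Competitor concentrations (molar, may include 0).
#' @param f_norm Normalised fluorescence response.
#' @param setup A [competition_setup].
#' @return List with `hill` (the [fit_hill()] result) and `K_i` (molar).
#' @export
ki_from_dose_response <- function(concs, f_norm, setup) {
  hf <- fit_hill(concs, f_norm)
  list(hill = hf, K_i = ki_from_ec50(hf$EC50, setup))
}
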