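#' Simulate a TRIC competition dose-response plate
#'
#' Generates a competitor dilution series (1:`factor` serial dilution from
#' `top_conc`) and, for each competitor concentration, solves the exact
#' three-species equilibrium ([solve_competitive_equilibrium()]) for the
#' bound-tracer fraction, which is mapped affinely to the normalised
#' fluorescence F_norm. A zero-competitor condition is included so downstream
#' fits can anchor the undisplaced level. Additive Gaussian noise is optional.
#'
#' @param setup A [competition_setup].
#' @param K_i Planted competitor dissociation constant (molar), > 0.
#' @param top_conc Highest final competitor concentration (molar).
#' @param n_points Number of dilution points (>= 4).
#' @param f_unbound,f_bound F_norm (permille) at zero and full tracer
#'   occupancy; the affine signal map.
#' @param noise_sd Additive Gaussian noise SD on F_norm.
#' @param replicates Replicate wells per concentration.
#' @param include_zero Include the zero-competitor reference condition.
#' @param seed Integer seed for noise.
#' @return Data frame with columns `conc` (molar), `f_norm`, `replicate`.
#' @examples
#' st <- competition_setup(20e-9, 10e-9, 25e-9)
#' dr <- simulate_tric_plate(st, K_i = 1e-7)
#' min(dr$conc[dr$conc > 0]) * 1e9  # 30.52 nM
#' @export
simulate_tric_plate <- function(setup, K_i, top_conc = 1e-3, n_points = 16L,
                                f_unbound = 800, f_bound = 900,
                                noise_sd = 0, replicates = 1L,
                                include_zero = TRUE, seed = NULL) {
  stopifnot(inherits(setup, "competition_setup"))
  assert_positive(K_i, "K_i")
  if (n_points < 4L) stop_multikin("n_points must be >= 4")
  concs <- dilution_series(top_conc, n_points)
  if (include_zero) concs <- c(0, concs)
  fb <- vapply(concs, function(L) {
    eq <- solve_competitive_equilibrium(setup$T_t, setup$C_t, L,
                                        setup$K_D_tracer, K_i)
    eq$TC / setup$C_t
  }, numeric(1L))
  f_true <- f_unbound + (f_bound - f_unbound) * fb
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    data.frame(conc = concs, f_norm = f_true, replicate = r)
  }))
  if (noise_sd > 0) {
    out$f_norm <- out$f_norm +
      with_seed(seed, stats::rnorm(nrow(out), sd = noise_sd))
  }
  out
}

#' Simulate a microarray competition spot table
#'
#' Emulates the structure of a peptide-microarray competition experiment:
#' each condition (one competitor concentration, plus a mandatory
#' no-competitor control) carries `spots` spots printed as internal left/right
#' duplicates, each with a raw intensity and a local background estimate.
#' The expected specific intensity falls with competitor concentration as a
#' logistic in log-concentration with midpoint `IC50`.
#'
#' @param spots Number of distinct spots per condition.
#' @param competitor_concs Competitor concentrations (molar); 0 is added as
#'   the control condition if absent. The default is the 16-point 1:1
#'   dilution series from 1 mM used throughout the competition assays.
#' @param IC50 Planted half-neutralisation concentration (molar).
#' @param hill_slope Slope of the neutralisation logistic.
#' @param intensity Mean full-binding spot intensity (greyscale units).
#' @param background Mean local background level.
#' @param noise_cv Relative (CV) Gaussian noise on spot intensities.
#' @param seed Integer seed.
#' @return Data frame (class `spot_table`) with columns `spot_id`, `side`,
#'   `condition_id`, `conc` (molar), `intensity`, `background`.
#' @export
simulate_microarray <- function(spots = 8L,
                                competitor_concs = 1e-3 / 2^(0:15),
                                IC50 = 1e-6, hill_slope = 1,
                                intensity = 1e4, background = 500,
                                noise_cv = 0, seed = NULL) {
  assert_positive(IC50, "IC50")
  assert_non_negative(competitor_concs, "competitor_concs")
  concs <- sort(unique(c(0, competitor_concs)))
  spot_ids <- sprintf("spot%02d", seq_len(spots))
  # per-spot intensity heterogeneity, fixed across conditions
  spot_scale <- with_seed(child_seed(seed, 0L),
                          exp(stats::rnorm(spots, sd = if (noise_cv > 0) 0.2 else 0)))
  rows <- list()
  for (ci in seq_along(concs)) {
    L <- concs[[ci]]
    rel <- 1 / (1 + (L / IC50)^hill_slope)
    for (side in c("left", "right")) {
      mu <- intensity * spot_scale * rel
      noise <- if (noise_cv > 0) {
        with_seed(child_seed(seed, 1000L * ci + (side == "right")),
                  stats::rnorm(spots, sd = noise_cv)) * mu
      } else 0
      rows[[length(rows) + 1L]] <- data.frame(
        spot_id = spot_ids, side = side,
        condition_id = sprintf("cond%02d", ci), conc = L,
        intensity = pmax(mu + noise + background, 0),
        background = background, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("spot_table", "data.frame")
  out
}
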