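# Shared fixtures, built in code at test time.

# The standard competition assay conditions: 20 nM target, 10 nM tracer,
# 25 nM tracer K_D.
std_setup <- function(K_D_tracer = 25e-9) {
  competition_setup(T_t = 20e-9, C_t = 10e-9, K_D_tracer = K_D_tracer)
}

# Independent two-species bound-fraction oracle: numeric root of the binding
# quadratic via uniroot, polished with Newton steps to machine precision,
# then TC / C_t.
oracle_bound_fraction <- function(T_t, C_t, K_D) {
  f <- function(T) T + T * C_t / (K_D + T) - T_t
  T <- uniroot(f, c(0, T_t), tol = 1e-15 * max(T_t, 1e-12))$root
  for (i in 1:3) {
    fp <- 1 + C_t * K_D / (K_D + T)^2
    T <- T - f(T) / fp
  }
  (T * C_t / (K_D + T)) / C_t
}

# Exact EC50 (half-displacement concentration) from the ternary equilibrium.
oracle_ec50 <- function(setup, K_i) {
  g <- tracer_bound_fraction(setup)
  half <- g / 2 * setup$C_t
  f <- function(L) {
    solve_competitive_equilibrium(setup$T_t, setup$C_t, L,
                                  setup$K_D_tracer, K_i)$TC - half
  }
  uniroot(f, c(1e-13, 10), tol = 1e-16)$root
}

# Standard three-concentration noiseless trace set, double-referenced.
fps_curves <- function(gt, concs = c(2.5e-7, 1e-6, 4e-6), noise_sd = 0,
                       seed = NULL, ...) {
  lapply(seq_along(concs), function(i) {
    double_reference_set(simulate_fps_trace(gt, concs[i], noise_sd = noise_sd,
                                            seed = child_seed_helper(seed, i),
                                            ...))
  })
}

child_seed_helper <- function(seed, i) if (is.null(seed)) NULL else seed * 100 + i
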