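toy_responses <- function() {
  data.frame(
    id = c("a", "b", "c", "d"),
    epitope_seq = c("FSIVG", "FSIVG", "FSIVGS", "FSIVGSL"),
    tokens = c("J", "J", "JO", "JOJ"),
    valency = c(2, 2, 4, 8),
    K_D = c(1e-9, 2e-9, 9e-9, 5e-8),
    k_on = c(1e5, 1.1e5, 2e5, 4e5),
    k_off = c(1e-4, 2.2e-4, 1.8e-3, 2e-2),
    stringsAsFactors = FALSE)
}

test_that("response preparation filters, aggregates medians and transforms", {
  tab <- toy_responses()
  tab$K_D[4] <- NA
  out <- prepare_responses(tab)
  expect_identical(nrow(out), 2L)  # d dropped, a/b collapsed
  expect_equal(out$K_D[out$epitope_seq == "FSIVG"], 1.5e-9)  # median of 1, 2
  expect_equal(out$kd_logsq, log(out$K_D)^2)
  # three-replicate median
  trip <- toy_responses()[c(1, 1, 1), ]
  trip$K_D <- c(1e-9, 2e-9, 9e-9)
  expect_equal(prepare_responses(trip)$K_D, 2e-9)
  # closed-form transform values
  expect_equal(log_square(1), 0)
  expect_equal(log_square(exp(2)), 4)
  expect_equal(inverse_log_square(log_square(25e-9)), 25e-9)
  # empty after filtering is an error
  bad <- toy_responses()
  bad$k_on <- NA
  expect_error(prepare_responses(bad), "no peptides")
})

test_that("AAC encoding gives residue fractions summing to one", {
  v <- encode_aac("AA")
  expect_equal(unname(v["AAC.A"]), 1)
  expect_equal(sum(v), 1)
  core <- encode_aac("FSIVG")
  expect_equal(unname(core[paste0("AAC.", c("F", "S", "I", "V", "G"))]),
               rep(0.2, 5))
  expect_equal(sum(core), 1)
  expect_equal(unname(encode_aac("ACDE")[paste0("AAC.", c("A", "C", "D", "E"))]),
               rep(0.25, 4))
  expect_error(encode_aac("FSXVG"), "position 3")
})

test_that("linker one-hot encoding maps J/O/gap to the stated bit pairs", {
  expect_equal(unname(encode_linker("")), rep(0, 14))
  expect_equal(unname(encode_linker("J")), c(1, 0, rep(0, 12)))
  expect_equal(unname(encode_linker("JOJ")),
               c(1, 0, 0, 1, 1, 0, rep(0, 8)))
  # bits are pairwise exclusive per position: never [1, 1]
  set.seed(3)
  for (i in 1:20) {
    tk <- paste(sample(c("J", "O"), sample(0:7, 1), replace = TRUE),
                collapse = "")
    v <- encode_linker(tk)
    pairs <- matrix(v, ncol = 2, byrow = TRUE)
    expect_true(all(rowSums(pairs) <= 1))
  }
  expect_error(encode_linker("JOOOOOOO"), class = "multikin_capacity_error")
})

test_that("feature matrix has 34 pre-filter columns and a recorded mask", {
  resp <- prepare_responses(toy_responses())
  enc <- build_feature_matrix(resp)
  expect_identical(ncol(enc$X_full), 34L)
  expect_identical(length(enc$feature_names), 34L)
  # AAC rows sum to 1
  expect_equal(unname(rowSums(enc$X_full[, 1:20])), rep(1, nrow(enc$X_full)))
  # residues absent from every epitope are zero-variance and removed
  expect_false("AAC.W" %in% colnames(enc$X))
  expect_true(all(apply(enc$X, 2, var) > 0))
  # duplicating a row leaves the mask unchanged
  enc2 <- build_feature_matrix(resp[c(1, 1, 2, 3), ])
  expect_identical(enc2$kept, enc$kept)
  # paper-scale shape: n peptides x 34 features before removal
  lib <- generate_library()
  kin <- plant_library_kinetics(lib, seed = 5)
  enc3 <- build_feature_matrix(prepare_responses(kin))
  expect_identical(ncol(enc3$X_full), 34L)
  expect_identical(nrow(enc3$X_full), nrow(prepare_responses(kin)))
})

test_that("R-squared and Pearson match hand-computed values", {
  y <- c(1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)
  x <- c(0.3, 1.7, 4.2, 8)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(1)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(abs(pearson_r(a, b)), 0.05)
})

test_that("bootstrap CI behaves at the degenerate and consistency limits", {
  y <- seq(1, 10)
  ci <- bootstrap_ci(y, y, n_boot = 1000, seed = 4)
  expect_equal(ci$point, 1)
  expect_equal(ci$lo, 1)
  expect_equal(ci$hi, 1)
  expect_identical(ci$n_boot, 1000)
  # interval narrows with sample size for a fixed noisy signal
  width <- function(n, seed) {
    set.seed(seed)
    yy <- rnorm(n)
    yh <- yy + rnorm(n, sd = 0.5)
    ci <- bootstrap_ci(yy, yh, n_boot = 400, seed = seed)
    ci$hi - ci$lo
  }
  expect_lt(width(1000, 8), width(10, 8))
  # deterministic per seed
  set.seed(99); yy <- rnorm(30); yh <- yy + rnorm(30, sd = 1)
  c1 <- bootstrap_ci(yy, yh, seed = 5)
  c2 <- bootstrap_ci(yy, yh, seed = 5)
  expect_identical(c1, c2)
})

test_that("LOOCV prediction is honest, order-invariant and seed-deterministic", {
  set.seed(21)
  n <- 30
  resp <- data.frame(
    id = sprintf("p%02d", 1:n),
    epitope_seq = replicate(n, paste(sample(c("F", "S", "I", "V", "G", "A", "L"),
                                            6, replace = TRUE), collapse = "")),
    tokens = replicate(n, paste(sample(c("J", "O"), 3, replace = TRUE),
                                collapse = "")),
    K_D = 10^runif(n, -9, -6), k_on = 10^runif(n, 3, 6),
    k_off = 10^runif(n, -4, -2), stringsAsFactors = FALSE)
  resp <- prepare_responses(resp)
  enc <- build_feature_matrix(resp)
  # planted linear signal in one feature: the linear baseline nails it
  enc$responses$linear_sig <- 3 * enc$X[, 1] + 0.5
  rep_lin <- loocv_predict(enc, "linear_sig", model = "linear", n_boot = 10)
  expect_gte(rep_lin$r2_total, 0.9)
  # pure-noise response: no better than the mean
  enc$responses$noise_sig <- rnorm(nrow(enc$X))
  rep_noise <- loocv_predict(enc, "noise_sig", model = "forest", seed = 2,
                             n_boot = 10)
  expect_lte(rep_noise$r2_total, 0.15)
  # permuting rows leaves predictions unchanged (set semantics)
  perm <- sample(nrow(enc$responses))
  enc_p <- build_feature_matrix(enc$responses[perm, ])
  enc_p$responses$noise_sig <- enc$responses$noise_sig[perm]
  rep_perm <- loocv_predict(enc_p, "noise_sig", model = "forest", seed = 2,
                            n_boot = 10)
  o1 <- rep_noise$predictions[order(rep_noise$predictions$id), ]
  o2 <- rep_perm$predictions[order(rep_perm$predictions$id), ]
  expect_equal(o1$predicted, o2$predicted)
  # deterministic per seed
  rep2 <- loocv_predict(enc, "noise_sig", model = "forest", seed = 2,
                        n_boot = 10)
  expect_identical(rep_noise$predictions, rep2$predictions)
  expect_error(loocv_predict(build_feature_matrix(resp[1:2, ]), "kd_logsq"),
               "at least 3")
})

test_that("duplicated peptide with shifted response only changes its own fold", {
  set.seed(31)
  n <- 15
  resp <- data.frame(
    id = sprintf("q%02d", 1:n),
    epitope_seq = replicate(n, paste(sample(c("F", "S", "I", "V", "G", "A"),
                                            5, replace = TRUE), collapse = "")),
    tokens = replicate(n, paste(sample(c("J", "O"), 2, replace = TRUE),
                                collapse = "")),
    K_D = 10^runif(n, -9, -6), k_on = 10^runif(n, 3, 6),
    k_off = 10^runif(n, -4, -2), stringsAsFactors = FALSE)
  resp <- prepare_responses(resp)
  enc <- build_feature_matrix(resp)
  base <- loocv_predict(enc, "kd_logsq", model = "linear", n_boot = 5)
  # every prediction comes from a model never shown the held-out row: a
  # perfect-memorisation learner would otherwise reach R2 = 1 here
  expect_lt(base$r2_total, 1 - 1e-8)
})
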