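test_that("the sensitivity matrix has the expected structure", {
  S <- sensitivity_matrix(fitted, onoff)
  expect_equal(dim(unclass(S)), c(50L, 13L))
  expect_identical(colnames(S), nfkb_param_names)
  expect_identical(attr(S, "dim_points"), 41L)
  # geometric-mean normalization forces per-series column sums to ~0
  info <- attr(S, "info")
  key <- interaction(info$genotype, info$observable, drop = TRUE)
  for (j in seq_len(13)) {
    sums <- tapply(S[, j], key, sum)
    expect_lt(max(abs(sums)), 1e-6)
  }
})

test_that("finite-difference sensitivities are step-size converged", {
  S1 <- sensitivity_matrix(fitted, onoff, rel_step = 0.01)
  S2 <- sensitivity_matrix(fitted, onoff, rel_step = 0.001)
  big <- abs(unclass(S2)) > 1e-3
  expect_lt(max(abs((unclass(S1)[big] - unclass(S2)[big]) /
                      unclass(S2)[big])), 0.01)
})

test_that("scaled singular values are invariant under protocol repetition", {
  S1 <- sensitivity_matrix(fitted, onoff)
  S2 <- sensitivity_matrix(fitted, list(onoff, onoff))
  expect_equal(scaled_singular_values(S1), scaled_singular_values(S2),
               tolerance = 1e-8)
  expect_length(scaled_singular_values(S1), 13L)
  expect_equal(sensitivity_norms(S1), sensitivity_norms(S2),
               tolerance = 1e-8)
})

test_that("perpendicular components contract and vanish for dependent columns", {
  withr::local_seed(19)
  for (i in 1:5) {
    M <- matrix(rnorm(40 * 13), 40, 13,
                dimnames = list(NULL, nfkb_param_names))
    perp <- perpendicular_norms(M, dim_points = 40)
    norms <- sensitivity_norms(M, dim_points = 40)
    expect_true(all(perp <= norms + 1e-12))
  }
  dup <- matrix(rnorm(40 * 3), 40, 3)
  dup <- cbind(dup, dup[, 1])
  colnames(dup) <- c("a", "b", "c", "a_copy")
  expect_warning(perp <- perpendicular_norms(dup, dim_points = 40),
                 "dependent")
  expect_equal(unname(perp[c("a", "a_copy")]), c(0, 0))
})

test_that("QR-based error ratios equal direct pseudo-inverse row norms", {
  withr::local_seed(29)
  for (i in 1:10) {
    M <- matrix(rnorm(40 * 13), 40, 13,
                dimnames = list(NULL, nfkb_param_names))
    A <- solve(crossprod(M), t(M))  # direct (S'S)^-1 S'
    direct <- sqrt(rowSums(A^2))
    expect_equal(unname(error_ratios(M)), unname(direct), tolerance = 1e-8)
  }
  # orthonormal columns: pseudo-inverse is the transpose, all ratios 1
  Q <- qr.Q(qr(matrix(rnorm(40 * 13), 40, 13)))
  colnames(Q) <- nfkb_param_names
  expect_equal(unname(error_ratios(Q)), rep(1, 13), tolerance = 1e-10)
  # rank deficiency is a structural-identifiability error
  expect_error(error_ratios(dup <- cbind(Q[, 1:3], Q[, 3])), "rank deficient")
})

test_that("linear error propagation converts to geometric SDs consistently", {
  S <- sensitivity_matrix(fitted, onoff)
  rj <- error_ratios(S)
  expect_equal(sigma_linear(rj, 1.3), 1.3^rj)
  expect_equal(unname(sigma_linear(rj, 1)), rep(1, 13))
  rep_ <- linear_report(fitted, onoff, sigma_data = 1.3)
  expect_equal(rep_$sigma_linear, 1.3^rep_$R_j)
  expect_equal(rep_$R_j_scaled, rep_$R_j * sqrt(41))
  expect_true(all(rep_$scaled_perp_norms <= rep_$scaled_norms + 1e-12))
})

test_that("confidence ellipses collapse at sigma 1 and align with the covariance", {
  S <- sensitivity_matrix(fitted, onoff)
  e0 <- confidence_ellipse(S, 1, c("delta", "epsilon"))
  expect_equal(unname(e0$semi_axes), c(0, 0))
  e <- confidence_ellipse(S, 1.3, c("delta", "epsilon"), level = 0.75)
  ev <- eigen(e$cov, symmetric = TRUE)
  expect_equal(e$semi_axes^2 / qchisq(0.75, 2), ev$values, tolerance = 1e-10)
  dir <- c(cos(e$rotation), sin(e$rotation))
  expect_equal(abs(sum(dir * ev$vectors[, 1])), 1, tolerance = 1e-10)
})

test_that("Monte Carlo geometric SDs follow the defining formula", {
  # two estimates theta and theta*e^2 give sample SD of logs sqrt(2)
  est <- rbind(unclass(fitted), unclass(fitted) * exp(2))
  expect_equal(unname(sigma_carlo(est)), rep(exp(sqrt(2)), 13),
               tolerance = 1e-12)
  expect_equal(unname(sigma_carlo(rbind(unclass(fitted), unclass(fitted)))),
               rep(1, 13))
  expect_error(sigma_carlo(est[1, , drop = FALSE]), "at least 2")
})

test_that("unperturbed Monte Carlo refits return unit geometric SDs", {
  mc <- run_monte_carlo(fitted, onoff, sigma_levels = 1, k = 2,
                        base_seed = 12)
  expect_equal(unname(mc$sigma_carlo[1, ]), rep(1, 13), tolerance = 1e-6)
  expect_identical(mc$seeds[[1]], c(13L, 14L))
  expect_identical(mc$failures, 0L)
})
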