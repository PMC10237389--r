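#' Log-log sensitivity matrix of the normalized observables
#'
#' Builds the matrix `S` with one row per scheduled (normalized) measurement
#' and one column per parameter, with entries
#' `s_ij = d ln(y_i) / d ln(theta_j)` computed by central finite differences
#' in log space: each parameter is perturbed to `1.01 theta_j` and
#' `0.99 theta_j`, the observables re-simulated and re-normalized, and
#' `s_ij = [ln y_i(1.01 theta_j) - ln y_i(0.99 theta_j)] / ln(1.01/0.99)`.
#' Because each series is scaled by its geometric mean, the entries of any
#' column sum to ~0 within a series, and a series of `n` points carries
#' `n - 1` independent rows; all scaling therefore uses the independent
#' count `dim`, not the row count.
#'
#' @param params an [nfkb_params] vector (strictly positive).
#' @param protocols an `nfkb_protocol` or list of them.
#' @param genotypes genotypes included (those with schedules).
#' @param rel_step relative perturbation (default 0.01, i.e. 1 percent).
#' @param rho normalization shift fraction.
#' @param rtol,atol integrator tolerances.
#' @return a numeric matrix of class `nfkb_sensitivity` with `dim` (the
#'   independent-data-point count) and a per-row `info` data.frame attached
#'   as attributes.
#' @export
sensitivity_matrix <- function(params, protocols,
                               genotypes = c("WT", "A20KO"),
                               rel_step = 0.01, rho = 0.03,
                               rtol = 1e-8, atol = 1e-10) {
  params <- as_nfkb_params(params)
  if (any(params == 0))
    stop("sensitivity analysis requires strictly positive parameters")
  if (inherits(protocols, "nfkb_protocol")) protocols <- list(protocols)
  lny <- function(p) {
    raw <- do.call(rbind, lapply(protocols, simulate_measurements, params = p,
                                 genotypes = genotypes,
                                 rtol = rtol, atol = atol))
    ms <- normalize_measurements(.new_measurements(raw), rho = rho)
    list(values = log(ms$value),
         info = as.data.frame(ms)[c("protocol", "genotype", "observable",
                                    "time_min")])
  }
  base <- lny(params)
  n <- length(base$values)
  S <- matrix(NA_real_, n, 13, dimnames = list(NULL, nfkb_param_names))
  denom <- log((1 + rel_step) / (1 - rel_step))
  for (j in seq_len(13)) {
    up <- params; up[j] <- up[j] * (1 + rel_step)
    dn <- params; dn[j] <- dn[j] * (1 - rel_step)
    vu <- tryCatch(lny(as_nfkb_params(up))$values, error = function(e)
      stop("simulation failed while perturbing ", nfkb_param_names[j]))
    vd <- tryCatch(lny(as_nfkb_params(dn))$values, error = function(e)
      stop("simulation failed while perturbing ", nfkb_param_names[j]))
    S[, j] <- (vu - vd) / denom
  }
  structure(S, dim_points = count_independent_points(protocols),
            info = base$info, class = c("nfkb_sensitivity", "matrix", "array"))
}

# Accept either an nfkb_sensitivity matrix (with its attached dim) or a
# plain matrix plus an explicit dim_points.
.sens_dim <- function(S, dim_points = NULL) {
  if (is.null(dim_points)) dim_points <- attr(S, "dim_points")
  if (is.null(dim_points))
    stop("dim_points must be supplied for a plain matrix")
  dim_points
}

#' Scaled singular values of the sensitivity matrix
#'
#' Singular values of `S` divided by `sqrt(dim)`, the square root of the
#' independent-data-point count, so that repeating an experiment (doubling
#' `dim`) leaves them unchanged. All scaled singular values well above zero
#' indicate structural identifiability.
#'
#' @param S a sensitivity matrix from [sensitivity_matrix()].
#' @param dim_points independent-point count (taken from `S` if attached).
#' @return 13 descending non-negative values.
#' @export
scaled_singular_values <- function(S, dim_points = NULL) {
  svd(unclass(S))$d / sqrt(.sens_dim(S, dim_points))
}

#' Scaled norms of the per-parameter sensitivity vectors
#'
#' Euclidean column norms of `S` divided by `sqrt(dim)`. A small norm means
#' the data barely respond to the parameter.
#'
#' @inheritParams scaled_singular_values
#' @return named vector of 13 scaled norms.
#' @export
sensitivity_norms <- function(S, dim_points = NULL) {
  sqrt(colSums(unclass(S)^2) / .sens_dim(S, dim_points))
}

#' Scaled norms of the perpendicular sensitivity components
#'
#' For each parameter, the component of its sensitivity vector orthogonal to
#' the span of all other columns, `S_j - P_j S_j`, dim-scaled. A small
#' perpendicular component means changes of the parameter can be nearly
#' compensated by the others, i.e. poor identifiability.
#'
#' @inheritParams scaled_singular_values
#' @return named vector of 13 scaled perpendicular norms; columns linearly
#'   dependent on the rest are reported as 0 with a warning.
#' @export
perpendicular_norms <- function(S, dim_points = NULL) {
  d <- .sens_dim(S, dim_points)
  S <- unclass(S)
  p <- ncol(S)
  out <- numeric(p)
  for (j in seq_len(p)) {
    Sm <- S[, -j, drop = FALSE]
    qrm <- qr(Sm)
    proj <- qr.fitted(qrm, S[, j])
    r2 <- sum((S[, j] - proj)^2)
    out[j] <- sqrt(max(r2, 0) / d)
  }
  rel <- out * sqrt(d) / pmax(sqrt(colSums(S^2)), .Machine$double.eps)
  if (any(rel < 1e-10)) {
    warning("linearly dependent sensitivity column(s): ",
            paste(colnames(S)[rel < 1e-10], collapse = ", "),
            "; perpendicular norm reported as 0")
    out[rel < 1e-10] <- 0
  }
  setNames(out, colnames(S))
}

#' Parameter-error to data-error ratios
#'
#' For lognormal measurement errors with common geometric SD `sigma_data`,
#' the induced estimation error of parameter `j` is lognormal with geometric
#' SD `sigma_linear_j = sigma_data^R_j`, where `R_j` is the l2-norm of the
#' j-th row of the pseudo-inverse `(S'S)^-1 S'`. The computation uses the
#' numerically stable QR route: the row norms of `R_a^-1`, `R_a` being the
#' leading p x p block of the QR factor of `S`.
#'
#' @inheritParams scaled_singular_values
#' @return named vector of 13 error ratios `R_j` (unscaled; multiply by
#'   `sqrt(dim)` for cross-protocol comparison).
#' @export
error_ratios <- function(S, dim_points = NULL) {
  S <- unclass(S)
  p <- ncol(S)
  qrS <- qr(S)
  if (qrS$rank < p)
    stop("sensitivity matrix is rank deficient: structurally non-identifiable")
  Ra <- qr.R(qrS)[seq_len(p), seq_len(p)]
  Ri <- backsolve(Ra, diag(p))
  rj <- sqrt(rowSums(Ri^2))
  out <- numeric(p)
  out[qrS$pivot] <- rj
  setNames(out, colnames(S))
}

#' Predicted geometric SD of parameter estimates (linear analysis)
#'
#' @param R_j error ratios from [error_ratios()].
#' @param sigma_data geometric SD of the measurement error (>= 1).
#' @return `sigma_data^R_j` per parameter.
#' @export
sigma_linear <- function(R_j, sigma_data) {
  stopifnot(sigma_data >= 1)
  sigma_data^R_j
}

#' Full linear identifiability report
#'
#' @param params an [nfkb_params] vector.
#' @param protocols an `nfkb_protocol` or list of them.
#' @param sigma_data geometric SD used for the `sigma_linear` column.
#' @param ... passed to [sensitivity_matrix()].
#' @return a list of class `nfkb_linear_report`: `scaled_singular_values`,
#'   `scaled_norms`, `scaled_perp_norms`, `R_j`, `R_j_scaled` (x sqrt(dim)),
#'   `sigma_linear`, `dim`, `n_rows`.
#' @export
linear_report <- function(params, protocols, sigma_data = 1.3, ...) {
  S <- sensitivity_matrix(params, protocols, ...)
  d <- attr(S, "dim_points")
  rj <- error_ratios(S)
  structure(list(
    scaled_singular_values = scaled_singular_values(S),
    scaled_norms = sensitivity_norms(S),
    scaled_perp_norms = perpendicular_norms(S),
    R_j = rj,
    R_j_scaled = rj * sqrt(d),
    sigma_linear = sigma_linear(rj, sigma_data),
    sigma_data = sigma_data,
    dim = d, n_rows = nrow(S)), class = "nfkb_linear_report")
}

#' @export
print.nfkb_linear_report <- function(x, ...) {
  cat(sprintf("Linear identifiability report (%d rows, dim = %d)\n",
              x$n_rows, x$dim))
  cat("scaled singular values:\n")
  print(signif(x$scaled_singular_values, 3))
  tab <- data.frame(norm = x$scaled_norms, perp = x$scaled_perp_norms,
                    R_j = x$R_j, sigma_linear = x$sigma_linear)
  print(signif(tab, 3))
  invisible(x)
}

#' Confidence ellipse for a parameter pair (linear analysis)
#'
#' 2-D marginal of the log-parameter covariance
#' `ln(sigma_data)^2 (S'S)^-1`, scaled by the chi-squared quantile with two
#' degrees of freedom at the requested confidence level.
#'
#' @param S a sensitivity matrix.
#' @param sigma_data geometric SD of measurement error (>= 1).
#' @param pair two parameter names or indices.
#' @param level confidence level (default 0.75).
#' @param center ellipse center in the log-parameter plane (default the
#'   origin, i.e. deviations from the nominal values).
#' @return list with `center`, `semi_axes` (lengths, descending), `rotation`
#'   (radians, first axis vs first parameter), `cov` (the 2x2 marginal).
#' @export
confidence_ellipse <- function(S, sigma_data, pair, level = 0.75,
                               center = c(0, 0)) {
  S <- unclass(S)
  if (is.character(pair)) pair <- match(pair, colnames(S))
  stopifnot(length(pair) == 2, !anyNA(pair))
  C <- log(sigma_data)^2 * solve(crossprod(S))
  C2 <- C[pair, pair]
  e <- eigen(C2, symmetric = TRUE)
  r2 <- qchisq(level, df = 2)
  list(center = center,
       semi_axes = sqrt(pmax(e$values, 0) * r2),
       rotation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       cov = C2)
}

#' Geometric SD of Monte Carlo parameter estimates
#'
#' `sigma_carlo_j = exp(SD(ln theta_jk))` over the `k` refitted estimates
#' (sample SD, n - 1 denominator).
#'
#' @param estimates k x p matrix of fitted parameter vectors.
#' @return named vector of per-parameter geometric SDs (>= 1).
#' @export
sigma_carlo <- function(estimates) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) < 2) stop("need at least 2 estimates")
  exp(apply(log(estimates), 2, sd))
}

#' Monte Carlo practical identifiability analysis
#'
#' For each measurement-noise level, draws `k` perturbed measurement sets
#' from the model's own unperturbed measurements (multiplicative lognormal
#' noise of geometric SD `sigma_data`), refits the 13 parameters to each,
#' and summarizes the scatter as per-parameter geometric SDs
#' [sigma_carlo()]. Replicate `r` at level `l` uses the recorded seed
#' `base_seed + 1000 (l - 1) + r`.
#'
#' @param params generating ("true") parameter set.
#' @param protocol an `nfkb_protocol` (measurement schedules required).
#' @param sigma_levels vector of geometric SDs (1 = unperturbed).
#' @param k replicates per level.
#' @param base_seed integer seed base.
#' @param genotypes genotypes included.
#' @param control an [fit_control()]; the default is a reduced-budget local
#'   refit (Levenberg-Marquardt from the nominal start, no global stage)
#'   suitable for many replicates.
#' @param rho normalization shift fraction.
#' @return a list of class `nfkb_mc`: `sigma_carlo` (levels x 13 matrix),
#'   `estimates` (list of k x 13 matrices per level), `sigma_levels`,
#'   `seeds`, `failures` (per-level count of non-converged refits, which
#'   are flagged but retained).
#' @export
run_monte_carlo <- function(params, protocol,
                            sigma_levels = c(1, 1.1, 1.2, 1.3), k = 50,
                            base_seed = 1, genotypes = c("WT", "A20KO"),
                            control = fit_control(de = FALSE, polish = TRUE,
                                                  lm_maxiter = 40),
                            rho = 0.03) {
  params <- as_nfkb_params(params)
  if (k < 2) stop("k must be >= 2")
  truth_raw <- simulate_measurements(params, protocol, genotypes = genotypes)
  estimates <- list()
  seeds <- list()
  failures <- integer(length(sigma_levels))
  sc <- matrix(NA_real_, length(sigma_levels), 13,
               dimnames = list(paste0("sigma_", sigma_levels),
                               nfkb_param_names))
  for (l in seq_along(sigma_levels)) {
    sig <- sigma_levels[l]
    est <- matrix(NA_real_, k, 13, dimnames = list(NULL, nfkb_param_names))
    sds <- integer(k)
    for (r in seq_len(k)) {
      sds[r] <- as.integer(base_seed + 1000L * (l - 1L) + r)
      noisy <- add_lognormal_noise(truth_raw, sig, seed = sds[r])
      ref <- normalize_measurements(noisy, rho = rho)
      ft <- fit_nfkb(ref, protocol, start = params, bounds_fold = 100,
                     genotypes = genotypes, control = control,
                     seed = sds[r], rho = rho)
      est[r, ] <- unclass(ft$params)
      if (!ft$converged) failures[l] <- failures[l] + 1L
    }
    estimates[[l]] <- est
    seeds[[l]] <- sds
    sc[l, ] <- sigma_carlo(est)
  }
  structure(list(sigma_carlo = sc, estimates = estimates,
                 sigma_levels = sigma_levels, seeds = seeds,
                 failures = failures, k = k, base_seed = base_seed),
            class = "nfkb_mc")
}

#' @export
print.nfkb_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo identifiability (k = %d per level)\n", x$k))
  print(signif(x$sigma_carlo, 3))
  if (any(x$failures > 0))
    cat("non-converged refits per level:",
        paste(x$failures, collapse = ", "), "\n")
  invisible(x)
}
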