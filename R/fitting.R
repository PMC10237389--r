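# Align two measurement sets on (protocol, genotype, observable, time)
# and return the matched value pairs; errors list the missing triples.
.align_sets <- function(model_set, reference_set) {
  key <- function(d) paste(d$protocol, d$genotype, d$observable,
                           signif(d$time_min, 10), sep = "|")
  km <- key(model_set); kr <- key(reference_set)
  missing <- setdiff(kr, km)
  extra <- setdiff(km, kr)
  if (length(missing) || length(extra))
    stop("schedule mismatch between sets; missing in model set: ",
         paste(utils::head(missing, 5), collapse = "; "),
         if (length(extra)) paste0("; unmatched in model set: ",
                                   paste(utils::head(extra, 5), collapse = "; ")))
  idx <- match(kr, km)
  list(model = model_set$value[idx], reference = reference_set$value)
}

#' Log-least-squares objective between two normalized measurement sets
#'
#' `J = sum_i (ln y_i_model - ln y_i_ref)^2` over all matched measurements.
#' Both sets must be normalized (geometric mean 1 per series), so J is
#' invariant to rescaling any raw series by a constant.
#'
#' @param model_set,reference_set normalized `nfkb_measurements` sets over
#'   identical schedules.
#' @return the objective value (dimensionless).
#' @export
objective_J <- function(model_set, reference_set) {
  if (!isTRUE(attr(model_set, "normalized")) ||
      !isTRUE(attr(reference_set, "normalized")))
    stop("both measurement sets must be normalized")
  v <- .align_sets(model_set, reference_set)
  sum((log(v$model) - log(v$reference))^2)
}

#' Average Multiplicative Distance between two measurement sets
#'
#' `AMD = exp(sqrt(J / N))`: the geometric-mean fold-discrepancy between two
#' normalized measurement sets. 1 means identical; 2 means an average
#' two-fold discrepancy.
#'
#' @inheritParams objective_J
#' @return a geometric distance `>= 1`.
#' @export
amd <- function(model_set, reference_set) {
  J <- objective_J(model_set, reference_set)
  exp(sqrt(J / nrow(reference_set)))
}

#' Optimizer settings for model fitting
#'
#' The global stage is a differential-evolution search (rand/1/bin) over
#' log-transformed parameters, initialized log-uniformly within the bounds;
#' the local stage polishes with Levenberg-Marquardt on the log residuals.
#'
#' @param pop_size DE population size (default 15 per parameter).
#' @param max_generations cap on DE generations.
#' @param max_evals cap on objective evaluations across both stages.
#' @param reltol relative objective improvement defining a stall.
#' @param stall_generations DE stops after this many stalled generations.
#' @param F,CR DE mutation weight and crossover probability.
#' @param de,polish enable the global / local stage.
#' @param lm_maxiter Levenberg-Marquardt iteration cap.
#' @return a list of class `nfkb_fit_control`.
#' @export
fit_control <- function(pop_size = 15 * 13, max_generations = 1000,
                        max_evals = 2e5, reltol = 1e-6,
                        stall_generations = 50, F = 0.8, CR = 0.9,
                        de = TRUE, polish = TRUE, lm_maxiter = 50) {
  structure(list(pop_size = pop_size, max_generations = max_generations,
                 max_evals = max_evals, reltol = reltol,
                 stall_generations = stall_generations, F = F, CR = CR,
                 de = de, polish = polish, lm_maxiter = lm_maxiter),
            class = "nfkb_fit_control")
}

# Internal: objective/residual closures for a reference set.
.make_objective <- function(reference_set, protocols, genotypes, rho,
                            compiled = TRUE) {
  if (!isTRUE(attr(reference_set, "normalized")))
    stop("reference set must be normalized")
  if (inherits(protocols, "nfkb_protocol")) protocols <- list(protocols)
  ln_ref <- log(reference_set$value)
  counter <- new.env()
  counter$evals <- 0L
  resid <- function(log_theta) {
    counter$evals <- counter$evals + 1L
    p <- tryCatch(as_nfkb_params(setNames(exp(log_theta), nfkb_param_names)),
                  error = function(e) NULL)
    if (is.null(p)) return(rep(1e3, length(ln_ref)))
    # extreme trial parameters can defeat the integrator; such points are
    # simply assigned a large residual
    ms <- tryCatch(suppressWarnings({
      raw <- do.call(rbind, lapply(protocols, simulate_measurements,
                                   params = p, genotypes = genotypes,
                                   compiled = compiled))
      normalize_measurements(.new_measurements(raw), rho = rho)
    }), error = function(e) NULL)
    if (is.null(ms)) return(rep(1e3, length(ln_ref)))
    v <- .align_sets(ms, reference_set)
    log(v$model) - ln_ref
  }
  J <- function(log_theta) sum(resid(log_theta)^2)
  list(resid = resid, J = J, counter = counter)
}

# Internal: differential evolution (rand/1/bin) with box bounds.
.de_optim <- function(J, lower, upper, control, counter) {
  d <- length(lower)
  np <- max(control$pop_size, 4L)
  pop <- matrix(runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                nrow = np)
  cost <- apply(pop, 1, J)
  best_hist <- min(cost)
  stall <- 0L
  gens <- 0L
  while (gens < control$max_generations &&
         counter$evals < control$max_evals &&
         stall < control$stall_generations) {
    gens <- gens + 1L
    for (i in seq_len(np)) {
      r <- sample(setdiff(seq_len(np), i), 3L)
      mutant <- pop[r[1], ] + control$F * (pop[r[2], ] - pop[r[3], ])
      jrand <- sample.int(d, 1L)
      cross <- runif(d) < control$CR
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      ct <- J(trial)
      if (ct <= cost[i]) { pop[i, ] <- trial; cost[i] <- ct }
      if (counter$evals >= control$max_evals) break
    }
    newbest <- min(cost)
    if (best_hist - newbest < control$reltol * max(best_hist, 1e-12))
      stall <- stall + 1L
    else stall <- 0L
    best_hist <- newbest
  }
  i <- which.min(cost)
  list(par = pop[i, ], value = cost[i],
       converged = stall >= control$stall_generations)
}

#' Fit the reduced model to a reference measurement set
#'
#' Minimizes the log-least-squares objective [objective_J()] over the 13
#' log-transformed rate constants: an optional differential-evolution global
#' search within multiplicative bounds around `start`, followed by a
#' Levenberg-Marquardt polish of the log residuals. Reproducible under a
#' fixed seed.
#'
#' @param reference_set a normalized `nfkb_measurements` reference.
#' @param protocols an `nfkb_protocol` or list of them covering the
#'   reference schedules.
#' @param start center of the search region, an [nfkb_params] vector.
#' @param bounds_fold multiplicative half-width of the box bounds (each
#'   parameter searched in `start/bounds_fold .. start*bounds_fold`), or a
#'   2 x 13 matrix of explicit lower/upper bounds.
#' @param genotypes genotypes present in the reference.
#' @param control an [fit_control()] list.
#' @param seed integer seed for the stochastic search.
#' @param rho normalization shift fraction.
#' @return a list of class `nfkb_fit`: `params` (the estimate), `J`, `AMD`,
#'   `converged`, `n_evaluations`, `seed`.
#' @export
fit_nfkb <- function(reference_set, protocols, start = nfkb_params("fitted"),
                     bounds_fold = 100, genotypes = c("WT", "A20KO"),
                     control = fit_control(), seed = NULL, rho = 0.03) {
  start <- as_nfkb_params(start)
  if (any(start == 0))
    stop("start parameters must be strictly positive (log search space)")
  if (is.matrix(bounds_fold)) {
    stopifnot(nrow(bounds_fold) == 2, ncol(bounds_fold) == 13)
    lower <- log(bounds_fold[1, ]); upper <- log(bounds_fold[2, ])
  } else {
    lower <- log(unclass(start) / bounds_fold)
    upper <- log(unclass(start) * bounds_fold)
  }
  obj <- .make_objective(reference_set, protocols, genotypes, rho)
  x0 <- pmin(pmax(log(unclass(start)), lower), upper)
  res <- with_seed(seed, {
    best <- list(par = x0, value = obj$J(x0), converged = FALSE)
    if (control$de && any(upper > lower)) {
      de <- .de_optim(obj$J, lower, upper, control, obj$counter)
      if (de$value <= best$value) best <- de
    }
    if (control$polish && any(upper > lower)) {
      # an exhausted iteration budget is an expected outcome, reported via
      # the converged flag rather than a warning
      lm <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(par = best$par, lower = lower, upper = upper,
                             fn = obj$resid,
                             control = minpack.lm::nls.lm.control(
                               maxiter = control$lm_maxiter))),
        error = function(e) NULL)
      if (!is.null(lm)) {
        val <- sum(lm$fvec^2)
        if (val <= best$value)
          best <- list(par = lm$par, value = val,
                       converged = lm$info %in% 1:3)
      }
    }
    best
  })
  params_hat <- as_nfkb_params(setNames(exp(res$par), nfkb_param_names))
  structure(list(params = params_hat, J = res$value,
                 AMD = exp(sqrt(res$value / nrow(reference_set))),
                 converged = res$converged,
                 n_evaluations = obj$counter$evals, seed = seed),
            class = "nfkb_fit")
}

#' @export
print.nfkb_fit <- function(x, ...) {
  cat(sprintf("NF-kB model fit: J = %.6g, AMD = %.4f, %s (%d evaluations)\n",
              x$J, x$AMD,
              if (x$converged) "converged" else "budget-limited",
              x$n_evaluations))
  print(x$params)
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit an `nfkb_fit` object.
#' @param path output JSON path.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(
    list(params = as.list(unclass(fit$params)), J = fit$J, AMD = fit$AMD,
         converged = fit$converged, n_evaluations = fit$n_evaluations,
         seed = fit$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
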