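test_that("the log-least-squares objective and AMD satisfy their identities", {
  ref <- manual_measurements(c(0.5, 1, 2))
  expect_equal(objective_J(ref, ref), 0)
  expect_equal(amd(ref, ref), 1)
  # one measurement off by a factor e contributes (ln e)^2 = 1
  off <- ref; off$value[1] <- off$value[1] * exp(1)
  expect_equal(objective_J(off, ref), 1)
  # a uniform 2-fold offset gives AMD exactly 2
  twice <- ref; twice$value <- twice$value * 2
  expect_equal(amd(twice, ref), 2, tolerance = 1e-12)
  expect_equal(amd(twice, ref),
               exp(sqrt(objective_J(twice, ref) / nrow(ref))))
  # AMD >= 1 for random discrepancies
  withr::local_seed(31)
  for (i in 1:10) {
    perturbed <- ref
    perturbed$value <- perturbed$value * exp(rnorm(3, 0, 0.5))
    expect_gte(amd(perturbed, ref), 1)
  }
})

test_that("objective errors name schedule mismatches and unnormalized input", {
  ref <- manual_measurements(c(0.5, 1, 2))
  short <- ref[-2, ]
  class(short) <- class(ref); attr(short, "normalized") <- TRUE
  expect_error(objective_J(short, ref), "missing in model set")
  raw <- manual_measurements(c(0.5, 1, 2), normalized = FALSE)
  expect_error(objective_J(raw, ref), "normalized")
})

test_that("rescaling a raw reference series leaves the fitted objective unchanged", {
  raw <- simulate_measurements(fitted, onoff)
  model <- normalize_measurements(
    simulate_measurements(params_limit_cycle, onoff))
  J1 <- objective_J(model, normalize_measurements(raw))
  scaled <- raw
  scale_by <- ifelse(scaled$observable == "NFkBn", 37, 1) *
    ifelse(scaled$genotype == "A20KO", 0.01, 1)
  scaled$value <- scaled$value * scale_by
  attr(scaled, "normalized") <- FALSE
  J2 <- objective_J(model, normalize_measurements(scaled))
  expect_equal(J1, J2, tolerance = 1e-10)
})

test_that("a local polish recovers the generating parameters from clean data", {
  ref <- normalize_measurements(simulate_measurements(fitted, onoff))
  start <- as_nfkb_params(setNames(unclass(fitted) *
                                     exp(c(0.2, -0.2, 0.1, -0.1, 0.2, -0.2,
                                           0.1, -0.1, 0.2, -0.2, 0.1, -0.1,
                                           0.2)),
                                   nfkb_param_names))
  ft <- fit_nfkb(ref, onoff, start = start,
                 control = fit_control(de = FALSE, polish = TRUE), seed = 3)
  expect_s3_class(ft, "nfkb_fit")
  expect_lt(ft$J, 1e-8)
  expect_lt(max(abs(log(unclass(ft$params) / unclass(fitted)))), 0.02)
  # minimizer contract: no worse than the start
  obj_start <- objective_J(normalize_measurements(
    simulate_measurements(start, onoff)), ref)
  expect_lte(ft$J, obj_start)
})

test_that("collapsed bounds return the objective at the pinned parameters", {
  ref <- normalize_measurements(simulate_measurements(fitted, onoff))
  bounds <- rbind(unclass(fitted), unclass(fitted))
  ft <- fit_nfkb(ref, onoff, start = fitted, bounds_fold = bounds)
  expect_equal(unclass(ft$params), unclass(fitted), tolerance = 1e-12)
  expect_equal(ft$J, objective_J(
    normalize_measurements(simulate_measurements(fitted, onoff)), ref))
  expect_identical(ft$n_evaluations, 1L)
})

test_that("the stochastic search is reproducible under a fixed seed", {
  noisy <- add_lognormal_noise(simulate_measurements(fitted, onoff), 1.2,
                               seed = 77)
  ref <- normalize_measurements(noisy)
  # start far from the optimum so the stochastic stage determines the result
  far <- as_nfkb_params(setNames(unclass(fitted) * 5, nfkb_param_names))
  ctl <- fit_control(pop_size = 10, max_generations = 3, polish = FALSE)
  f1 <- fit_nfkb(ref, onoff, start = far, bounds_fold = 10,
                 control = ctl, seed = 5)
  f2 <- fit_nfkb(ref, onoff, start = far, bounds_fold = 10,
                 control = ctl, seed = 5)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$J, f2$J)
  f3 <- fit_nfkb(ref, onoff, start = far, bounds_fold = 10,
                 control = ctl, seed = 6)
  expect_false(identical(unclass(f1$params), unclass(f3$params)))
  expect_lt(f1$J, objective_J(normalize_measurements(
    simulate_measurements(far, onoff)), ref))
})
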