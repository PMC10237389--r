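test_that("right-hand side matches hand evaluations at the resting state", {
  rest <- c(1, 0, 0, 0, 0, 0)
  for (preset in c("fitted", "prefitted"))
    expect_equal(unname(nfkb_rhs(rest, nfkb_params(preset), tnf = 0)),
                 rep(0, 6))
  # TNF on: only the IKK activation term is nonzero at rest
  d <- nfkb_rhs(rest, fitted, tnf = 1)
  expect_equal(unname(d), c(-0.00195, 0.00195, 0, 0, 0, 0), tolerance = 1e-12)
})

test_that("rhs rejects invalid states and stimuli", {
  expect_error(nfkb_rhs(c(-0.1, 0, 0, 0, 0, 0), fitted, tnf = 0),
               "non-negative")
  expect_error(nfkb_rhs(c(1, 0, 0, 0, 0, 0), fitted, tnf = 0.5),
               "tnf must be 0 or 1")
})

test_that("without active IKK the nuclear NF-kB level cannot rise", {
  withr::local_seed(11)
  for (i in 1:20) {
    s <- runif(6); s[2] <- 0  # IKKa = 0
    d <- nfkb_rhs(s, random_params(), tnf = sample(0:1, 1))
    expect_lte(d[["NFkBn"]], 0)
  }
})

test_that("the released IkBa-degradation flux splits exactly between nucleus and cytoplasm", {
  # The Michaelis-type factors delta/(IkBa+delta) and IkBa/(IkBa+delta)
  # partition the complex-degradation flux a3*IKKa*(1-NFkBn); reconstructing
  # both shares from the rhs must recover the full flux at any state.
  withr::local_seed(7)
  for (i in 1:20) {
    s <- setNames(runif(6), nfkb_state_names)
    p <- random_params()
    d <- nfkb_rhs(s, p, tnf = 1)
    import <- p[["i1a"]] * s[["IkBa"]] * s[["NFkBn"]] /
      (s[["NFkBn"]] + p[["epsilon"]])
    to_nucleus <- d[["NFkBn"]] + import
    linear_part <- p[["c4a"]] * s[["IkBat"]] - p[["c5a"]] * s[["IkBa"]] -
      p[["a2"]] * s[["IKKa"]] * s[["IkBa"]]
    consumed <- linear_part - import - d[["IkBa"]]
    release <- p[["a3"]] * s[["IKKa"]] * (1 - s[["NFkBn"]])
    expect_equal(to_nucleus + consumed, release, tolerance = 1e-12)
  }
})

test_that("compiled and R integrators produce the same trajectory", {
  trc <- simulate_nfkb(fitted, onoff, "WT", dt_min = 10, compiled = TRUE)
  trr <- simulate_nfkb(fitted, onoff, "WT", dt_min = 10, compiled = FALSE)
  expect_equal(trc, trr, tolerance = 1e-8)
})

test_that("trajectories stay non-negative with NFkBn and IKKn bounded by 1", {
  withr::local_seed(23)
  for (i in 1:5) {
    p <- random_params(fold = 3)
    for (g in c("WT", "A20KO")) {
      tr <- simulate_nfkb(p, onoff, g, dt_min = 5)
      expect_true(all(as.matrix(tr[nfkb_state_names]) >= -1e-9))
      expect_true(all(tr$NFkBn <= 1 + 1e-9))
      expect_true(all(tr$IKKn <= 1 + 1e-9))
    }
  }
})

test_that("halving integrator tolerances leaves trajectories unchanged to 1e-6", {
  tr1 <- simulate_nfkb(fitted, onoff, "WT", dt_min = 5)
  tr2 <- simulate_nfkb(fitted, onoff, "WT", dt_min = 5,
                       rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(as.matrix(tr1[nfkb_state_names]) -
                    as.matrix(tr2[nfkb_state_names]))), 1e-6)
})

test_that("zeroing A20-driven IKK inactivation is equivalent to zeroed A20 synthesis", {
  # With k2 = 0 the IKKa equation decouples from A20, so all variables
  # except A20 itself must match the knockout realization.
  tr_k2 <- simulate_nfkb(nfkb_params("fitted", k2 = 0), onoff, "WT",
                         dt_min = 10)
  tr_ko <- simulate_nfkb(fitted, onoff, "A20KO", dt_min = 10)
  keep <- setdiff(nfkb_state_names, "A20")
  expect_lt(max(abs(as.matrix(tr_k2[keep]) - as.matrix(tr_ko[keep]))), 1e-8)
  expect_true(all(tr_ko$A20 == 0))
})

test_that("the TNF-off system relaxes to the resting steady state", {
  expect_equal(unname(resting_state(fitted)), c(1, 0, 0, 0, 0, 0))
  prot <- nfkb_protocol("off", data.frame(start = 0, end = 6000, tnf = 0))
  tr <- simulate_nfkb(fitted, prot, "WT", times_min = c(0, 6000),
                      init = c(0.5, 0.1, 0.2, 0.1, 0.1, 0.1))
  expect_equal(unname(unlist(tr[nrow(tr), nfkb_state_names])),
               c(1, 0, 0, 0, 0, 0), tolerance = 1e-4)
})

test_that("constant TNF-off simulation from rest stays at the fixed point", {
  prot <- nfkb_protocol("off", data.frame(start = 0, end = 720, tnf = 0))
  tr <- simulate_nfkb(fitted, prot, "WT", dt_min = 60)
  expect_equal(max(abs(sweep(as.matrix(tr[nfkb_state_names]), 2,
                             c(1, 0, 0, 0, 0, 0)))), 0, tolerance = 1e-9)
})

test_that("TNF-on fixed points reproduce the stable, unstable and adapted regimes", {
  fp <- stimulated_fixed_point(fitted)
  expect_true(fp$converged)
  expect_lt(fp$residual_norm, 1e-12)
  expect_true(fp$stable)
  expect_true(all(fp$state > 0))

  fp_lc <- stimulated_fixed_point(params_limit_cycle)
  expect_true(fp_lc$converged)
  expect_false(fp_lc$stable)

  fp_ad <- stimulated_fixed_point(params_adaptation)
  expect_true(fp_ad$converged)
  expect_lt(fp_ad$state[["NFkBn"]], 0.05)
})
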