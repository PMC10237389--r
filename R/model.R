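#' State variable names of the reduced model
#'
#' Six non-dimensional fractions: neutral and active IKK (`IKKn`, `IKKa`),
#' free nuclear NF-kB (`NFkBn`), A20 protein, free cytoplasmic IkBa protein
#' (`IkBa`) and IkBa transcript (`IkBat`). Total NF-kB is conserved, so the
#' cytoplasmic (NF-kB|IkBa) complex level is `1 - NFkBn`, and total IkBa
#' protein is `IkBa + 1 - NFkBn`.
#'
#' @export
nfkb_state_names <- c("IKKn", "IKKa", "NFkBn", "A20", "IkBa", "IkBat")

#' Right-hand side of the reduced 6-ODE NF-kB model
#'
#' Time derivatives (per second) of the six state variables under a constant
#' TNF indicator. The model couples two negative feedbacks: IkBa sequesters
#' nuclear NF-kB (with a transcription/translation delay through `IkBat`),
#' and NF-kB-induced A20 inactivates active IKK.
#'
#' @param state named (or canonically ordered) numeric vector of the six
#'   state variables; all components must be non-negative.
#' @param params an [nfkb_params] vector.
#' @param tnf TNF indicator, 0 (off) or 1 (on).
#' @param a20ko logical; `TRUE` zeroes the A20 synthesis term (A20 knockout).
#' @return named numeric vector of the six derivatives.
#' @examples
#' nfkb_rhs(c(1, 0, 0, 0, 0, 0), nfkb_params("fitted"), tnf = 0)
#' @export
nfkb_rhs <- function(state, params, tnf, a20ko = FALSE) {
  params <- as_nfkb_params(params)
  state <- unlist(state)
  if (length(state) != 6L)
    stop("state must have 6 components")
  if (is.null(names(state))) names(state) <- nfkb_state_names
  state <- state[nfkb_state_names]
  if (any(!is.finite(state)) || any(state < 0))
    stop("state components must be finite and non-negative")
  if (!(identical(as.numeric(tnf), 0) || identical(as.numeric(tnf), 1)))
    stop("tnf must be 0 or 1")
  p <- as.list(unclass(params))
  IKKn <- state[["IKKn"]]; IKKa <- state[["IKKa"]]; NFkBn <- state[["NFkBn"]]
  A20 <- state[["A20"]]; IkBa <- state[["IkBa"]]; IkBat <- state[["IkBat"]]
  release <- p$a3 * IKKa * (1 - NFkBn)
  import <- p$i1a * IkBa * NFkBn / (NFkBn + p$epsilon)
  c(IKKn  = p$k_deg - p$k_deg * IKKn - tnf * p$k1 * IKKn,
    IKKa  = tnf * p$k1 * IKKn - (p$k3 + p$k_deg + tnf * p$k2 * A20) * IKKa,
    NFkBn = release * p$delta / (IkBa + p$delta) - import,
    A20   = (1 - a20ko) * p$c_deg * NFkBn - p$c_deg * A20,
    IkBa  = p$c4a * IkBat - p$c5a * IkBa - p$a2 * IKKa * IkBa -
            release * IkBa / (IkBa + p$delta) - import,
    IkBat = p$c3a * NFkBn - p$c3a * IkBat)
}

# R-function RHS in deSolve's calling convention (reference implementation;
# the compiled C version in src/ is the default integration path).
.rhs_desolve <- function(t, y, parms) {
  p <- parms
  release <- p[["a3"]] * y[2L] * (1 - y[3L])
  import <- p[["i1a"]] * y[5L] * y[3L] / (y[3L] + p[["epsilon"]])
  list(c(
    p[["k_deg"]] - p[["k_deg"]] * y[1L] - p[["TR"]] * p[["k1"]] * y[1L],
    p[["TR"]] * p[["k1"]] * y[1L] -
      (p[["k3"]] + p[["k_deg"]] + p[["TR"]] * p[["k2"]] * y[4L]) * y[2L],
    release * p[["delta"]] / (y[5L] + p[["delta"]]) - import,
    (1 - p[["A20KO"]]) * p[["c_deg"]] * y[3L] - p[["c_deg"]] * y[4L],
    p[["c4a"]] * y[6L] - p[["c5a"]] * y[5L] - p[["a2"]] * y[2L] * y[5L] -
      release * y[5L] / (y[5L] + p[["delta"]]) - import,
    p[["c3a"]] * y[3L] - p[["c3a"]] * y[6L]))
}

#' Resting steady state (TNF off)
#'
#' With TNF off the model relaxes to the state in which all IKK is in its
#' neutral form and the downstream variables are zero. This is an exact
#' fixed point of the right-hand side.
#'
#' @param params an [nfkb_params] vector.
#' @return named state vector `(1, 0, 0, 0, 0, 0)`.
#' @export
resting_state <- function(params) {
  params <- as_nfkb_params(params)
  s <- setNames(c(1, 0, 0, 0, 0, 0), nfkb_state_names)
  stopifnot(max(abs(nfkb_rhs(s, params, tnf = 0))) == 0)
  s
}

# Integrate one piecewise-constant-TNF problem. segments: data.frame with
# start, end (minutes), tnf in {0,1}. times_min: requested output times.
# Integration restarts at every TNF switch so the discontinuity never sits
# inside an adaptive step.
.integrate_piecewise <- function(params, segments, times_min, a20ko = FALSE,
                                 init = NULL, rtol = 1e-8, atol = 1e-10,
                                 compiled = TRUE) {
  params <- as_nfkb_params(params)
  if (is.null(init)) init <- resting_state(params)
  init <- unlist(init)
  if (length(init) != 6L) stop("init must have 6 components")
  if (!is.null(names(init))) init <- init[nfkb_state_names]
  y <- setNames(as.numeric(init), nfkb_state_names)
  times_min <- sort(unique(times_min))
  if (min(times_min) < min(segments$start) - 1e-9 ||
      max(times_min) > max(segments$end) + 1e-9)
    stop("requested times fall outside the protocol span")
  out <- NULL
  for (i in seq_len(nrow(segments))) {
    s0 <- segments$start[i]; s1 <- segments$end[i]
    tt <- times_min[times_min >= s0 - 1e-9 & times_min <= s1 + 1e-9]
    tt <- sort(unique(c(s0, tt, s1))) * 60  # seconds
    parms <- c(unclass(params), TR = segments$tnf[i], A20KO = as.numeric(a20ko))
    sol <- if (compiled) {
      deSolve::ode(y = y, times = tt, func = "nfkb_derivs", parms = parms,
                   dllname = "nfkbid", initfunc = "nfkb_initmod",
                   rtol = rtol, atol = atol)
    } else {
      deSolve::ode(y = y, times = tt, func = .rhs_desolve, parms = parms,
                   rtol = rtol, atol = atol)
    }
    if (attr(sol, "istate")[1L] < 0)
      stop(sprintf("integration failed in segment %d (%g-%g min)", i, s0, s1))
    y <- sol[nrow(sol), -1L]
    block <- sol[, , drop = FALSE]
    if (!is.null(out)) block <- block[-1L, , drop = FALSE]
    out <- rbind(out, block)
  }
  df <- as.data.frame(out)
  names(df) <- c("time_min", nfkb_state_names)
  df$time_min <- df$time_min / 60
  # keep only requested times (segment boundaries were added for restarts)
  df <- df[vapply(df$time_min,
                  function(t) any(abs(t - times_min) < 1e-7), logical(1)), ]
  df <- df[!duplicated(round(df$time_min, 7)), ]
  rownames(df) <- NULL
  df
}

#' Simulate the reduced model under a stimulation protocol
#'
#' Integrates the model (stiffness-switching `lsoda`, compiled right-hand
#' side) over a protocol's TNF segments, restarting the integrator at every
#' TNF switch. The default initial condition is the resting steady state.
#'
#' @param params an [nfkb_params] vector.
#' @param protocol an [nfkb_protocol] object (see [make_on_off()] etc.).
#' @param genotype `"WT"` or `"A20KO"`; the knockout zeroes A20 synthesis.
#' @param times_min output times in minutes; default a regular `dt_min` grid
#'   over the protocol span, always augmented with any scheduled measurement
#'   times of the protocol.
#' @param dt_min default grid spacing in minutes.
#' @param init initial state (default: resting steady state).
#' @param rtol,atol integrator tolerances.
#' @param compiled use the compiled C right-hand side (default) or the R one.
#' @return a data.frame with `time_min`, the six state variables, and derived
#'   observables `IkBa_total` (`IkBa + 1 - NFkBn`, total IkBa protein) and
#'   `NFkB_complexed` (`1 - NFkBn`).
#' @examples
#' tr <- simulate_nfkb(nfkb_params("fitted"), make_on_off(), "WT", dt_min = 5)
#' head(tr)
#' @export
simulate_nfkb <- function(params, protocol, genotype = c("WT", "A20KO"),
                          times_min = NULL, dt_min = 1, init = NULL,
                          rtol = 1e-8, atol = 1e-10, compiled = TRUE) {
  genotype <- match.arg(genotype)
  stopifnot(inherits(protocol, "nfkb_protocol"))
  segs <- protocol$segments
  horizon <- max(segs$end)
  sched_times <- unlist(protocol$schedule[[genotype]], use.names = FALSE)
  if (is.null(times_min))
    times_min <- seq(min(segs$start), horizon, by = dt_min)
  times_min <- sort(unique(c(times_min, sched_times)))
  df <- .integrate_piecewise(params, segs, times_min,
                             a20ko = identical(genotype, "A20KO"),
                             init = init, rtol = rtol, atol = atol,
                             compiled = compiled)
  df$IkBa_total <- df$IkBa + 1 - df$NFkBn
  df$NFkB_complexed <- 1 - df$NFkBn
  df
}

#' Write / read a trajectory as CSV
#'
#' The CSV carries the columns `time_min`, the six state variables, and
#' `IkBa_total`.
#'
#' @param trajectory a data.frame from [simulate_nfkb()].
#' @param path output file path.
#' @export
write_trajectory <- function(trajectory, path) {
  cols <- c("time_min", nfkb_state_names, "IkBa_total")
  write.csv(trajectory[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read.csv(path)
}

# Numerical Jacobian of the RHS at a state (central differences).
.rhs_jacobian <- function(state, params, tnf, a20ko = FALSE) {
  f <- function(y) nfkb_rhs(pmax(y, 0), params, tnf, a20ko)
  n <- length(state)
  J <- matrix(0, n, n, dimnames = list(nfkb_state_names, nfkb_state_names))
  for (j in seq_len(n)) {
    h <- max(1e-8, 1e-6 * abs(state[j]))
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- dn[j] - h
    J[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  J
}

#' Fixed point under sustained TNF and its stability
#'
#' Solves `rhs = 0` with TNF on by damped Newton iteration, seeded from the
#' time average of the tail of a long simulation (so the solver also finds
#' the unstable focus inside a stable limit cycle). Stability is judged from
#' the eigenvalues of the numerically differentiated Jacobian.
#'
#' @param params an [nfkb_params] vector.
#' @param genotype `"WT"` or `"A20KO"`.
#' @param horizon_h length of the seeding simulation in hours.
#' @param tol residual infinity-norm tolerance for the root.
#' @return a list of class `nfkb_fixed_point` with elements `state`,
#'   `stable` (max real eigenvalue < 0, with a 1e-9 1/s margin),
#'   `eigenvalue_max_real_part` (1/s), `residual_norm` and `converged`.
#' @examples
#' fp <- stimulated_fixed_point(nfkb_params("fitted"))
#' fp$stable
#' @export
stimulated_fixed_point <- function(params, genotype = c("WT", "A20KO"),
                                   horizon_h = 200, tol = 1e-12) {
  genotype <- match.arg(genotype)
  params <- as_nfkb_params(params)
  a20ko <- identical(genotype, "A20KO")
  segs <- data.frame(start = 0, end = horizon_h * 60, tnf = 1)
  tr <- .integrate_piecewise(params, segs,
                             seq(0, horizon_h * 60, by = 5), a20ko = a20ko)
  tail_rows <- tr$time_min >= 0.75 * horizon_h * 60
  x <- colMeans(tr[tail_rows, nfkb_state_names])
  f <- function(y) nfkb_rhs(pmax(y, 0), params, tnf = 1, a20ko = a20ko)
  converged <- FALSE
  for (it in seq_len(200)) {
    fx <- f(x)
    if (max(abs(fx)) < tol) { converged <- TRUE; break }
    J <- .rhs_jacobian(x, params, tnf = 1, a20ko = a20ko)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      xn <- pmax(x + lambda * step, 0)
      if (max(abs(f(xn))) < max(abs(fx)) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    x <- xn
  }
  J <- .rhs_jacobian(x, params, tnf = 1, a20ko = a20ko)
  ev <- eigen(J, only.values = TRUE)$values
  max_re <- max(Re(ev))
  structure(list(state = setNames(x, nfkb_state_names),
                 stable = max_re < -1e-9,
                 eigenvalue_max_real_part = max_re,
                 residual_norm = max(abs(f(x))),
                 converged = converged),
            class = "nfkb_fixed_point")
}

#' @export
print.nfkb_fixed_point <- function(x, ...) {
  cat("TNF-on fixed point",
      if (x$converged) "(converged)" else
        sprintf("(NOT converged, residual %.2e)", x$residual_norm), "\n")
  print(signif(x$state, 5))
  cat(sprintf("stable: %s (max Re(eigenvalue) = %.3e 1/s)\n",
              x$stable, x$eigenvalue_max_real_part))
  invisible(x)
}
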