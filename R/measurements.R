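# Internal: run code with a temporarily seeded RNG, restoring global state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Internal: construct a measurement-set data.frame.
.new_measurements <- function(df, normalized = FALSE) {
  # radix sort: locale-independent ordering, so row order (and hence the
  # assignment of seeded noise draws to measurements) is reproducible
  df <- df[order(df$protocol, df$genotype, df$observable, df$time_min,
                 method = "radix"), ]
  rownames(df) <- NULL
  structure(df, class = c("nfkb_measurements", "data.frame"),
            normalized = normalized)
}

#' Measurement bookkeeping of a measurement set
#'
#' @param ms an `nfkb_measurements` data.frame.
#' @return list with `N` (measurements), `n_series` ((protocol, genotype,
#'   observable) series) and `dim = N - n_series` (independent data points
#'   after geometric-mean normalization).
#' @export
measurement_counts <- function(ms) {
  stopifnot(inherits(ms, "nfkb_measurements"))
  key <- interaction(ms$protocol, ms$genotype, ms$observable, drop = TRUE)
  list(N = nrow(ms), n_series = nlevels(key),
       dim = nrow(ms) - nlevels(key))
}

#' Extract scheduled observables from a trajectory
#'
#' Samples `IKKa`, `NFkBn`, `A20` and `IkBat` directly and total IkBa
#' protein as `IkBa + 1 - NFkBn` at the protocol's scheduled measurement
#' times (linear interpolation on the trajectory grid where needed).
#'
#' @param trajectory data.frame from [simulate_nfkb()].
#' @param protocol an `nfkb_protocol` with a schedule for `genotype`.
#' @param genotype `"WT"` or `"A20KO"`.
#' @return a raw (unnormalized) `nfkb_measurements` data.frame with columns
#'   `protocol`, `genotype`, `observable`, `time_min`, `value`.
#' @export
extract_observables <- function(trajectory, protocol, genotype = "WT") {
  stopifnot(inherits(protocol, "nfkb_protocol"))
  sched <- protocol$schedule[[genotype]]
  if (is.null(sched) || !length(sched))
    stop("protocol '", protocol$name, "' has no schedule for ", genotype)
  if (!"IkBa_total" %in% names(trajectory))
    trajectory$IkBa_total <- trajectory$IkBa + 1 - trajectory$NFkBn
  rows <- lapply(names(sched), function(obs) {
    tt <- sched[[obs]]
    if (min(tt) < min(trajectory$time_min) - 1e-9 ||
        max(tt) > max(trajectory$time_min) + 1e-9)
      stop("scheduled time outside trajectory span for ", obs)
    v <- approx(trajectory$time_min, trajectory[[obs]], xout = tt)$y
    v <- pmax(v, 0)  # integrator undershoot can leave values at -atol
    data.frame(protocol = protocol$name, genotype = genotype,
               observable = obs, time_min = tt, value = v)
  })
  .new_measurements(do.call(rbind, rows))
}

#' Simulate a protocol's full measurement set
#'
#' Convenience wrapper: simulates each requested genotype under the protocol
#' and extracts the scheduled observables.
#'
#' @inheritParams simulate_nfkb
#' @param genotypes genotypes to include (those with a non-empty schedule).
#' @return a raw `nfkb_measurements` data.frame.
#' @examples
#' ms <- simulate_measurements(nfkb_params("fitted"), make_on_off())
#' measurement_counts(ms)  # N = 50, 9 series, dim = 41
#' @export
simulate_measurements <- function(params, protocol,
                                  genotypes = c("WT", "A20KO"),
                                  rtol = 1e-8, atol = 1e-10, compiled = TRUE) {
  genotypes <- intersect(genotypes, names(protocol$schedule))
  sets <- lapply(genotypes, function(g) {
    tt <- sort(unique(unlist(protocol$schedule[[g]], use.names = FALSE)))
    tr <- simulate_nfkb(params, protocol, g, times_min = tt,
                        rtol = rtol, atol = atol, compiled = compiled)
    extract_observables(tr, protocol, g)
  })
  .new_measurements(do.call(rbind, sets))
}

#' Two-step normalization of one measurement series
#'
#' Measurements are assumed to be in arbitrary units with multiplicative
#' (lognormal) errors. Each series is first shifted by `rho * max(x)`
#' (values below a few percent of the series maximum mostly carry
#' measurement noise) and then divided by its geometric mean, so the
#' normalized series has geometric mean exactly 1 and a series of `n`
#' points carries `n - 1` independent numbers.
#'
#' @param x non-negative numeric vector (one series), `max(x) > 0`.
#' @param rho shift fraction (default 0.03).
#' @return normalized series with geometric mean 1.
#' @examples
#' normalize_series(c(0, 1, 1))
#' @export
normalize_series <- function(x, rho = 0.03) {
  if (!length(x)) stop("empty series")
  if (any(x < 0)) stop("series values must be non-negative")
  m <- max(x)
  if (m <= 0) stop("all-zero series cannot be normalized")
  xp <- x + rho * m
  xp / exp(mean(log(xp)))
}

#' Normalize every series of a measurement set
#'
#' Applies [normalize_series()] per (protocol, genotype, observable,
#' replicate) series.
#'
#' @param ms a raw `nfkb_measurements` data.frame.
#' @param rho shift fraction (default 0.03).
#' @return a normalized `nfkb_measurements` data.frame.
#' @export
normalize_measurements <- function(ms, rho = 0.03) {
  stopifnot(inherits(ms, "nfkb_measurements"))
  if (isTRUE(attr(ms, "normalized")))
    stop("measurement set is already normalized")
  keys <- list(ms$protocol, ms$genotype, ms$observable)
  if ("replicate" %in% names(ms)) keys <- c(keys, list(ms$replicate))
  key <- interaction(keys, drop = TRUE)
  ms$value <- unsplit(lapply(split(ms$value, key), normalize_series,
                             rho = rho), key)
  .new_measurements(as.data.frame(ms), normalized = TRUE)
}

#' Multiplicative lognormal measurement noise
#'
#' Replaces each raw measurement by an independent draw from
#' `Lognormal(mu, sigma^2)` with median equal to the unperturbed value and
#' `sigma = ln(sigma_data)`, where `sigma_data >= 1` is the geometric
#' standard deviation of the measurement error. `sigma_data = 1` is a no-op.
#'
#' @param ms a raw (unnormalized) `nfkb_measurements` data.frame.
#' @param sigma_data geometric standard deviation, `>= 1`.
#' @param seed optional integer seed (global RNG state is restored).
#' @return a perturbed raw `nfkb_measurements` data.frame.
#' @export
add_lognormal_noise <- function(ms, sigma_data, seed = NULL) {
  stopifnot(inherits(ms, "nfkb_measurements"))
  if (isTRUE(attr(ms, "normalized")))
    stop("noise must be applied to raw measurements, before normalization")
  if (!is.numeric(sigma_data) || sigma_data < 1)
    stop("sigma_data must be >= 1")
  if (sigma_data == 1) return(ms)
  ms$value <- with_seed(seed,
    ms$value * exp(rnorm(nrow(ms), mean = 0, sd = log(sigma_data))))
  .new_measurements(as.data.frame(ms), normalized = FALSE)
}

#' Read / write measurement sets as long-format CSV
#'
#' Columns: `protocol`, `genotype`, `observable`, `time_min`, `value` and
#' optionally `replicate`. A header comment records whether the set is
#' normalized.
#'
#' @param ms an `nfkb_measurements` data.frame.
#' @param path CSV file path.
#' @export
write_measurements <- function(ms, path) {
  stopifnot(inherits(ms, "nfkb_measurements"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nfkbid measurements; normalized: %s",
                     isTRUE(attr(ms, "normalized"))), con)
  write.csv(as.data.frame(ms), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  first <- readLines(path, n = 1)
  normalized <- grepl("normalized: TRUE", first)
  df <- read.csv(path, comment.char = "#")
  .new_measurements(df, normalized = normalized)
}
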