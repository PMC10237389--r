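#' TNF stimulation protocols
#'
#' A protocol couples a piecewise-constant TNF stimulus (contiguous on/off
#' segments in minutes) with per-genotype, per-observable measurement
#' schedules. The five measurable observables are `IKKa`, `NFkBn`,
#' `IkBa_total` (total IkBa protein), `A20` (wild type only) and `IkBat`
#' (IkBa transcript).
#'
#' @param name protocol label.
#' @param segments data.frame with columns `start`, `end` (minutes) and
#'   `tnf` (0/1); must be contiguous, non-overlapping, starting at 0.
#' @param schedule named list (`WT`, `A20KO`) of named lists mapping
#'   observable to a strictly increasing vector of measurement times
#'   (minutes) within the stimulus horizon; may be empty.
#' @return an object of class `nfkb_protocol`.
#' @export
nfkb_protocol <- function(name, segments, schedule = list()) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("start", "end", "tnf") %in% names(segments)))
  segments <- segments[order(segments$start), c("start", "end", "tnf")]
  if (nrow(segments) == 0 || segments$start[1] != 0)
    stop("segments must start at 0")
  if (any(segments$end <= segments$start))
    stop("each segment must have end > start")
  if (nrow(segments) > 1 &&
      any(abs(segments$start[-1] - segments$end[-nrow(segments)]) > 1e-9))
    stop("segments must be contiguous and non-overlapping")
  if (!all(segments$tnf %in% c(0, 1)))
    stop("tnf must be 0 or 1 in every segment")
  horizon <- max(segments$end)
  observables <- c("IKKa", "NFkBn", "IkBa_total", "A20", "IkBat")
  for (g in names(schedule)) {
    if (!g %in% c("WT", "A20KO"))
      stop("schedule genotype must be WT or A20KO, got: ", g)
    for (obs in names(schedule[[g]])) {
      if (!obs %in% observables)
        stop("unknown observable in schedule: ", obs)
      if (g == "A20KO" && obs == "A20")
        stop("A20 cannot be measured in the A20KO genotype")
      tt <- schedule[[g]][[obs]]
      if (any(diff(tt) <= 0))
        stop("measurement times must be strictly increasing for ", g, "/", obs)
      if (any(tt < 0) || any(tt > horizon + 1e-9))
        stop("measurement times outside the stimulus horizon for ", g, "/", obs)
      schedule[[g]][[obs]] <- as.numeric(tt)
    }
  }
  structure(list(name = name, segments = segments, schedule = schedule),
            class = "nfkb_protocol")
}

#' @export
print.nfkb_protocol <- function(x, ...) {
  cat("Protocol:", x$name, "\n")
  on <- x$segments[x$segments$tnf == 1, ]
  cat(sprintf("  TNF ON: %s (horizon %g min)\n",
              if (nrow(on)) paste(sprintf("%g-%g", on$start, on$end),
                                  collapse = ", ") else "never",
              max(x$segments$end)))
  cts <- protocol_counts(x)
  cat(sprintf("  measurements: N = %d in %d series (dim = %d)\n",
              cts$N, cts$n_series, cts$dim))
  invisible(x)
}

#' The on-off identification protocol
#'
#' 2 h of continuous TNF stimulation (0-120 min) followed by a 10 h washout
#' (120-720 min), with sparse measurement schedules for the five observables
#' in wild-type cells and the same schedules minus A20 in A20-knockout
#' cells: 50 measurements in 9 series, i.e. 41 independent data points.
#' This simple protocol is a near-optimal identification experiment: the
#' stimulation phase raises every variable except IKKn and the washout
#' lets them decay, pinning down both forward and backward rates.
#'
#' @return an `nfkb_protocol`.
#' @examples
#' protocol_counts(make_on_off())
#' @export
make_on_off <- function() {
  wt <- list(
    IKKa       = c(0, 5, 30),
    NFkBn      = c(0, 5, 30, 60, 90, 120, 150, 180),
    IkBa_total = c(0, 5, 30, 60, 120, 180, 300, 720),
    A20        = c(0, 30, 60, 300),
    IkBat      = c(0, 30, 60, 300))
  nfkb_protocol(
    name = "on_off",
    segments = data.frame(start = c(0, 120), end = c(120, 720), tnf = c(1, 0)),
    schedule = list(WT = wt, A20KO = wt[setdiff(names(wt), "A20")]))
}

#' Tonic and pulsatile stimulus shapes
#'
#' `make_tonic()` builds a single switch-on protocol (TNF off up to `onset`,
#' then on to the horizon). `make_pulsatile()` builds `n_pulses` TNF pulses
#' of length `pulse_len` separated by `gap` minutes, starting at 0.
#' Measurement schedules are empty unless supplied.
#'
#' @param horizon total protocol length, minutes.
#' @param onset time of TNF switch-on, minutes (0 for stimulation from the
#'   start).
#' @param schedule optional measurement schedule (see [nfkb_protocol()]).
#' @return an `nfkb_protocol`.
#' @export
make_tonic <- function(horizon, onset = 0, schedule = list()) {
  if (horizon <= onset || onset < 0)
    stop("require 0 <= onset < horizon")
  segs <- if (onset > 0)
    data.frame(start = c(0, onset), end = c(onset, horizon), tnf = c(0, 1))
  else
    data.frame(start = 0, end = horizon, tnf = 1)
  nfkb_protocol(sprintf("tonic_%gmin_from_%gmin", horizon, onset),
                segs, schedule)
}

#' @param pulse_len pulse length, minutes.
#' @param gap gap between pulses, minutes.
#' @param n_pulses number of pulses.
#' @rdname make_tonic
#' @export
make_pulsatile <- function(pulse_len, gap, n_pulses, schedule = list()) {
  if (pulse_len <= 0 || gap <= 0 || n_pulses < 1)
    stop("pulse_len, gap must be positive and n_pulses >= 1")
  starts <- (seq_len(n_pulses) - 1) * (pulse_len + gap)
  segs <- do.call(rbind, lapply(seq_len(n_pulses), function(i) {
    on <- data.frame(start = starts[i], end = starts[i] + pulse_len, tnf = 1)
    if (i < n_pulses)
      rbind(on, data.frame(start = starts[i] + pulse_len,
                           end = starts[i + 1], tnf = 0))
    else on
  }))
  nfkb_protocol(sprintf("pulses_%gx%gmin_gap%gmin", n_pulses, pulse_len, gap),
                segs, schedule)
}

#' Measurement bookkeeping of a protocol
#'
#' `N` is the total number of scheduled measurements, `n_series` the number
#' of (genotype, observable) series, and `dim = N - n_series` the number of
#' independent data points: scaling each series by its geometric mean leaves
#' only `n - 1` independent numbers per series of `n` points.
#'
#' @param protocol an `nfkb_protocol`.
#' @return list with `N`, `n_series`, `dim`.
#' @export
protocol_counts <- function(protocol) {
  stopifnot(inherits(protocol, "nfkb_protocol"))
  lens <- unlist(lapply(protocol$schedule, function(g) vapply(g, length, 1L)))
  N <- sum(lens)
  n_series <- sum(lens > 0)
  list(N = as.integer(N), n_series = as.integer(n_series),
       dim = as.integer(N - n_series))
}

#' Independent data points of a set of protocols
#'
#' @param protocols one `nfkb_protocol` or a list of them.
#' @return integer: total `N - n_series` over all protocols.
#' @examples
#' count_independent_points(make_on_off())  # 41
#' @export
count_independent_points <- function(protocols) {
  if (inherits(protocols, "nfkb_protocol")) protocols <- list(protocols)
  dims <- vapply(protocols, function(p) {
    cts <- protocol_counts(p)
    if (cts$N == 0L) stop("protocol '", p$name, "' has an empty schedule")
    cts$dim
  }, integer(1))
  sum(dims)
}

#' Read / write protocols as YAML or JSON
#'
#' Schema: `{name, segments: [[start, end, tnf], ...], schedule: {WT:
#' {IKKa: [...], ...}, A20KO: {...}}}`. Round-tripping is the identity.
#'
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return `read_protocol` returns an `nfkb_protocol`.
#' @export
read_protocol <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported protocol file extension: ", ext))
  if (is.null(x$name) || is.null(x$segments))
    stop("protocol file must contain 'name' and 'segments'")
  segs <- x$segments
  if (!is.data.frame(segs)) {
    if (!is.matrix(segs))  # list of [start, end, tnf] triples
      segs <- do.call(rbind, lapply(segs, function(s) as.numeric(unlist(s))))
    if (ncol(segs) != 3)
      stop("each segment must be [start, end, tnf]")
    segs <- data.frame(start = segs[, 1], end = segs[, 2], tnf = segs[, 3])
  }
  sched <- x$schedule
  if (is.null(sched)) sched <- list()
  sched <- lapply(sched, function(g) lapply(g, function(v) as.numeric(unlist(v))))
  nfkb_protocol(x$name, segs, sched)
}

#' @param protocol an `nfkb_protocol`.
#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "nfkb_protocol"))
  x <- list(name = protocol$name,
            segments = lapply(seq_len(nrow(protocol$segments)), function(i)
              as.numeric(protocol$segments[i, c("start", "end", "tnf")])),
            schedule = protocol$schedule)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(x, path),
    stop("unsupported protocol file extension: ", ext))
  invisible(path)
}

# Resolve a --protocol CLI argument: built-in name or file path.
resolve_protocol <- function(spec) {
  if (identical(spec, "on_off")) return(make_on_off())
  if (file.exists(spec)) return(read_protocol(spec))
  stop("unknown protocol: ", spec,
       " (use 'on_off' or a YAML/JSON protocol file)")
}
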