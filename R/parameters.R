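#' Names of the 13 model rate constants
#'
#' Order used throughout the package: `k_deg`, `k1`, `k2`, `k3`, `a2`, `a3`,
#' `delta`, `epsilon`, `c_deg`, `c4a`, `c5a`, `c3a`, `i1a`. All are first-order
#' rate constants in 1/s except the dimensionless Michaelis-type constants
#' `delta` and `epsilon`.
#'
#' @export
nfkb_param_names <- c("k_deg", "k1", "k2", "k3", "a2", "a3", "delta",
                      "epsilon", "c_deg", "c4a", "c5a", "c3a", "i1a")

# Presets: "prefitted" carries the values obtained directly from the reduction
# of the detailed 15-variable model; "fitted" the values after refitting the
# reduced model to the detailed one over the combination experiment.
.nfkb_presets <- list(
  prefitted = c(k_deg = 0.000125, k1 = 0.0025,  k2 = 0.0625, k3 = 0.0015,
                a2 = 0.04,        a3 = 0.2,     delta = 0.0833,
                epsilon = 0.0167, c_deg = 0.000171, c4a = 0.0031,
                c5a = 0.0001,     c3a = 0.0004, i1a = 0.001),
  fitted    = c(k_deg = 0.000107, k1 = 0.00195, k2 = 0.0357, k3 = 0.00145,
                a2 = 0.0763,      a3 = 0.0946,  delta = 0.108,
                epsilon = 0.0428, c_deg = 0.000106, c4a = 0.00313,
                c5a = 0.0000578,  c3a = 0.000372, i1a = 0.000595)
)

#' Model parameter sets
#'
#' Returns one of the two named parameter presets of the reduced model,
#' optionally with individual rate constants overridden (as used when
#' exploring dynamical regimes, e.g. `nfkb_params("fitted", k2 = 0)` for the
#' A20-feedback-free variant).
#'
#' @param preset `"fitted"` (default) or `"prefitted"`.
#' @param ... named overrides of individual parameters.
#' @return a named numeric vector of class `nfkb_params` with the 13 rate
#'   constants in canonical order.
#' @examples
#' nfkb_params("fitted")
#' nfkb_params("fitted", a2 = 0.02, c5a = 1e-5, i1a = 1e-4)
#' @export
nfkb_params <- function(preset = c("fitted", "prefitted"), ...) {
  preset <- match.arg(preset)
  p <- .nfkb_presets[[preset]]
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), nfkb_param_names)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- unlist(dots)
  }
  as_nfkb_params(p)
}

#' Coerce and validate a parameter vector
#'
#' @param x named numeric vector containing all 13 rate constants.
#' @return a validated `nfkb_params` vector in canonical order.
#' @export
as_nfkb_params <- function(x) {
  x <- unlist(x)
  if (!is.numeric(x) || is.null(names(x)))
    stop("parameters must be a named numeric vector")
  missing <- setdiff(nfkb_param_names, names(x))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  p <- x[nfkb_param_names]
  if (any(!is.finite(p)) || any(p < 0))
    stop("all parameters must be finite and non-negative")
  if (p[["delta"]] <= 0 || p[["epsilon"]] <= 0)
    stop("delta and epsilon must be strictly positive (they appear in denominators)")
  structure(p, class = "nfkb_params")
}

#' @export
print.nfkb_params <- function(x, ...) {
  cat("Reduced NF-kB model parameters (1/s; delta, epsilon dimensionless):\n")
  print(signif(unclass(x), 4), ...)
  invisible(x)
}

#' Read / write parameter sets
#'
#' Parameter sets are stored as flat JSON or YAML objects keyed by the
#' canonical parameter names; the format is chosen from the file extension.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_params` returns an `nfkb_params` vector.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported parameter file extension: ", ext))
  as_nfkb_params(unlist(x))
}

#' @param params an `nfkb_params` vector (or coercible).
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  params <- as_nfkb_params(params)
  ext <- tolower(tools::file_ext(path))
  x <- as.list(unclass(params))
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(x, path),
    stop("unsupported parameter file extension: ", ext))
  invisible(path)
}

# Resolve a --params CLI argument: preset name or file path.
resolve_params <- function(spec) {
  if (spec %in% names(.nfkb_presets)) nfkb_params(spec) else read_params(spec)
}
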