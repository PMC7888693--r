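#' Derive the coefficient of friction from a catchment threshold
#'
#' Solves the Gaussian distance-decay kernel \eqn{f(d) = e^{-d^2/\beta}} for
#' \eqn{\beta} such that the weight at the catchment limit `d_max` equals
#' `w_min`, i.e. \eqn{\beta = d_{max}^2 / \ln(1/w_{min})}.
#'
#' @param d_max Maximum travel time (minutes, > 0) defining the catchment.
#' @param w_min Weight assigned at `d = d_max`; must lie strictly in (0, 1).
#' @return The coefficient of friction \eqn{\beta} in minutes squared.
#' @examples
#' derive_beta(30, 0.01)            # ~195.42
#' gaussian_weight(30, derive_beta(30, 0.01))  # back to 0.01
#' @seealso [gaussian_weight()], [decay_params()]
#' @export
derive_beta <- function(d_max, w_min) {
  if (!is.numeric(d_max) || length(d_max) != 1L || !is.finite(d_max) || d_max <= 0)
    stop("`d_max` must be a single positive number (minutes)")
  if (!is.numeric(w_min) || length(w_min) != 1L || !is.finite(w_min) ||
      w_min <= 0 || w_min >= 1)
    stop("`w_min` must lie strictly in (0, 1)")
  d_max^2 / log(1 / w_min)
}

#' Gaussian distance-decay weight
#'
#' Evaluates \eqn{f(d) = e^{-d^2/\beta}}: 1 at zero distance, strictly
#' decreasing in `d`, and equal to `w_min` at `d = d_max` when `beta` was
#' derived with [derive_beta()].
#'
#' @param d Travel time(s) in minutes, non-negative. Vectorised.
#' @param beta Coefficient of friction (minutes squared, > 0).
#' @return Weights in (0, 1], same length as `d`.
#' @export
gaussian_weight <- function(d, beta) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0))
    stop("`d` must be finite and non-negative")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("`beta` must be a single positive number")
  exp(-d^2 / beta)
}

#' Distance-decay parameter set
#'
#' Bundles the catchment threshold, the Gaussian coefficient of friction and
#' the weighting mode used throughout the floating catchment area methods.
#' In `"continuous"` mode every supply-demand pair receives an individual
#' weight from its own travel time; in `"subzones"` mode the catchment is cut
#' into `n_zones` equal-width travel-time bands and every pair in a band gets
#' the Gaussian weight of the band midpoint (the discrete scheme of the
#' earlier enhanced-2SFCA lineage).
#'
#' `beta` is derived from `(d_max, w_min)` unless given explicitly; when
#' given, `w_min` is recomputed as the weight at `d_max` so the two are
#' always consistent.
#'
#' @param d_max Maximum travel time (minutes, > 0). Default 30, the
#'   conventional car-travel threshold for primary care.
#' @param w_min Weight at the catchment limit, in (0, 1). Default 0.01.
#' @param mode `"continuous"` (default) or `"subzones"`.
#' @param n_zones Number of subzones (only used in subzones mode). Default 4.
#' @param beta Optional explicit coefficient of friction (minutes squared).
#' @return An object of class `decay_params`.
#' @examples
#' p <- decay_params(d_max = 30, w_min = 0.01)
#' weight_for(15, p)
#' @export
decay_params <- function(d_max = 30, w_min = 0.01,
                         mode = c("continuous", "subzones"),
                         n_zones = 4L, beta = NULL) {
  mode <- match.arg(mode)
  if (is.null(beta)) {
    beta <- derive_beta(d_max, w_min)
  } else {
    if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
      stop("`beta` must be a single positive number")
    if (!is.numeric(d_max) || length(d_max) != 1L || d_max <= 0)
      stop("`d_max` must be a single positive number (minutes)")
    w_min <- gaussian_weight(d_max, beta)
  }
  if (mode == "subzones") {
    if (!is.numeric(n_zones) || length(n_zones) != 1L || n_zones < 1 ||
        n_zones != as.integer(n_zones))
      stop("`n_zones` must be a positive integer in subzones mode")
    n_zones <- as.integer(n_zones)
  }
  structure(
    list(d_max = as.numeric(d_max), beta = beta, w_min = w_min,
         mode = mode, n_zones = n_zones),
    class = "decay_params"
  )
}

#' @export
print.decay_params <- function(x, ...) {
  cat("Gaussian distance-decay parameters\n")
  cat(sprintf("  d_max : %g min\n  beta  : %g min^2\n  w_min : %g\n  mode  : %s%s\n",
              x$d_max, x$beta, x$w_min, x$mode,
              if (x$mode == "subzones") sprintf(" (%d zones)", x$n_zones) else ""))
  invisible(x)
}

#' Equal-width subzone scheme over a catchment
#'
#' Cuts `[0, d_max]` into `n_zones` equal-width travel-time bands,
#' left-closed right-open except for the final band which is closed at
#' `d_max`. Each band is represented by its midpoint, the travel time at
#' which its Gaussian weight is evaluated (a band from 0 to 5 minutes is
#' weighted as d = 2.5).
#'
#' @param d_max Maximum travel time (minutes, > 0).
#' @param n_zones Number of bands (positive integer).
#' @return A data.frame with columns `lower`, `upper`, `mid`.
#' @export
subzone_scheme <- function(d_max, n_zones) {
  if (!is.numeric(d_max) || length(d_max) != 1L || d_max <= 0)
    stop("`d_max` must be a single positive number (minutes)")
  if (!is.numeric(n_zones) || length(n_zones) != 1L || n_zones < 1 ||
      n_zones != as.integer(n_zones))
    stop("`n_zones` must be a positive integer")
  n_zones <- as.integer(n_zones)
  width <- d_max / n_zones
  lower <- (seq_len(n_zones) - 1) * width
  upper <- seq_len(n_zones) * width
  data.frame(lower = lower, upper = upper, mid = (lower + upper) / 2)
}

#' Distance-decay weight for in-catchment travel times
#'
#' Dispatches on the mode of `params`: continuous mode evaluates the
#' Gaussian kernel at each travel time; subzones mode evaluates it at the
#' midpoint of the travel time's band. Travel times beyond `d_max` are out
#' of catchment and an error — callers filter pairs first.
#'
#' @param d Travel time(s) in minutes, within `[0, d_max]`. Vectorised.
#' @param params A [decay_params()] object.
#' @return Weights in (0, 1], same length as `d`.
#' @export
weight_for <- function(d, params) {
  stopifnot(inherits(params, "decay_params"))
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0))
    stop("`d` must be finite and non-negative")
  if (any(d > params$d_max))
    stop(sprintf("travel time beyond the catchment threshold d_max = %g; filter pairs first",
                 params$d_max))
  if (params$mode == "continuous") {
    gaussian_weight(d, params$beta)
  } else {
    width <- params$d_max / params$n_zones
    zone <- pmin(floor(d / width) + 1L, params$n_zones)  # d = d_max falls in the last band
    mids <- subzone_scheme(params$d_max, params$n_zones)$mid
    gaussian_weight(mids[zone], params$beta)
  }
}
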