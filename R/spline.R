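#' B-spline basis for the log baseline hazard
#'
#' Builds the cubic (by default) B-spline basis used to model
#' \eqn{\log h_0(t) = \gamma^T B(t)}. Internal knots are placed at the
#' equally-spaced percentiles `k/(K+1)`, `k = 1..K`, of the observed
#' survival times; boundary knots at 0 and `max(observed_times)`.
#' Evaluation points outside the boundary are clamped to it (constant
#' extrapolation of the basis), which keeps the hazard positive and finite.
#'
#' @param observed_times Observed survival times (events and censorings).
#' @param t Evaluation times.
#' @param n_internal_knots Number of internal knots K (>= 1).
#' @param degree Spline degree (default cubic).
#' @return A `length(t) x (K + degree + 1)` basis matrix whose rows sum to
#'   1 (partition of unity). The knot vector is attached as attribute
#'   `knots` and the boundary as `boundary`.
#' @export
spline_log_hazard_basis <- function(observed_times, t, n_internal_knots = 5,
                                    degree = 3) {
  stopifnot(n_internal_knots >= 1, degree >= 1,
            length(unique(observed_times)) > 1)
  internal <- stats::quantile(observed_times,
                              probs = seq_len(n_internal_knots) /
                                (n_internal_knots + 1),
                              names = FALSE)
  boundary <- c(0, max(observed_times))
  spline_basis_eval(t, internal, boundary, degree)
}

# evaluate the clamped B-spline basis for a known knot configuration
spline_basis_eval <- function(t, internal, boundary, degree = 3) {
  knots <- c(rep(boundary[1], degree + 1), internal,
             rep(boundary[2], degree + 1))
  tc <- pmin(pmax(t, boundary[1]), boundary[2])
  B <- splines::splineDesign(knots, tc, ord = degree + 1, outer.ok = TRUE)
  attr(B, "knots") <- internal
  attr(B, "boundary") <- boundary
  B
}
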