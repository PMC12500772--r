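#' Coexistence fixed point of the homogeneous map
#'
#' Closed form of the unique positive coexistence state:
#' `m* = alpha (r - 1) / (1 - alpha r)` and
#' `a* = (1 - alpha r) / (r (1 - alpha))`. The proportional-differential
#' feedback is referenced to `a*`, so the fixed point does not depend on
#' the gains `kp`, `kd`.
#'
#' @param params An [ma_params()] object satisfying condition C1 or C2.
#' @return Named numeric vector `c(m = , a = )`.
#' @examples
#' fixed_point(ma_params(alpha = 0.5, r = 1.4))
#' @export
fixed_point <- function(params) {
  stopifnot(inherits(params, "ma_params"))
  alpha <- params$alpha; r <- params$r
  if (abs(alpha * r - 1) < 1e-12 || abs(alpha - 1) < 1e-12) {
    stop("degenerate parameters: alpha * r = 1 or alpha = 1")
  }
  if (!params$coexistence) {
    stop("no positive coexistence fixed point: neither condition C1 nor C2 holds")
  }
  c(m = alpha * (r - 1) / (1 - alpha * r),
    a = (1 - alpha * r) / (r * (1 - alpha)))
}

#' One step of the homogeneous (spatially uniform) controlled map
#'
#' Applies the reaction update at a single spatially uniform state:
#' mussels grow by grazing (`r m a`) and die with a Holling II saturated
#' mortality (`m / (1 + m)`); algae follow the layer-exchange/grazing
#' balance with the proportional feedback `kp (a - a*)` added, the whole
#' bracket scaled by `tau / (1 - kd)` after solving the differential
#' feedback term for the next state.
#'
#' Negative outputs are returned as-is (they signal impending divergence
#' for large `tau`); nonnegativity is enforced only on the input.
#'
#' @param state Named numeric vector `c(m = , a = )` with nonnegative
#'   entries.
#' @param params An [ma_params()] with `tau` set.
#' @return Named numeric vector `c(m = , a = )`.
#' @examples
#' p <- ma_params(tau = 3.6)
#' step_homogeneous(fixed_point(p), p)
#' @export
step_homogeneous <- function(state, params) {
  stopifnot(inherits(params, "ma_params"), !is.null(params$tau))
  m <- state[["m"]]; a <- state[["a"]]
  stopifnot(m >= 0, a >= 0)
  astar <- fixed_point(params)[["a"]]
  tau <- params$tau
  c(m = m + tau * (params$r * m * a - m / (1 + m)),
    a = a + tau / (1 - params$kd) *
      ((params$alpha * (1 - a) - m * a) / params$gamma +
         params$kp * (a - astar)))
}

#' Jacobian of the homogeneous map at the coexistence fixed point
#'
#' Closed-form linearisation `J(tau)` of the controlled map evaluated at
#' `(m*, a*)`. The four entries are polynomial in `tau` with coefficients
#' in `alpha`, `r`, `gamma`, `kp`, `kd`.
#'
#' @param params An [ma_params()] object.
#' @param tau Monitoring time step; defaults to `params$tau`.
#' @return A 2x2 numeric matrix.
#' @examples
#' jacobian(ma_params(tau = 1))
#' @export
jacobian <- function(params, tau = params$tau) {
  stopifnot(inherits(params, "ma_params"), !is.null(tau))
  alpha <- params$alpha; r <- params$r; gamma <- params$gamma
  kp <- params$kp; kd <- params$kd
  if (kd == 1) stop("degenerate parameters: kd = 1")
  matrix(c(
    1 - (r - 1) * alpha * (r * alpha - 1) * tau / (alpha - 1)^2,
    r * alpha * (1 - r) * tau / (r * alpha - 1),
    (r * alpha - 1) * tau / (r * (alpha - 1) * gamma * (kd - 1)),
    1 + (gamma * kp + r * alpha * (alpha - 1 - gamma * kp)) * tau /
      ((r * alpha - 1) * gamma * (kd - 1))
  ), nrow = 2, byrow = TRUE)
}

# Jacobian of the map at an arbitrary state (used for Lyapunov exponents
# and finite-difference cross-checks)
jacobian_at <- function(state, params) {
  m <- state[[1]]; a <- state[[2]]
  tau <- params$tau; kd <- params$kd
  matrix(c(
    1 + tau * (params$r * a - 1 / (1 + m)^2),
    tau * params$r * m,
    -tau * a / (params$gamma * (1 - kd)),
    1 + tau / (1 - kd) * (-(params$alpha + m) / params$gamma + params$kp)
  ), nrow = 2, byrow = TRUE)
}

#' Stability classification of the coexistence fixed point
#'
#' Computes the eigenvalues of `J(tau)` and labels the fixed point by
#' their moduli and the discriminant `p^2 - 4q` (with `p = -tr J`,
#' `q = det J`): saddle, stable/unstable node, focus or degenerate node.
#' Alongside the direct eigenvalue label, the closed-form parameter
#' conditions for a saddle (SD1-SD4), a stable node (SN1-SN3) and a
#' stable degenerate node (SDN1-SDN3) are matched and reported.
#'
#' @param params An [ma_params()] with `tau` set; condition C2 must hold.
#' @param tol Modulus tolerance around 1 below which the point is
#'   labelled non-hyperbolic.
#' @return An object of class `ma_stability` with fields `eigenvalues`,
#'   `trace`, `det`, `label` and `matched_condition`.
#' @examples
#' classify_fixed_point(ma_params(tau = 3.6))
#' @export
classify_fixed_point <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "ma_params"), !is.null(params$tau))
  J <- jacobian(params)
  ev <- eigen(J, only.values = TRUE)$values
  mods <- Mod(ev)
  p <- -sum(diag(J))
  q <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  disc <- p^2 - 4 * q

  label <- if (any(abs(mods - 1) < tol)) {
    "non-hyperbolic"
  } else if (disc > 0 && xor(mods[1] > 1, mods[2] > 1)) {
    "saddle"
  } else if (all(mods < 1)) {
    if (disc > 0) "stable-node"
    else if (disc < 0) "stable-focus"
    else "stable-degenerate-node"
  } else {
    if (disc > 0) "unstable-node"
    else if (disc < 0) "unstable-focus"
    else "unstable-degenerate-node"
  }

  structure(
    list(eigenvalues = ev, trace = -p, det = q, discriminant = disc,
         label = label,
         matched_condition = matched_condition(params)),
    class = "ma_stability"
  )
}

# Which of the closed-form parameter blocks (SD1-SD4, SN1-SN3, SDN1-SDN3)
# the parameter set satisfies, or "none".
matched_condition <- function(params, tol = 1e-9) {
  th <- flip_thresholds(params)
  alpha <- params$alpha; gamma <- params$gamma
  kp <- params$kp; kd <- params$kd; tau <- params$tau
  kds <- th$kd_star; kps <- th$kp_star
  g0 <- th$gamma0; tf <- th$tau_f; tfb <- th$tau_fbar; tN <- th$tau_N
  kp_lo <- (alpha - 1) / gamma
  eq <- function(x, y) is.finite(x) && is.finite(y) && abs(x - y) <= tol * max(1, abs(y))

  if (kds < kd && kd < 1 && kp < kp_lo && is.finite(tfb) &&
      0 < tau && tau < tfb) return("SD1")
  if (kd <= kds && kp < kp_lo && is.finite(tfb) &&
      0 < tau && tau < tfb) return("SD2")
  if (kd > 1 && kp > kp_lo && is.finite(tfb) &&
      0 < tau && tau < tfb) return("SD3")
  if (kds < kd && kd < 1 && kp_lo < kp && kp < kps && is.finite(tf) &&
      tf < tau && tau < tfb) return("SD4")

  in_kp_band <- is.finite(kps) && kp_lo < kp && kp < kps
  if (0 < kd && kd < 1 && eq(gamma, g0) && in_kp_band && is.finite(tf) &&
      0 < tau && tau < tf) return("SN1")
  if (kds < kd && kd < 1 && gamma < g0 && in_kp_band && is.finite(tf) &&
      0 < tau && tau < tf) return("SN2")
  if (kds < kd && kd < 1 && gamma > g0 && in_kp_band && is.finite(tf) &&
      0 < tau && tau < tf) return("SN3")

  at_kps <- is.finite(kps) && eq(kp, kps)
  if (0 < kd && kd < 1 && eq(gamma, g0) && at_kps &&
      0 < tau && tau < tN) return("SDN1")
  if (kds < kd && kd < 1 && gamma < g0 && at_kps &&
      0 < tau && tau < tN) return("SDN2")
  if (kds < kd && kd < 1 && gamma > g0 && at_kps &&
      0 < tau && tau < tN) return("SDN3")
  "none"
}

#' @export
print.ma_stability <- function(x, ...) {
  cat("<ma_stability>\n")
  cat(sprintf("  eigenvalues: %s, %s\n",
              format(x$eigenvalues[1]), format(x$eigenvalues[2])))
  cat(sprintf("  trace = %g, det = %g\n", x$trace, x$det))
  cat(sprintf("  label: %s (condition %s)\n", x$label, x$matched_condition))
  invisible(x)
}

#' Iterate the homogeneous map and record the attractor
#'
#' Runs the map for `transient` steps from `start` (default: the fixed
#' point displaced by +0.01 in each coordinate), then records `record`
#' further states and detects the minimal period of the recorded segment.
#'
#' @param params An [ma_params()] with `tau` set.
#' @param start Named numeric start state; default `fixed_point + 0.01`.
#' @param transient,record Nonnegative integers.
#' @param tolerance,max_period Passed to [detect_period()].
#' @param floor Divergence floor: any coordinate below it aborts with an
#'   error naming the step.
#' @return An `ma_orbit`: a tibble with columns `t`, `m`, `a`, and
#'   attributes `period` (integer or `NA` for aperiodic),
#'   `transient_used` and `tolerance`.
#' @examples
#' orb <- iterate_map(ma_params(tau = 4.2), transient = 2000, record = 128)
#' attr(orb, "period")
#' @export
iterate_map <- function(params, start = NULL, transient = 10000L,
                        record = 256L, tolerance = 1e-6, max_period = 64L,
                        floor = -10) {
  stopifnot(inherits(params, "ma_params"), !is.null(params$tau),
            transient >= 0, record >= 0)
  if (is.null(start)) start <- fixed_point(params) + 0.01
  astar <- fixed_point(params)[["a"]]
  samp <- cpp_homog_orbit(start[["m"]], start[["a"]],
                          params$alpha, params$r, params$gamma,
                          params$kp, params$kd, astar, params$tau,
                          as.integer(transient), as.integer(record), floor)
  out <- tibble::tibble(t = transient + seq_len(record),
                        m = samp[, 1], a = samp[, 2])
  period <- if (record >= 2 * max_period) {
    detect_period(samp, tolerance = tolerance, max_period = max_period)
  } else {
    NA_integer_
  }
  structure(out, period = period, transient_used = as.integer(transient),
            tolerance = tolerance, class = c("ma_orbit", class(out)))
}

#' Minimal period of a recorded orbit segment
#'
#' Returns the smallest `P <= max_period` such that every recorded state
#' is within `tolerance` (Euclidean) of the state `P` steps later, or
#' `NA` (aperiodic) if none qualifies.
#'
#' @param samples Two-column matrix (or data frame) of states; at least
#'   `2 * max_period` rows.
#' @param tolerance Euclidean distance tolerance.
#' @param max_period Largest period considered.
#' @return Integer period or `NA_integer_`.
#' @export
detect_period <- function(samples, tolerance = 1e-6, max_period = 64L) {
  samples <- as.matrix(samples[, c(1, 2)])
  nr <- nrow(samples)
  if (nr < 2 * max_period) {
    stop("need at least 2 * max_period samples to detect periods up to ",
         max_period)
  }
  for (P in seq_len(max_period)) {
    idx <- seq_len(nr - P)
    d2 <- (samples[idx, 1] - samples[idx + P, 1])^2 +
      (samples[idx, 2] - samples[idx + P, 2])^2
    if (all(d2 <= tolerance^2)) return(P)
  }
  NA_integer_
}

#' Maximum Lyapunov exponent of the homogeneous map
#'
#' Estimates the largest Lyapunov exponent by propagating a tangent
#' vector with the state-dependent Jacobian along the attractor and
#' averaging the log of its norm growth, renormalising every step.
#' Negative at stable fixed points and periodic orbits, positive in
#' chaos; at a stable fixed point it equals `log |lambda_max|` of
#' `J(tau)`.
#'
#' @inheritParams iterate_map
#' @param steps Accumulation steps (>= 1000).
#' @return Scalar exponent (per iteration).
#' @examples
#' max_lyapunov(ma_params(tau = 3.6))
#' @export
max_lyapunov <- function(params, start = NULL, transient = 1000L,
                         steps = 10000L, floor = -10) {
  stopifnot(inherits(params, "ma_params"), !is.null(params$tau),
            steps >= 1000)
  if (is.null(start)) start <- fixed_point(params) + 0.01
  astar <- fixed_point(params)[["a"]]
  cpp_lyapunov(start[["m"]], start[["a"]],
               params$alpha, params$r, params$gamma,
               params$kp, params$kd, astar, params$tau,
               as.integer(transient), as.integer(steps), floor)
}
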