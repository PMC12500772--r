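#' Closed-form flip-bifurcation thresholds
#'
#' Evaluates the critical quantities controlling the flip (period
#' doubling) of the coexistence fixed point: the boundary mortality ratio
#' `gamma0`, the gain boundaries `kd_star` and `kp_star`, the vertex
#' `tau_N` of the determinant parabola and the two roots `tau_f` (the
#' flip threshold, where one eigenvalue of `J(tau)` reaches -1) and
#' `tau_fbar`. When the discriminant is negative the `tau` roots are
#' reported as `NA` (no flip along this parameter ray).
#'
#' @param params An [ma_params()] object (its `tau`, if any, is ignored).
#' @return An object of class `ma_flip_thresholds`: a list with fields
#'   `gamma0`, `kd_star`, `kp_star`, `tau_N`, `tau_f`, `tau_fbar` and
#'   `discriminant`.
#' @examples
#' flip_thresholds(ma_params(alpha = 0.5, r = 1.4, gamma = 1.2))
#' @export
flip_thresholds <- function(params) {
  stopifnot(inherits(params, "ma_params"))
  alpha <- params$alpha; r <- params$r; gamma <- params$gamma
  kp <- params$kp; kd <- params$kd
  if (abs(alpha - 1 - gamma * kp) < 1e-14) {
    stop("degenerate parameters: alpha - 1 - gamma * kp = 0")
  }
  if (kd == 1) stop("degenerate parameters: kd = 1")

  gamma0 <- -(alpha - 1)^3 / ((r - 1) * alpha * (r * alpha - 1)^2)
  kd_star <- 1 + (alpha - 1)^3 / ((r - 1) * alpha * (r * alpha - 1)^2 * gamma)
  kp_rad <- (r - 1) * alpha * (kd - 1) / ((alpha - 1) * gamma)
  kp_star <- if (kp_rad >= 0) {
    -2 * sqrt(kp_rad) +
      alpha * (gamma + r * ((alpha - 1)^3 +
                              (-1 - (r - 1) * alpha * (r * alpha - 2)) * gamma) +
                 (r - 1) * (r * alpha - 1)^2 * gamma * kd) /
        ((alpha - 1)^2 * (r * alpha - 1) * gamma)
  } else {
    NaN
  }
  denom <- (r - 1) * alpha * (r * alpha - 1)^2 * (alpha - 1 - gamma * kp)
  tau_N <- (r^2 * alpha^2 * (2 + alpha) * gamma * (kd - 1) +
              gamma * (kp + alpha * ((alpha - 2) * kp + kd - 1)) -
              r^3 * alpha^3 * gamma * (kd - 1)) / denom +
    (r * alpha * (alpha^3 - 1 + gamma - alpha^2 * (3 + gamma * kp) +
                    alpha * (3 + 2 * gamma * (1 + kp - kd)) -
                    gamma * (kp + kd))) / denom
  disc <- tau_N^2 - 4 * (alpha - 1)^2 * gamma * (1 - kd) /
    ((r - 1) * alpha * (r * alpha - 1) * (alpha - 1 - gamma * kp))
  if (is.finite(disc) && disc >= 0) {
    tau_f <- tau_N - sqrt(disc)
    tau_fbar <- tau_N + sqrt(disc)
  } else {
    tau_f <- NA_real_
    tau_fbar <- NA_real_
  }
  structure(
    list(gamma0 = gamma0, kd_star = kd_star, kp_star = kp_star,
         tau_N = tau_N, tau_f = tau_f, tau_fbar = tau_fbar,
         discriminant = disc),
    class = "ma_flip_thresholds"
  )
}

#' @export
print.ma_flip_thresholds <- function(x, ...) {
  cat("<ma_flip_thresholds>\n")
  cat(sprintf("  tau_f = %s, tau_N = %g, tau_fbar = %s\n",
              format(x$tau_f), x$tau_N, format(x$tau_fbar)))
  cat(sprintf("  gamma0 = %g, kd* = %g, kp* = %g\n",
              x$gamma0, x$kd_star, x$kp_star))
  invisible(x)
}

#' Numerical flip threshold (eigenvalue -1 root)
#'
#' Independent root-finding check of the closed-form `tau_f`: bisection
#' on `1 + tr J(tau) + det J(tau) = 0`, the condition for an eigenvalue
#' to equal -1.
#'
#' @param params An [ma_params()] object.
#' @param bracket Search interval for `tau`.
#' @param tol Root tolerance.
#' @return The smallest root in the bracket, or `NA` if the
#'   characteristic quantity does not change sign there.
#' @export
flip_threshold_numeric <- function(params, bracket = c(1e-6, 50),
                                   tol = 1e-10) {
  f <- function(tau) {
    J <- jacobian(params, tau = tau)
    1 + sum(diag(J)) + (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
  }
  # det(J + I) = 0 is quadratic in tau: the sign may change twice. Scan a
  # grid for the first sign change, then bisect.
  taus <- seq(bracket[1], bracket[2], length.out = 2048)
  vals <- vapply(taus, f, numeric(1))
  sc <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (length(sc) == 0) return(NA_real_)
  stats::uniroot(f, c(taus[sc[1]], taus[sc[1] + 1]), tol = tol)$root
}

# The two excluded tau values in the flip condition blocks (transversality
# exclusions; both share one closed form up to the factor 2 vs 4).
flip_excluded_taus <- function(params) {
  alpha <- params$alpha; r <- params$r; gamma <- params$gamma
  kp <- params$kp; kd <- params$kd
  den <- (r - 1) * alpha * (r * alpha - 1)^2 * gamma * (kd - 1) -
    (gamma * kp + r * alpha * (alpha - 1 - gamma * kp)) * (alpha - 1)^2
  base <- (alpha - 1)^2 * (r * alpha - 1) * gamma * (kd - 1) / den
  c(2 * base, 4 * base)
}

#' Which flip-condition block holds
#'
#' Checks the three closed-form flip-bifurcation condition blocks (H1:
#' `gamma = gamma0`; H2: `gamma < gamma0`; H3: `gamma > gamma0`, each
#' with the gain bands and `tau = tau_f` plus the two transversality
#' exclusions) and returns the first that fires, `H1` taking precedence
#' on the boundary `gamma = gamma0`.
#'
#' @param params An [ma_params()] with `tau` set.
#' @param tol Relative tolerance for the equalities `tau = tau_f` and
#'   `gamma = gamma0`.
#' @return `"H1"`, `"H2"`, `"H3"` or `"none"`.
#' @export
flip_condition <- function(params, tol = 1e-8) {
  stopifnot(inherits(params, "ma_params"), !is.null(params$tau))
  th <- flip_thresholds(params)
  if (!is.finite(th$tau_f)) return("none")
  alpha <- params$alpha; gamma <- params$gamma
  kp <- params$kp; kd <- params$kd; tau <- params$tau
  eq <- function(x, y) abs(x - y) <= tol * max(1, abs(y))
  if (!eq(tau, th$tau_f)) return("none")
  excl <- flip_excluded_taus(params)
  if (any(vapply(excl, function(e) is.finite(e) && eq(tau, e), logical(1)))) {
    return("none")
  }
  kp_band <- is.finite(th$kp_star) &&
    (alpha - 1) / gamma < kp && kp < th$kp_star
  if (!kp_band) return("none")
  if (0 < kd && kd < 1 && eq(gamma, th$gamma0)) return("H1")
  if (th$kd_star < kd && kd < 1 && gamma < th$gamma0) return("H2")
  if (th$kd_star < kd && kd < 1 && gamma > th$gamma0) return("H3")
  "none"
}

#' Centre-manifold normal form of the flip bifurcation
#'
#' Performs the full reduction of the homogeneous map at `tau = tau_f`:
#' shifts the fixed point to the origin, expands to third order (the
#' coefficients `a_ijk`, `b_ijk` of the `w`, `z`, `tau-tau_f`
#' expansion), diagonalises with the critical eigenvector transformation,
#' solves for the quadratic centre-manifold coefficients `e1`, `e2`
#' (`e3 = 0`), restricts the dynamics to the manifold to obtain the
#' one-dimensional cubic map with coefficients `mu1`-`mu5`, and reports
#' the transversality and criticality quantities `eta1 = mu2` and
#' `eta2 = mu5 + mu1^2`. A stable period-2 orbit bifurcates when
#' `eta2 > 0`, an unstable one when `eta2 < 0`.
#'
#' The quadratic/cubic expansion coefficients are cross-validated against
#' finite-difference Taylor coefficients of the shifted map; a
#' discrepancy aborts (it would silently corrupt `eta2`).
#'
#' @param params An [ma_params()] object; `tau` is ignored (the reduction
#'   is performed at `tau_f`).
#' @param validate Check expansion coefficients against finite
#'   differences (default `TRUE`).
#' @return An object of class `ma_flip_report`: list with `thresholds`,
#'   `matched_condition`, `coeffs` (all expansion and normal-form
#'   coefficients), `eta1`, `eta2` and `verdict`.
#' @examples
#' nf <- normal_form(ma_params(alpha = 0.5, r = 1.4, gamma = 1.2))
#' nf$eta1
#' nf$eta2
#' @export
normal_form <- function(params, validate = TRUE) {
  stopifnot(inherits(params, "ma_params"))
  th <- flip_thresholds(params)
  if (!is.finite(th$tau_f)) {
    stop("no flip threshold: discriminant is negative for this parameter set")
  }
  cond <- flip_condition(with_tau(params, th$tau_f))
  alpha <- params$alpha; r <- params$r; gamma <- params$gamma
  kp <- params$kp; kd <- params$kd; tf <- th$tau_f

  a100 <- 1 - (r - 1) * alpha * (r * alpha - 1) * tf / (alpha - 1)^2
  a010 <- r * alpha * (1 - r) * tf / (r * alpha - 1)
  a200 <- (r * alpha - 1)^3 * tf / (alpha - 1)^3
  a110 <- r * tf
  a101 <- -(r - 1) * alpha * (r * alpha - 1) / (alpha - 1)^2
  a011 <- r * alpha * (1 - r) / (r * alpha - 1)
  a201 <- (r * alpha - 1)^3 / (alpha - 1)^3
  a111 <- r
  a300 <- -(r * alpha - 1)^4 * tf / (alpha - 1)^4
  b100 <- (r * alpha - 1) * tf / (r * (alpha - 1) * gamma * (kd - 1))
  b010 <- 1 + (gamma * kp + r * alpha * (alpha - 1 - gamma * kp)) * tf /
    ((r * alpha - 1) * gamma * (kd - 1))
  b110 <- -tf / (gamma * (1 - kd))
  b101 <- -(r * alpha - 1) / (r * (alpha - 1) * gamma * (1 - kd))
  b011 <- (gamma * kp + r * alpha * (alpha - 1 - gamma * kp)) /
    ((r * alpha - 1) * gamma * (kd - 1))
  b111 <- -1 / (gamma * (1 - kd))

  if (validate) {
    validate_expansion(params, tf,
                       list(a200 = a200, a110 = a110, a300 = a300,
                            b110 = b110))
  }

  lambda2 <- 1 + a100 + b010
  e1 <- (1 + a100) * ((1 + a100) * a110 + a010 * (b110 - a200)) /
    (-1 + lambda2^2)
  e2 <- (a011 * (1 + a100)^2 -
           a010 * ((1 + a100) * a101 - (1 + a100) * b011 + a010 * b101)) /
    (a010 * (1 + lambda2)^2)
  e3 <- 0

  mu1 <- (a100^2 * a110 +
            a100 * (a010 * (b110 - a200) - a110 * (lambda2 - 1)) -
            a110 * lambda2 + a010 * (b110 + a200 * lambda2)) / (1 + lambda2)
  mu2 <- (-a010 * (a010 * b101 - (1 + a100) * b011) +
            (a011 * (1 + a100) - a010 * a101) * (a100 - lambda2)) /
    (a010 * (1 + lambda2))
  mu3 <- (a011 * e1 * (a100 - lambda2)^2 +
            a010 * (a100 - lambda2) *
              ((1 + a100) * a111 - a101 * e1 + b011 * e1 + a110 * e2 +
                 2 * a100 * a110 * e2 - a110 * e2 * lambda2) +
            a010^2 * (b111 - b101 * e1 + b110 * e2 +
                        a100 * (b111 - a201 + 2 * (b110 - a200) * e2) +
                        a201 * lambda2 + 2 * a200 * e2 * lambda2 -
                        b110 * e2 * lambda2)) /
    (a010 * (1 + lambda2))
  mu4 <- e2 * (a011 * (a100 - lambda2)^2 -
                 a010 * (a100 * (a101 - b011) + a010 * b101 +
                           (b011 - a101) * lambda2)) /
    (a010 * (1 + lambda2))
  mu5 <- (a010^2 * a300 * (lambda2 - a100) +
            a010 * e1 * (-2 * a100 * (a200 - b110) - b110 * (lambda2 - 1) +
                           2 * a200 * lambda2) +
            a110 * e1 * (2 * a100^2 + a100 * (1 - 3 * lambda2) +
                           (lambda2 - 1) * lambda2)) /
    (1 + lambda2)

  eta1 <- mu2
  eta2 <- mu5 + mu1^2
  verdict <- if (abs(eta1 * eta2) < 1e-10) {
    "degenerate (eta1 * eta2 = 0)"
  } else if (eta2 > 0) {
    "stable period-2 bifurcates"
  } else {
    "unstable period-2 bifurcates"
  }

  structure(
    list(
      thresholds = th,
      matched_condition = cond,
      coeffs = list(a100 = a100, a010 = a010, a200 = a200, a110 = a110,
                    a101 = a101, a011 = a011, a201 = a201, a111 = a111,
                    a300 = a300, b100 = b100, b010 = b010, b110 = b110,
                    b101 = b101, b011 = b011, b111 = b111,
                    lambda2 = lambda2, e1 = e1, e2 = e2, e3 = e3,
                    mu1 = mu1, mu2 = mu2, mu3 = mu3, mu4 = mu4, mu5 = mu5),
      eta1 = eta1, eta2 = eta2, verdict = verdict
    ),
    class = "ma_flip_report"
  )
}

# Cross-check the tau-independent quadratic/cubic expansion coefficients
# against finite-difference Taylor coefficients of the shifted map at the
# fixed point.
validate_expansion <- function(params, tf, cf, h = 1e-3, rtol = 1e-4) {
  p <- with_tau(params, tf)
  s0 <- fixed_point(p)
  f <- function(w, z) step_homogeneous(c(m = s0[["m"]] + w,
                                         a = s0[["a"]] + z), p) - s0
  fww <- (f(h, 0) - 2 * f(0, 0) + f(-h, 0)) / h^2
  fwz <- (f(h, h) - f(h, -h) - f(-h, h) + f(-h, -h)) / (4 * h^2)
  fwww <- (f(2 * h, 0) - 2 * f(h, 0) + 2 * f(-h, 0) - f(-2 * h, 0)) /
    (2 * h^3)
  got <- c(a200 = fww[["m"]] / 2, a110 = fwz[["m"]], a300 = fwww[["m"]] / 6,
           b110 = fwz[["a"]])
  want <- unlist(cf)[names(got)]
  bad <- abs(got - want) > rtol * pmax(1, abs(want))
  if (any(bad)) {
    stop("expansion coefficient mismatch vs finite differences: ",
         paste(names(got)[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.ma_flip_report <- function(x, ...) {
  cat("<ma_flip_report>\n")
  cat(sprintf("  tau_f = %s (condition %s)\n",
              format(x$thresholds$tau_f), x$matched_condition))
  cat(sprintf("  eta1 = %g, eta2 = %g\n", x$eta1, x$eta2))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' Empirical check of supercritical amplitude scaling
#'
#' Simulates the homogeneous map at `tau = tau_f + epsilon` for each
#' requested offset, locates the bifurcated period-2 orbit, and fits the
#' log amplitude against log epsilon. A supercritical flip gives slope
#' 1/2.
#'
#' @param params An [ma_params()] object (reduction at `tau_f`).
#' @param epsilon Positive offsets above threshold.
#' @param transient,record Orbit settings per offset.
#' @return List with `slope`, `amplitudes` (tibble of epsilon,
#'   amplitude, period) and `ok` (slope within 0.5 +/- 0.1 and every
#'   offset yielded period 2).
#' @export
verify_supercriticality <- function(params, epsilon = c(0.01, 0.04, 0.16),
                                    transient = 20000L, record = 128L) {
  nf <- normal_form(params, validate = FALSE)
  if (nf$eta2 <= 0) stop("eta2 <= 0: bifurcating period-2 orbit is unstable")
  tf <- nf$thresholds$tau_f
  rows <- purrr::map(epsilon, function(eps) {
    orb <- iterate_map(with_tau(params, tf + eps),
                       transient = transient, record = record)
    per <- attr(orb, "period")
    amp <- if (identical(per, 2L)) {
      st <- as.matrix(orb[1:2, c("m", "a")])
      sqrt(sum((st[1, ] - st[2, ])^2)) / 2
    } else {
      NA_real_
    }
    tibble::tibble(epsilon = eps, amplitude = amp, period = per)
  })
  amps <- dplyr::bind_rows(rows)
  ok_periods <- all(!is.na(amps$amplitude))
  slope <- if (ok_periods && nrow(amps) >= 2) {
    stats::coef(stats::lm(log(amplitude) ~ log(epsilon), data = amps))[[2]]
  } else {
    NA_real_
  }
  list(slope = slope, amplitudes = amps,
       ok = ok_periods && is.finite(slope) && abs(slope - 0.5) <= 0.1)
}
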