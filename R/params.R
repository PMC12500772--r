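#' Nondimensional model parameters
#'
#' Bundles the reaction and control parameters of the homogeneous
#' mussel-algae map. `alpha` is the dimensionless layer-exchange ratio,
#' `r` the dimensionless algae-to-mussel conversion parameter, `gamma`
#' the dimensionless mortality ratio, `kp` and `kd` the proportional and
#' differential feedback gains, and `tau` the dimensionless monitoring
#' time step (the bifurcation parameter).
#'
#' A positive coexistence fixed point exists when either
#' `0 < 1/alpha < r < 1` (condition C1) or `0 < alpha < 1/r < 1`
#' (condition C2) holds; the latter is the regime studied throughout.
#' The differential gain must satisfy `kd != 1` because the controlled
#' algae update divides by `1 - kd`.
#'
#' @param alpha Exchange ratio, > 0.
#' @param r Conversion parameter, > 0.
#' @param gamma Mortality ratio, > 0.
#' @param kp Proportional gain (any real).
#' @param kd Differential gain (real, not equal to 1).
#' @param tau Monitoring time step, > 0, or `NULL` when the object is used
#'   for threshold computations that treat `tau` as the free parameter.
#'
#' @return An object of class `ma_params`.
#' @examples
#' p <- ma_params(alpha = 0.5, r = 1.4, gamma = 1.2, tau = 3.6)
#' fixed_point(p)
#' @export
ma_params <- function(alpha = 0.5, r = 1.4, gamma = 1.2,
                      kp = 0, kd = 0, tau = NULL) {
  stopifnot(is.numeric(alpha), alpha > 0, is.numeric(r), r > 0,
            is.numeric(gamma), gamma > 0, is.numeric(kp), is.numeric(kd))
  if (kd == 1) {
    stop("`kd` must not equal 1: the controlled update divides by 1 - kd")
  }
  if (!is.null(tau)) stopifnot(is.numeric(tau), tau > 0)
  structure(
    list(alpha = alpha, r = r, gamma = gamma, kp = kp, kd = kd, tau = tau,
         coexistence = has_coexistence(alpha, r)),
    class = "ma_params"
  )
}

# C1: 0 < 1/alpha < r < 1;  C2: 0 < alpha < 1/r < 1
has_coexistence <- function(alpha, r) {
  c1 <- 1 / alpha < r && r < 1
  c2 <- alpha < 1 / r && 1 / r < 1
  c1 || c2
}

#' @export
print.ma_params <- function(x, ...) {
  cat("<ma_params>\n")
  cat(sprintf("  alpha = %g, r = %g, gamma = %g\n", x$alpha, x$r, x$gamma))
  cat(sprintf("  control: kp = %g, kd = %g\n", x$kp, x$kd))
  cat(sprintf("  tau = %s\n", if (is.null(x$tau)) "<free>" else format(x$tau)))
  cat(sprintf("  coexistence fixed point: %s\n",
              if (x$coexistence) "yes" else "no"))
  invisible(x)
}

with_tau <- function(params, tau) {
  params$tau <- tau
  params
}

#' Diffusion / lattice geometry parameters
#'
#' `d_m1` and `d_a2` are the mussel and algae self-diffusion coefficients;
#' `d_m2` (mussels moving along algae gradients) and `d_a1` (algae moving
#' along mussel gradients) are the cross-diffusion coefficients. `delta`
#' is the spatial step of the lattice and `n` the side length of the
#' periodic n-by-n grid.
#'
#' @param d_m1,d_m2,d_a1,d_a2 Nonnegative diffusion coefficients.
#' @param delta Space step, > 0.
#' @param n Lattice side length, integer >= 2.
#' @return An object of class `ma_diffusion`.
#' @examples
#' ma_diffusion(d_m1 = 0.8, d_a2 = 1, delta = 10)
#' @export
ma_diffusion <- function(d_m1 = 0, d_m2 = 0, d_a1 = 0, d_a2 = 0,
                         delta = 10, n = 100L) {
  stopifnot(d_m1 >= 0, d_m2 >= 0, d_a1 >= 0, d_a2 >= 0,
            delta > 0, n >= 2)
  structure(
    list(d_m1 = d_m1, d_m2 = d_m2, d_a1 = d_a1, d_a2 = d_a2,
         delta = delta, n = as.integer(n)),
    class = "ma_diffusion"
  )
}

#' @export
print.ma_diffusion <- function(x, ...) {
  cat("<ma_diffusion>\n")
  cat(sprintf("  self: d_m1 = %g, d_a2 = %g; cross: d_m2 = %g, d_a1 = %g\n",
              x$d_m1, x$d_a2, x$d_m2, x$d_a1))
  cat(sprintf("  delta = %g, n = %d\n", x$delta, x$n))
  invisible(x)
}

#' Dimensional (physical) parameters
#'
#' Physical parameters of the mussel-algae bed before
#' nondimensionalisation. Defaults are field estimates for an intertidal
#' mussel bed: consumption rate `c` in m^3/g/h, conversion efficiency `e`
#' in g/g, maximum mortality `d_M` in g/g/h, saturation density `k_M` in
#' g/m^2, upper-layer algae concentration `A_up` in g/m^3, exchange rate
#' `rho` per hour, lower-layer height `H` in m, advection speed `V` in
#' m/h, and the four dimensional diffusion coefficients in m^2/h.
#'
#' @param c_,e,d_M,k_M,A_up,rho,H,V,D_M,D_Mbar,D_Abar,D_A See description.
#' @return An object of class `ma_physical`.
#' @examples
#' nondimensionalize(ma_physical(), tau_hours = 260)
#' @export
ma_physical <- function(c_ = 0.1, e = 0.2, d_M = 0.014, k_M = 200,
                        A_up = 1, rho = 100, H = 0.1, V = 0,
                        D_M = 0.0112, D_Mbar = 1.4, D_Abar = 2.1e-5,
                        D_A = 0.014) {
  vals <- c(c_ = c_, e = e, d_M = d_M, k_M = k_M, A_up = A_up, rho = rho,
            H = H, D_M = D_M, D_Mbar = D_Mbar, D_Abar = D_Abar, D_A = D_A)
  if (any(vals <= 0)) stop("all physical parameters except V must be > 0")
  if (V < 0) stop("V must be >= 0")
  structure(as.list(c(vals, V = V)), class = "ma_physical")
}

#' Nondimensionalise physical parameters
#'
#' Converts a dimensional parameter set to the nondimensional reaction
#' parameters, diffusion coefficients and advection number used by the
#' lattice model: `omega = c k_M / H`, `r = c e A_up / d_M`,
#' `alpha = rho / omega`, `gamma = d_M / omega`, `tau = tau_hours d_M`,
#' `d_m1 = D_M / d_M`, `d_m2 = D_Mbar A_up / (d_M k_M)`,
#' `d_a1 = D_Abar k_M / (A_up d_M)`, `d_a2 = D_A / d_M` and
#' `nu = V / d_M`.
#'
#' @param phys An [ma_physical()] object.
#' @param tau_hours Monitoring interval in hours.
#' @return A list with elements `params` (an [ma_params()] without
#'   control), `diffusion` (coefficients only; `delta` and `n` are lattice
#'   choices, not physical quantities), `omega` and `nu`.
#' @export
nondimensionalize <- function(phys, tau_hours) {
  stopifnot(inherits(phys, "ma_physical"), tau_hours > 0)
  omega <- phys$c_ * phys$k_M / phys$H
  r <- phys$c_ * phys$e * phys$A_up / phys$d_M
  alpha <- phys$rho / omega
  gamma <- phys$d_M / omega
  tau <- tau_hours * phys$d_M
  list(
    params = ma_params(alpha = alpha, r = r, gamma = gamma,
                       kp = 0, kd = 0, tau = tau),
    diffusion = c(d_m1 = phys$D_M / phys$d_M,
                  d_m2 = phys$D_Mbar * phys$A_up / (phys$d_M * phys$k_M),
                  d_a1 = phys$D_Abar * phys$k_M / (phys$A_up * phys$d_M),
                  d_a2 = phys$D_A / phys$d_M),
    omega = omega,
    nu = phys$V / phys$d_M
  )
}
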