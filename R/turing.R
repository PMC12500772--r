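#' Eigenvalues of the discrete Laplacian on a periodic lattice
#'
#' For the five-point Laplacian on an `n x n` lattice with periodic
#' boundaries, the eigenvalues indexed by mode `(k, l)` are
#' `lambda_kl = 4 (sin^2((k-1) pi / n) + sin^2((l-1) pi / n))`,
#' all lying in `[0, 8]` with `lambda_11 = 0` (the spatially homogeneous
#' mode).
#'
#' @param n Lattice side length (>= 2).
#' @return An `n x n` matrix with entry `[k, l]` equal to `lambda_kl`.
#' @examples
#' laplacian_eigenvalues(2)
#' @export
laplacian_eigenvalues <- function(n) {
  stopifnot(n >= 2)
  s <- 4 * sin((seq_len(n) - 1) * pi / n)^2
  outer(s, s, "+")
}

# Per-mode 2x2 linearisation entries and largest eigenvalue modulus,
# vectorised over the whole mode grid. Returns a list of matrices.
mode_matrices <- function(params, diff, tau) {
  J <- jacobian(params, tau = tau)
  lkl <- laplacian_eigenvalues(diff$n)
  s <- tau / diff$delta^2 * lkl
  A11 <- J[1, 1] - s * (J[1, 1] * diff$d_m1 + J[1, 2] * diff$d_a1)
  A12 <- J[1, 2] - s * (J[1, 1] * diff$d_m2 + J[1, 2] * diff$d_a2)
  A21 <- J[2, 1] - s * (J[2, 1] * diff$d_m1 + J[2, 2] * diff$d_a1)
  A22 <- J[2, 2] - s * (J[2, 1] * diff$d_m2 + J[2, 2] * diff$d_a2)
  tr <- A11 + A22
  det <- A11 * A22 - A12 * A21
  disc <- tr^2 - 4 * det
  # real branch: larger |root| is (|tr| + sqrt(disc)) / 2;
  # complex branch: |root|^2 = det (necessarily >= 0 there)
  zmax <- ifelse(disc >= 0,
                 (abs(tr) + sqrt(pmax(disc, 0))) / 2,
                 sqrt(pmax(det, 0)))
  zmin <- ifelse(disc >= 0,
                 abs(abs(tr) - sqrt(pmax(disc, 0))) / 2,
                 sqrt(pmax(det, 0)))
  list(lambda = lkl, A11 = A11, A12 = A12, A21 = A21, A22 = A22,
       trace = tr, det = det, disc = disc, zmax = zmax, zmin = zmin)
}

#' Per-mode linearisation of the lattice model
#'
#' Projects the linearised lattice dynamics around the uniform steady
#' state onto each discrete-Laplacian mode `(k, l)`, giving a 2x2 map per
#' mode whose entries combine the homogeneous Jacobian with the
#' diffusion matrix: `A(k, l) = J (I - (tau / delta^2) lambda_kl D)`,
#' `D = ((d_m1, d_m2), (d_a1, d_a2))`.
#'
#' @param params An [ma_params()] object.
#' @param diff An [ma_diffusion()] object.
#' @param tau Monitoring time step; defaults to `params$tau`.
#' @return A tibble with one row per mode: `k`, `l`, `lambda_kl`, the
#'   four entries `A11`-`A22`, and the eigenvalue moduli `mod_max`,
#'   `mod_min`.
#' @export
mode_linearization <- function(params, diff, tau = params$tau) {
  stopifnot(inherits(diff, "ma_diffusion"), !is.null(tau))
  mm <- mode_matrices(params, diff, tau)
  n <- diff$n
  tibble::tibble(
    k = rep(seq_len(n), times = n),
    l = rep(seq_len(n), each = n),
    lambda_kl = as.vector(mm$lambda),
    A11 = as.vector(mm$A11), A12 = as.vector(mm$A12),
    A21 = as.vector(mm$A21), A22 = as.vector(mm$A22),
    mod_max = as.vector(mm$zmax), mod_min = as.vector(mm$zmin)
  )
}

#' Turing instability indicator Z_m
#'
#' `Z(k, l, tau)` is the larger eigenvalue modulus of the mode-(k, l)
#' linearisation, and `Z_m(tau)` its maximum over all modes except the
#' homogeneous one `(1, 1)`. `Z_m > 1` signals Turing instability of the
#' uniform steady state.
#'
#' @inheritParams mode_linearization
#' @return Scalar `Z_m(tau)`.
#' @examples
#' p <- ma_params()
#' d <- ma_diffusion(d_m1 = 0.8, d_a2 = 1, delta = 10)
#' zm(p, d, tau = 3.6)
#' @export
zm <- function(params, diff, tau = params$tau) {
  stopifnot(inherits(diff, "ma_diffusion"), !is.null(tau))
  z <- mode_matrices(params, diff, tau)$zmax
  z[1, 1] <- -Inf   # the homogeneous mode is excluded by definition
  max(z)
}

#' Z_m over a grid of tau values
#'
#' @inheritParams mode_linearization
#' @param tau_grid Increasing vector of tau values.
#' @return Tibble with columns `tau`, `Zm`.
#' @export
zm_curve <- function(params, diff, tau_grid) {
  tibble::tibble(
    tau = tau_grid,
    Zm = vapply(tau_grid, function(t) zm(params, diff, tau = t), numeric(1))
  )
}

# Both determination formulas of the secondary (closed-form) threshold
# reporting path, evaluated at a given tau. The first mixes a trace
# modulus and a product and is reported verbatim for reference only; the
# authoritative threshold is always the direct Z_m = 1 root.
prop3_values <- function(params, diff, tau) {
  mm <- mode_matrices(params, diff, tau)
  v1 <- abs(mm$trace) - mm$A12 * mm$A21
  v2 <- mm$A12 * mm$A21
  v1[1, 1] <- -Inf
  v2[1, 1] <- -Inf
  c(formula1 = max(v1), formula2 = max(v2))
}

#' Turing bifurcation threshold
#'
#' Locates the smallest `tau` with `Z_m(tau) = 1` by bisection over the
#' bracket, identifies the critical mode (the arg-max mode at the
#' threshold) and records the `Z_m` curve. Two closed-form determination
#' quantities are evaluated at the threshold for reference; the reported
#' `tau_prime` is always the direct root.
#'
#' @inheritParams mode_linearization
#' @param bracket Interval searched for the root; default
#'   `c(0.1, 3) * tau_f` with `tau_f` from [flip_thresholds()].
#' @param tol Bisection tolerance.
#' @param curve_points Number of grid points stored in the returned
#'   `Zm_curve`.
#' @return An object of class `ma_turing_report`: `tau_prime` (or `NA`),
#'   `critical_mode`, `critical_lambda`, `Zm_curve` (tibble), `prop3`
#'   and the inputs.
#' @examples
#' p <- ma_params()
#' d <- ma_diffusion(d_m1 = 0.8, d_a2 = 1, delta = 10)
#' turing_threshold(p, d)$tau_prime
#' @export
turing_threshold <- function(params, diff, bracket = NULL, tol = 1e-6,
                             curve_points = 200L) {
  stopifnot(inherits(params, "ma_params"), inherits(diff, "ma_diffusion"))
  if (is.null(bracket)) {
    tf <- flip_thresholds(params)$tau_f
    if (!is.finite(tf)) tf <- 4
    bracket <- c(0.1 * tf, 3 * tf)
  }
  f <- function(tau) zm(params, diff, tau = tau) - 1
  grid <- seq(bracket[1], bracket[2], length.out = 512)
  vals <- vapply(grid, f, numeric(1))
  sc <- which(vals[-1] * vals[-length(vals)] <= 0 & vals[-1] != vals[-length(vals)])
  curve <- tibble::tibble(
    tau = seq(bracket[1], bracket[2], length.out = curve_points),
    Zm = vapply(seq(bracket[1], bracket[2], length.out = curve_points),
                function(t) zm(params, diff, tau = t), numeric(1))
  )
  if (length(sc) == 0) {
    out <- list(tau_prime = NA_real_, critical_mode = c(NA_integer_, NA_integer_),
                critical_lambda = NA_real_, Zm_curve = curve,
                prop3 = c(formula1 = NA_real_, formula2 = NA_real_),
                params = params, diffusion = diff,
                note = "Z_m(tau) - 1 does not change sign on the bracket")
    return(structure(out, class = "ma_turing_report"))
  }
  root <- stats::uniroot(f, c(grid[sc[1]], grid[sc[1] + 1]), tol = tol)$root
  mm <- mode_matrices(params, diff, root)
  z <- mm$zmax
  z[1, 1] <- -Inf
  idx <- arrayInd(which.max(z), dim(z))
  structure(
    list(tau_prime = root,
         critical_mode = c(k = idx[1], l = idx[2]),
         critical_lambda = mm$lambda[idx],
         Zm_curve = curve,
         prop3 = prop3_values(params, diff, root),
         params = params, diffusion = diff, note = NULL),
    class = "ma_turing_report"
  )
}

#' @export
print.ma_turing_report <- function(x, ...) {
  cat("<ma_turing_report>\n")
  if (is.na(x$tau_prime)) {
    cat("  no threshold found:", x$note, "\n")
  } else {
    cat(sprintf("  tau_prime = %.6g at mode (%d, %d), lambda_kl = %.4g\n",
                x$tau_prime, x$critical_mode[1], x$critical_mode[2],
                x$critical_lambda))
  }
  invisible(x)
}

#' Dynamical regime at a given tau
#'
#' Combines the flip threshold of the homogeneous map with the Turing
#' indicator: below `tau_f` with `Z_m <= 1` the uniform steady state is
#' stable (`homogeneous`); `Z_m > 1` below `tau_f` is diffusion-driven
#' (`pure-Turing`) instability; `Z_m > 1` at or above `tau_f` is
#' `flip-Turing` instability. At or above `tau_f` with `Z_m <= 1` the
#' state remains spatially homogeneous (though oscillating in time) and
#' is labelled `homogeneous`.
#'
#' @inheritParams mode_linearization
#' @return One of `"homogeneous"`, `"pure-Turing"`, `"flip-Turing"`.
#' @export
classify_region <- function(params, diff, tau = params$tau) {
  stopifnot(!is.null(tau))
  tf <- flip_thresholds(params)$tau_f
  if (!is.finite(tf)) tf <- Inf
  z <- zm(params, diff, tau = tau)
  if (z <= 1) return("homogeneous")
  if (tau < tf) "pure-Turing" else "flip-Turing"
}

#' Region map over a (tau, diffusion-coefficient) grid
#'
#' Sweeps `tau` against one diffusion coefficient and labels each cell
#' with [classify_region()], reproducing the standard three-region
#' bifurcation diagrams of the lattice model.
#'
#' @param params An [ma_params()] object.
#' @param diff Baseline [ma_diffusion()].
#' @param coef Name of the swept coefficient
#'   (`"d_m1"`, `"d_m2"`, `"d_a1"` or `"d_a2"`).
#' @param coef_values,tau_values Grid vectors.
#' @return Tibble with columns `tau`, the swept coefficient, `region`.
#' @export
region_map <- function(params, diff, coef = "d_a2", coef_values,
                       tau_values) {
  coef <- match.arg(coef, c("d_m1", "d_m2", "d_a1", "d_a2"))
  grid <- expand.grid(tau = tau_values, value = coef_values)
  grid$region <- purrr::map2_chr(grid$tau, grid$value, function(tau, v) {
    d <- diff
    d[[coef]] <- v
    classify_region(params, d, tau = tau)
  })
  out <- tibble::as_tibble(grid)
  names(out)[names(out) == "value"] <- coef
  out
}
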