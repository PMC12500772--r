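#' Bifurcation diagram of the homogeneous map
#'
#' For each `tau` on the grid, iterates the map past the transient and
#' records the attractor samples. Divergent `tau` values are kept as `NA`
#' rows rather than aborting the sweep.
#'
#' @param params An [ma_params()] object (`tau` ignored).
#' @param tau_range Length-2 numeric range.
#' @param resolution Grid step in `tau`.
#' @param transient,record Per-`tau` orbit settings.
#' @param start Start state; default `fixed_point + 0.01`.
#' @return An `ma_bifurcation` tibble with columns `tau`, `m`, `a`
#'   (`record` rows per `tau`).
#' @examples
#' bd <- bifurcation_diagram(ma_params(), c(3.5, 4.5), 0.1,
#'                           transient = 2000, record = 32)
#' @export
bifurcation_diagram <- function(params, tau_range, resolution,
                                transient = 2000L, record = 128L,
                                start = NULL) {
  taus <- seq(tau_range[1], tau_range[2], by = resolution)
  rows <- purrr::map(taus, function(tau) {
    orb <- tryCatch(
      iterate_map(with_tau(params, tau), start = start,
                  transient = transient, record = record,
                  max_period = 1L),
      error = function(e) NULL
    )
    if (is.null(orb)) {
      tibble::tibble(tau = tau, m = NA_real_, a = rep(NA_real_, record))
    } else {
      tibble::tibble(tau = tau, m = orb$m, a = orb$a)
    }
  })
  out <- dplyr::bind_rows(rows)
  structure(out, record = as.integer(record),
            class = c("ma_bifurcation", class(out)))
}

# number of distinct attractor branches at one tau of a diagram
branch_count <- function(diagram, tau, cluster_tol = 1e-4) {
  a <- diagram$a[abs(diagram$tau - tau) < 1e-12]
  a <- a[!is.na(a)]
  if (length(a) == 0) return(NA_integer_)
  gap_clusters(a, cluster_tol)
}

gap_clusters <- function(x, tol) {
  x <- sort(x)
  if (length(x) == 1) return(1L)
  sum(diff(x) > tol) + 1L
}

#' Maximum-Lyapunov sweep and chaos onset
#'
#' Estimates the maximum Lyapunov exponent on a `tau` grid and locates
#' the chaos onset: the first grid `tau` whose exponent is positive and
#' stays positive at the next grid point (sustained rule).
#'
#' @inheritParams bifurcation_diagram
#' @param resolution Grid step (<= 0.01 for onset detection to be
#'   meaningful).
#' @param transient,steps Lyapunov estimator settings.
#' @return An `ma_lyapunov_curve` tibble with columns `tau`, `mle`, and
#'   attribute `onset` (`NA` when no sustained positive exponent occurs).
#' @examples
#' lc <- chaos_onset(ma_params(), c(4.6, 4.8), 0.01,
#'                   transient = 500, steps = 2000)
#' attr(lc, "onset")
#' @export
chaos_onset <- function(params, tau_range, resolution = 0.005,
                        transient = 1000L, steps = 10000L, start = NULL) {
  taus <- seq(tau_range[1], tau_range[2], by = resolution)
  mle <- vapply(taus, function(tau) {
    tryCatch(max_lyapunov(with_tau(params, tau), start = start,
                          transient = transient, steps = steps),
             error = function(e) NA_real_)
  }, numeric(1))
  pos <- !is.na(mle) & mle > 0
  sustained <- pos & c(pos[-1], FALSE)
  onset <- if (any(sustained)) taus[which(sustained)[1]] else NA_real_
  out <- tibble::tibble(tau = taus, mle = mle)
  structure(out, onset = onset,
            class = c("ma_lyapunov_curve", class(out)))
}

#' Count the distinct states of a lattice pattern
#'
#' Greedily clusters the site values of a field: after sorting, a new
#' cluster opens wherever the gap between consecutive values exceeds
#' `cluster_tol`. A pattern is `uniform` when its spatial standard
#' deviation is below `uniformity_threshold` (one cluster), `disordered`
#' when the cluster count exceeds `disorder_cutoff`, and `k-state`
#' otherwise.
#'
#' @param field Numeric matrix (typically the algae field of a
#'   snapshot).
#' @param cluster_tol Gap threshold separating states (density units).
#' @param uniformity_threshold Spatial-sd threshold for the uniform
#'   label.
#' @param disorder_cutoff State count beyond which the pattern is
#'   labelled disordered.
#' @return A one-row tibble: `state_count`, `uniformity`, `label`.
#' @examples
#' count_states(matrix(0.4286, 10, 10))
#' @export
count_states <- function(field, cluster_tol = 0.02,
                         uniformity_threshold = 1e-4,
                         disorder_cutoff = 16L) {
  stopifnot(all(is.finite(field)))
  unif <- stats::sd(field)
  k <- gap_clusters(as.vector(field), cluster_tol)
  label <- if (unif < uniformity_threshold && k == 1L) {
    "uniform"
  } else if (k > disorder_cutoff) {
    "disordered"
  } else {
    "k-state"
  }
  tibble::tibble(state_count = k, uniformity = unif, label = label)
}

#' Threshold response to a control gain
#'
#' Sweeps one control gain and recomputes the flip threshold `tau_f` or
#' the Turing threshold `tau_prime` at each value.
#'
#' @param params Baseline [ma_params()].
#' @param which `"flip"` or `"turing"`.
#' @param sweep_param `"kp"` or `"kd"`.
#' @param values Grid of gain values.
#' @param diff An [ma_diffusion()] (required for `which = "turing"`).
#' @return Tibble with columns `value` and `threshold` (`NA` where no
#'   threshold exists), plus attribute `direction` summarising
#'   monotonicity (`"increasing"`, `"decreasing"` or `"mixed"`).
#' @export
threshold_sweep <- function(params, which = c("flip", "turing"),
                            sweep_param = c("kp", "kd"), values,
                            diff = NULL) {
  which <- match.arg(which)
  sweep_param <- match.arg(sweep_param)
  if (which == "turing") stopifnot(inherits(diff, "ma_diffusion"))
  th <- vapply(values, function(v) {
    p <- params
    p[[sweep_param]] <- v
    out <- tryCatch({
      if (which == "flip") {
        flip_thresholds(p)$tau_f
      } else {
        turing_threshold(p, diff)$tau_prime
      }
    }, error = function(e) NA_real_)
    if (is.null(out)) NA_real_ else out
  }, numeric(1))
  thf <- th[is.finite(th)]
  d <- thf[-1] - thf[-length(thf)]
  direction <- if (length(d) == 0) {
    "mixed"
  } else if (all(d > 0)) {
    "increasing"
  } else if (all(d < 0)) {
    "decreasing"
  } else {
    "mixed"
  }
  structure(tibble::tibble(value = values, threshold = th),
            direction = direction)
}

#' Pattern response to a control-gain sweep
#'
#' Simulates the lattice at each value of one control gain (same seed
#' and configuration throughout) and summarises the final algae pattern
#' with [count_states()]. The sweep is evaluated in the order of
#' `values`; the attribute `first_uniform` records the first gain value
#' whose pattern is uniform. By default each run is cut short once the
#' fields become numerically uniform (spatial sd below `uniform_tol`),
#' since an exactly uniform lattice stays uniform.
#'
#' @param params Baseline [ma_params()] with `tau` set.
#' @param diff An [ma_diffusion()].
#' @param config An [lattice_config()].
#' @param sweep_param `"kp"` or `"kd"`.
#' @param values Gain values in sweep order.
#' @param cluster_tol,uniformity_threshold Passed to [count_states()].
#' @param uniform_tol Early-uniform tolerance for [simulate_lattice()].
#' @param stop_at_uniform Stop sweeping once a uniform pattern is found.
#' @return Tibble with columns `value`, `state_count`, `uniformity`,
#'   `label`; attribute `first_uniform`.
#' @export
pattern_control_sweep <- function(params, diff, config = lattice_config(),
                                  sweep_param = c("kp", "kd"), values,
                                  cluster_tol = 0.02,
                                  uniformity_threshold = 1e-4,
                                  uniform_tol = 1e-14,
                                  stop_at_uniform = TRUE) {
  sweep_param <- match.arg(sweep_param)
  rows <- list()
  first_uniform <- NA_real_
  for (v in values) {
    p <- params
    p[[sweep_param]] <- v
    row <- tryCatch({
      traj <- simulate_lattice(p, diff, config, uniform_tol = uniform_tol)
      cs <- count_states(traj$state$a, cluster_tol = cluster_tol,
                         uniformity_threshold = uniformity_threshold)
      dplyr::mutate(cs, value = v, .before = 1)
    }, error = function(e) {
      tibble::tibble(value = v, state_count = NA_integer_,
                     uniformity = NA_real_, label = "divergent")
    })
    rows[[length(rows) + 1]] <- row
    if (is.na(first_uniform) && identical(row$label, "uniform")) {
      first_uniform <- v
      if (stop_at_uniform) break
    }
  }
  structure(dplyr::bind_rows(rows), first_uniform = first_uniform)
}
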