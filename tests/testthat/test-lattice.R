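test_that("discrete Laplacian wraps periodically and telescopes to zero", {
  expect_equal(discrete_laplacian(matrix(0.7, 5, 5)), matrix(0, 5, 5))

  # 2x2 impulse: every neighbour direction wraps onto the opposite cell
  f <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(discrete_laplacian(f),
               matrix(c(-4, 2, 2, 0), 2, 2))

  withr::with_seed(606, {
    g <- matrix(rnorm(49), 7, 7)
    expect_equal(sum(discrete_laplacian(g)), 0, tolerance = 1e-12)
  })
})

test_that("dispersal stage conserves mass and fixes uniform states", {
  p <- base_params(tau = 3.6)
  d <- ma_diffusion(0.8, 0.3, 0.2, 1, delta = 10, n = 8)
  withr::with_seed(707, {
    st <- lattice_state(matrix(runif(64, 0.5, 0.9), 8, 8),
                        matrix(runif(64, 0.3, 0.5), 8, 8))
  })
  out <- diffusion_stage(st, p, d)
  expect_equal(sum(out$m), sum(st$m), tolerance = 1e-12)
  expect_equal(sum(out$a), sum(st$a), tolerance = 1e-12)

  uni <- lattice_state(matrix(0.7, 8, 8), matrix(0.4, 8, 8))
  out_u <- diffusion_stage(uni, p, d)
  expect_equal(out_u$m, uni$m)
  expect_equal(out_u$a, uni$a)

  d0 <- ma_diffusion(0, 0, 0, 0, delta = 10, n = 8)
  out0 <- diffusion_stage(st, p, d0)
  expect_identical(out0$m, st$m)
})

test_that("reaction stage applies the homogeneous update sitewise", {
  p <- base_params(tau = 3.6)
  uni <- lattice_state(matrix(0.7, 6, 6), matrix(0.45, 6, 6))
  out <- reaction_stage(uni, p)
  ref <- step_homogeneous(c(m = 0.7, a = 0.45), p)
  expect_equal(out$m, matrix(ref[["m"]], 6, 6))
  expect_equal(out$a, matrix(ref[["a"]], 6, 6))

  fp <- fixed_point(p)
  at_fp <- lattice_state(matrix(fp[["m"]], 6, 6), matrix(fp[["a"]], 6, 6))
  out_fp <- reaction_stage(at_fp, p)
  expect_equal(out_fp$m, at_fp$m, tolerance = 1e-14)
  expect_equal(out_fp$a, at_fp$a, tolerance = 1e-14)
})

test_that("an exactly uniform lattice reproduces the homogeneous orbit", {
  p <- base_params(tau = 4.2)  # period-2 regime
  d <- case1_diffusion(n = 16)
  cfg <- lattice_config(n = 16, steps = 60, transient = 0,
                        perturb_amplitude = 0, record_stride = 1)
  traj <- simulate_lattice(p, d, cfg)
  expect_equal(length(traj$snapshots), 61)
  expect_true(all(traj$sd_trace$sd_a < 1e-12))

  start <- fixed_point(p)
  orb <- iterate_map(p, start = start, transient = 0, record = 60,
                     max_period = 1L)
  per_step_err <- vapply(seq_len(60), function(t) {
    snap <- traj$snapshots[[t + 1]]
    max(abs(snap$a - orb$a[t]), abs(snap$m - orb$m[t]))
  }, numeric(1))
  expect_true(all(per_step_err < 1e-12 * seq_len(60)))
})

test_that("one full lattice step commutes with cyclic shifts", {
  p <- base_params(tau = 3.8)
  d <- ma_diffusion(0.8, 0.2, 0.1, 1, delta = 10, n = 9)
  withr::with_seed(808, {
    st <- lattice_state(matrix(runif(81, 0.5, 0.9), 9, 9),
                        matrix(runif(81, 0.3, 0.5), 9, 9))
  })
  shift <- function(mat, di, dj) {
    n <- nrow(mat)
    mat[((seq_len(n) - 1 + di) %% n) + 1, ((seq_len(n) - 1 + dj) %% n) + 1]
  }
  step_lattice <- function(s) reaction_stage(diffusion_stage(s, p, d), p)
  out1 <- step_lattice(st)
  st_shifted <- lattice_state(shift(st$m, 3, 5), shift(st$a, 3, 5))
  out2 <- step_lattice(st_shifted)
  expect_equal(out2$m, shift(out1$m, 3, 5), tolerance = 1e-14)
  expect_equal(out2$a, shift(out1$a, 3, 5), tolerance = 1e-14)
})

test_that("case-1 simulations reproduce uniform and patterned endpoints", {
  p <- base_params(tau = 3.6)
  cfg <- lattice_config(seed = 42)

  # d_a2 = 1: below both thresholds, perturbations decay to uniformity
  traj_u <- simulate_lattice(p, case1_diffusion(d_a2 = 1), cfg)
  expect_lt(dplyr::last(traj_u$sd_trace$sd_a), 1e-6)

  # d_a2 = 0.4: pure-Turing regime, a stationary pattern persists
  traj_p <- simulate_lattice(p, case1_diffusion(d_a2 = 0.4), cfg)
  expect_gt(dplyr::last(traj_p$sd_trace$sd_a), 1e-3)
  late <- traj_p$sd_trace$sd_a[4500:5000]
  expect_lt(stats::sd(late) / mean(late), 0.05)  # stationary plateau
})

test_that("spatial variance decays below and grows above the threshold", {
  tr <- turing_threshold(base_params(), case1_diffusion())
  cfg <- lattice_config(seed = 7, steps = 2000, transient = 1500)
  below <- simulate_lattice(with_tau_set(base_params(), tr$tau_prime - 0.05),
                            case1_diffusion(), cfg)
  above <- simulate_lattice(with_tau_set(base_params(), tr$tau_prime + 0.05),
                            case1_diffusion(), cfg)
  expect_lt(dplyr::last(below$sd_trace$sd_a), 1e-6)
  expect_gt(dplyr::last(above$sd_trace$sd_a),
            10 * above$sd_trace$sd_a[1])
})

test_that("single-mode perturbations decay at the per-mode rate", {
  # seed one Laplacian eigenvector and compare the measured decay of its
  # amplitude with the linear prediction Z(k, l, tau)
  p <- base_params(tau = 3.0)
  n <- 32L
  d <- case1_diffusion(n = n)
  cases <- list(c(2L, 1L), c(4L, 3L))
  for (kl in cases) {
    k <- kl[1]; l <- kl[2]
    fp <- fixed_point(p)
    xi <- outer(cos(2 * pi * (k - 1) * (seq_len(n) - 1) / n),
                cos(2 * pi * (l - 1) * (seq_len(n) - 1) / n))
    amp0 <- 1e-6
    init <- lattice_state(matrix(fp[["m"]], n, n) + amp0 * xi,
                          matrix(fp[["a"]], n, n) + amp0 * xi)
    cfg <- lattice_config(n = n, steps = 40, transient = 0,
                          perturb_amplitude = 0, record_stride = 1)
    traj <- simulate_lattice(p, d, cfg, init = init)
    proj <- vapply(traj$snapshots, function(s) {
      sum((s$a - mean(s$a)) * xi) / sum(xi^2)
    }, numeric(1))
    # average per-step contraction over the last 20 steps
    rate <- exp(mean(diff(log(abs(proj[21:41])))))
    ml <- mode_linearization(p, d)
    zkl <- ml$mod_max[ml$k == k & ml$l == l]
    expect_equal(rate, zkl, tolerance = 0.05,
                 label = sprintf("decay rate of mode (%d, %d)", k, l))
  }
})

test_that("clamping reports its interventions and divergence is named", {
  p <- base_params(tau = 3.6)
  d <- case1_diffusion(n = 8)
  cfg <- lattice_config(n = 8, steps = 10, transient = 0,
                        perturb_amplitude = 0, record_stride = 5)
  traj <- simulate_lattice(p, d, cfg, clamp = TRUE)
  expect_identical(traj$clamp_count, 0)  # defaults never trigger it

  cfg_div <- lattice_config(n = 8, steps = 60, transient = 0,
                            perturb_amplitude = 0.01, seed = 5,
                            record_stride = 30)
  expect_error(
    simulate_lattice(with_tau_set(p, 30), d, cfg_div),
    "diverged at step"
  )
})
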