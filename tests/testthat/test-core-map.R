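test_that("fixed point matches the closed form and is control-invariant", {
  p <- base_params()
  fp <- fixed_point(p)
  expect_equal(unname(fp), c(2 / 3, 3 / 7), tolerance = 1e-12)

  # alpha = 0.5, r = 1.8 solves the fixed-point equations at (4, 1/9)
  fp2 <- fixed_point(ma_params(alpha = 0.5, r = 1.8))
  expect_equal(unname(fp2), c(4, 1 / 9), tolerance = 1e-12)

  # the PD feedback vanishes at a*, so gains do not move the fixed point
  expect_identical(fixed_point(base_params(kp = -0.1, kd = -0.5)), fp)

  expect_error(fixed_point(ma_params(alpha = 0.9, r = 1.4)),
               "no positive coexistence")
  expect_error(fixed_point(ma_params(alpha = 0.5, r = 2)), "degenerate")
})

test_that("fixed point is invariant under the map for random C2 sets", {
  withr::with_seed(101, {
    for (i in 1:200) {
      p <- random_c2_params(tau = runif(1, 0.5, 6))
      fp <- fixed_point(p)
      expect_equal(step_homogeneous(fp, p), fp, tolerance = 1e-12)
    }
  })
})

test_that("one homogeneous step matches hand evaluation and reductions", {
  p <- base_params(tau = 3.6)
  out <- step_homogeneous(c(m = 0.7, a = 0.45), p)
  expect_equal(unname(out), c(0.805247058823529, 0.33), tolerance = 1e-12)

  # with kp = kd = 0 the controlled update is the uncontrolled one:
  # 1 / (1 - kd) = 1 and the kp term is absent
  pc <- base_params(tau = 3.6, kp = 0, kd = 0)
  expect_identical(step_homogeneous(c(m = 0.7, a = 0.45), pc), out)
})

test_that("closed-form Jacobian matches printed values and finite differences", {
  p <- base_params(tau = 1)
  J <- jacobian(p)
  expect_equal(J, matrix(c(1.24, 0.93333333, -0.35714286, 0.02777778),
                         2, 2, byrow = TRUE), tolerance = 1e-7)
  expect_equal(jacobian(p, tau = 0), diag(2))

  fd_jacobian <- function(p) {
    fp <- fixed_point(p)
    h <- 1e-6
    cbind(
      (step_homogeneous(fp + c(h, 0), p) - step_homogeneous(fp - c(h, 0), p)),
      (step_homogeneous(fp + c(0, h), p) - step_homogeneous(fp - c(0, h), p))
    ) / (2 * h)
  }
  withr::with_seed(202, {
    for (i in 1:50) {
      p <- random_c2_params(tau = runif(1, 0.5, 6))
      expect_equal(jacobian(p), unname(fd_jacobian(p)), tolerance = 1e-5)
    }
  })
})

test_that("stability classification follows the eigenvalues", {
  expect_identical(classify_fixed_point(base_params(tau = 3.6))$label,
                   "stable-node")
  rep5 <- classify_fixed_point(base_params(tau = 5))
  expect_identical(rep5$label, "saddle")
  expect_equal(sort(Re(rep5$eigenvalues)), c(-1.753, 0.092),
               tolerance = 1e-2)
  rep1 <- classify_fixed_point(base_params(tau = 1))
  expect_identical(rep1$label, "stable-node")
  expect_equal(sort(Re(rep1$eigenvalues)), c(0.449, 0.818), tolerance = 1e-2)

  # exactly at the flip threshold one eigenvalue sits on the unit circle
  tf <- flip_thresholds(base_params())$tau_f
  expect_identical(classify_fixed_point(base_params(tau = tf))$label,
                   "non-hyperbolic")

  # trace / det consistency with the eigenvalues
  ev <- rep5$eigenvalues
  expect_equal(Re(sum(ev)), rep5$trace, tolerance = 1e-10)
  expect_equal(Re(prod(ev)), rep5$det, tolerance = 1e-10)
})

test_that("condition matching agrees with the eigenvalue label", {
  withr::with_seed(303, {
    hits <- 0
    for (i in 1:300) {
      p <- random_c2_params(tau = runif(1, 0.2, 12))
      rep <- tryCatch(classify_fixed_point(p), error = function(e) NULL)
      if (is.null(rep) || rep$matched_condition == "none") next
      hits <- hits + 1
      expected <- switch(substr(rep$matched_condition, 1, 3),
                         "SD1" = , "SD2" = , "SD3" = , "SD4" = "saddle",
                         "SN1" = , "SN2" = , "SN3" = "stable-node",
                         "SDN" = "stable-degenerate-node")
      expect_identical(rep$label, expected,
                       label = sprintf("condition %s at i=%d",
                                       rep$matched_condition, i))
    }
    expect_gt(hits, 20)  # the sweep actually exercises the blocks
  })
})

test_that("orbit periods follow the period-doubling cascade", {
  for (case in list(list(4.2, 2L), list(5.15, 10L))) {
    orb <- iterate_map(base_params(tau = case[[1]]))
    expect_identical(attr(orb, "period"), case[[2]])
  }
  # a stable fixed point started exactly there stays put
  p <- base_params(tau = 3.6)
  orb <- iterate_map(p, start = fixed_point(p), transient = 100, record = 130)
  expect_true(all(abs(orb$a - fixed_point(p)[["a"]]) < 1e-12))
  expect_identical(attr(orb, "period"), 1L)
})

test_that("period detection handles constants, short input and chaos", {
  const <- matrix(rep(c(0.5, 0.4), each = 20), ncol = 2)
  expect_identical(detect_period(const, max_period = 10L), 1L)
  expect_error(detect_period(const[1:10, ], max_period = 10L), "at least")
  orb <- iterate_map(base_params(tau = 5.06))
  expect_identical(attr(orb, "period"), NA_integer_)
})

test_that("divergent orbits raise an error naming the step", {
  expect_error(iterate_map(base_params(tau = 50), transient = 1000,
                           record = 10),
               "diverged.*step")
})

test_that("Lyapunov exponent matches closed forms on simple attractors", {
  # stable fixed point: exponent is log of the largest eigenvalue modulus
  p <- base_params(tau = 3.6)
  ev <- eigen(jacobian(p), only.values = TRUE)$values
  expect_lt(abs(max_lyapunov(p) - log(max(Mod(ev)))), 1e-3)

  # period-2 orbit: half the log-modulus of the product of the two
  # Jacobians along the orbit (independent closed form)
  p2 <- base_params(tau = 4.2)
  orb <- iterate_map(p2, transient = 10000, record = 130)
  st <- as.matrix(orb[1:2, c("m", "a")])
  J2 <- musselcml:::jacobian_at(st[2, ], p2) %*%
    musselcml:::jacobian_at(st[1, ], p2)
  expected <- log(max(Mod(eigen(J2, only.values = TRUE)$values))) / 2
  expect_lt(abs(max_lyapunov(p2) - expected), 1e-3)
  expect_lt(max_lyapunov(p2), 0)

  # chaos
  expect_gt(max_lyapunov(base_params(tau = 5.06)), 0)
})

test_that("nondimensionalisation reproduces the tabulated scales", {
  nd <- nondimensionalize(ma_physical(), tau_hours = 260)
  expect_equal(nd$omega, 200)
  expect_equal(nd$params$r, 1 / 0.7, tolerance = 1e-12)  # prints as ~1.4
  expect_equal(nd$params$alpha, 0.5)
  expect_equal(nd$params$gamma, 7e-5)
  expect_equal(nd$params$tau, 3.64)
  expect_equal(unname(nd$diffusion["d_m1"]), 0.8)
  expect_equal(nd$nu, 0)

  # zero diffusivities map to zero nondimensional coefficients
  ph <- ma_physical(D_M = 1e-300, D_Mbar = 1e-300, D_Abar = 1e-300,
                    D_A = 1e-300)
  expect_true(all(nondimensionalize(ph, 260)$diffusion < 1e-290))
})
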