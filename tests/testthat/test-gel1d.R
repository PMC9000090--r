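test_that("implicit velocity solve reproduces the closed-form response", {
  gp <- gel_params(N = 128)
  L <- gp$L_over_lam * gp$lam
  x <- (1:128 - 0.5) * L / 128
  kmode <- 2 * pi * 3 / L
  Famp <- 0.7
  force <- Famp * sin(kmode * x)
  v <- numeric(128)
  for (i in 1:3000) v <- velocity_step_1d(v, NULL, gp, dt = 0.5, L, force)
  # steady state of tau v' = -v + lam^2 v'' + F sin(kx):
  # v = F sin(kx) / (1 + lam^2 k^2)
  expect_equal(v, Famp * sin(kmode * x) / (1 + gp$lam^2 * kmode^2),
               tolerance = 1e-12)
})

test_that("uniform actomyosin produces no flow", {
  gp <- gel_params(N = 64)
  v <- velocity_step_1d(numeric(64), rep(0.7, 64), gp, dt = 0.5)
  expect_equal(v, numeric(64), tolerance = 1e-14)
})

test_that("an actomyosin bump drives convergent antisymmetric flow", {
  gp <- gel_params(N = 128)
  L <- gp$L_over_lam * gp$lam
  x <- (1:128 - 0.5) * L / 128
  m <- 0.1 + 0.8 * exp(-((x - L / 2) / 4)^2)
  v <- numeric(128)
  for (i in 1:2000) v <- velocity_step_1d(v, m, gp, dt = 0.5)
  # antisymmetric about the bump and pointing inward (contractile)
  expect_equal(v, -rev(v), tolerance = 1e-10)
  left <- x < L / 2 - 2 & x > L / 2 - 20
  expect_true(all(v[left] > 0))          # flow toward the bump from the left
})

test_that("transport is an identity without flow or diffusion", {
  c0 <- runif(64, 0, 2)
  expect_equal(transport_step_1d(c0, numeric(64), 0, 0.1, L = 10), c0)
})

test_that("transport conserves mass to machine precision", {
  set.seed(42)
  L <- 100
  c0 <- runif(128, 0.1, 2)
  v <- 0.3 * sin(2 * pi * (1:128) / 128) + 0.1
  c1 <- c0
  for (i in 1:1000)
    c1 <- transport_step_1d(c1, v, D = 0.1, dt = 0.5, L = L)
  expect_equal(mean(c1), mean(c0), tolerance = 1e-10)
})

test_that("uniform advection translates a bump at the exact speed", {
  L <- 100; N <- 200
  x <- (1:N - 0.5) * L / N
  c0 <- exp(-((x - 30) / 5)^2)
  v0 <- 0.5
  c1 <- c0
  steps <- 400; dt <- 0.2
  for (i in 1:steps)
    c1 <- transport_step_1d(c1, rep(v0, N), D = 0, dt = dt, L = L)
  shift_exact <- v0 * steps * dt                  # 40 um
  # centre of mass moves at exactly v0 (conservative scheme)
  com <- function(c) sum(x * c) / sum(c)
  expect_equal(com(c1) - com(c0), shift_exact, tolerance = 1e-6)
  # shape close to the exact translate, limited numerical diffusion
  c_exact <- exp(-((x - 70) / 5)^2)
  expect_lt(sqrt(mean((c1 - c_exact)^2)) / max(c_exact), 0.1)
})

test_that("without active stress the uniform state follows the reaction ODE", {
  p <- chem_params(S = 0.02)
  gp <- gel_params(sigma_prime = 0, N = 64)
  L <- gp$L_over_lam * gp$lam
  init <- field1d(r = rep(0.3, 64), m = rep(0.3, 64), L = L)
  ky <- sim1d_q(init = init, p = p, gp = gp, t_end = 150, dt_max = 0.02)
  ref <- deSolve::ode(y = c(r = 0.3, m = 0.3), times = ky$times,
                      func = function(t, y, parms)
                        list(c(rr_rate(y[1], y[2], p),
                               rm_rate(y[1], y[2], p))),
                      parms = NULL, method = "ode45")
  expect_equal(rowMeans(ky$r), unname(ref[, "r"]), tolerance = 0.02)
  expect_equal(rowMeans(ky$m), unname(ref[, "m"]), tolerance = 0.02)
  # and stays spatially uniform
  expect_lt(max(apply(ky$m, 1, sd)), 1e-10)
})

test_that("fast-diffusing activator forms no Turing pattern", {
  # without mechanics, D_r >> D_m keeps the fields homogeneous
  p <- chem_params(S = 0.01)
  gp <- gel_params(sigma_prime = 0, D_r = 0.1, D_m = 0.01, N = 100)
  ky <- sim1d_q(p = p, gp = gp, t_end = 500, seed = 4)
  final_cv <- sd(ky$m[nrow(ky$m), ]) / mean(ky$m[nrow(ky$m), ])
  expect_lt(final_cv, 1e-3)
})

test_that("high contractility with no stimulus sustains a stationary peak", {
  p <- chem_params(S = 0)
  gp <- gel_params(sigma_prime = 80, N = 150)
  L <- gp$L_over_lam * gp$lam
  x <- (1:150 - 0.5) * L / 150
  bump <- 0.8 * exp(-((x - L / 2) / 5)^2)
  init <- field1d(r = bump, m = p$S_m / p$k_d + bump, L = L)
  ky <- sim1d_q(init = init, p = p, gp = gp, t_end = 600)
  cl <- classify_spatial(ky)
  expect_equal(cl$label, "localized-contraction")
  # the peak stays pinned at the seeding site
  mlast <- ky$m[nrow(ky$m), ]; rlast <- ky$r[nrow(ky$r), ]
  ipk <- which.max(mlast)
  expect_equal(ipk, 75, tolerance = 3)
  expect_gt(max(mlast), 5 * p$S_m / p$k_d)
  # RhoA localizes on the flanks of the actomyosin peak, not on top of it
  wrap <- function(i) (i - 1) %% 150 + 1
  expect_gt(max(rlast[wrap(ipk + (3:10))]), rlast[ipk])
  expect_gt(max(rlast[wrap(ipk - (3:10))]), rlast[ipk])
})

test_that("actomyosin advection is required for pattern formation", {
  p <- chem_params(S = 0)
  gp <- gel_params(sigma_prime = 100, N = 100)
  ky <- sim1d_q(p = p, gp = gp, t_end = 500, seed = 2, r_seed = 0.08,
                advect_m = FALSE)
  mlast <- ky$m[nrow(ky$m), ]
  expect_lt(sd(mlast) / mean(mlast), 0.02)
})

test_that("nearby contractile peaks attract and merge", {
  p <- chem_params(S = 0)
  gp <- gel_params(sigma_prime = 80, N = 150)
  L <- gp$L_over_lam * gp$lam
  x <- (1:150 - 0.5) * L / 150
  sep <- 10                                        # < lambda = 14.3 um
  bump <- function(x0) 0.7 * exp(-((x - x0) / 3)^2)
  init <- field1d(r = bump(L / 2 - sep / 2) + bump(L / 2 + sep / 2),
                  m = p$S_m / p$k_d + bump(L / 2 - sep / 2) +
                      bump(L / 2 + sep / 2), L = L)
  ky <- sim1d_q(init = init, p = p, gp = gp, t_end = 400)
  mlast <- ky$m[nrow(ky$m), ]
  peaks <- cortexgel:::find_peaks_prominent(mlast, 0.2 * diff(range(mlast)))
  expect_equal(length(peaks), 1)
})

test_that("spatial classifier labels manufactured kymographs correctly", {
  N <- 100; L <- 143; t <- 0:399
  x <- (1:N - 0.5) * L / N
  # stationary localized peak
  m_loc <- outer(rep(1, 400), 0.1 + exp(-((x - 70) / 5)^2))
  expect_equal(classify_spatial(fake_kymo(m_loc, t, L))$label,
               "localized-contraction")
  # coherently travelling wave
  m_tw <- 0.5 + 0.3 * cos(outer(t * 0.05, rep(1, N)) -
                          outer(rep(1, 400), 2 * pi * 3 * x / L))
  expect_equal(classify_spatial(fake_kymo(m_tw, t, L))$label,
               "propagating-waves")
  # uniform global oscillation
  m_osc <- outer(0.5 + 0.3 * sin(t / 8), rep(1, N))
  expect_equal(classify_spatial(fake_kymo(m_osc, t, L))$label, "oscillatory")
  # uniform settled high state
  m_hi <- outer(rep(1.2, 400), rep(1, N))
  expect_equal(classify_spatial(fake_kymo(m_hi, t, L))$label,
               "homogeneous-contractile")
})

test_that("memory correlation follows its conventions", {
  N <- 100; L <- 143
  stim <- stimulus_boxcar(S_in = 0.03, x0 = 60, x1 = 80, t_on = 0,
                          t_off = 100)
  x <- (1:N - 0.5) * L / N
  ind <- as.numeric(x >= 60 & x <= 80)
  ky <- fake_kymo(outer(rep(1, 200), 0.2 + 0.5 * ind), 0:199, L)
  expect_equal(memory_correlation(ky, stim), 1)
  ky2 <- fake_kymo(matrix(0.4, 200, N), 0:199, L)
  expect_equal(memory_correlation(ky2, stim), 0)
})

test_that("spatial mean RhoA equals the trapezoidal mean", {
  ky <- fake_kymo(matrix(rep(runif(64, 0, 2), each = 10), nrow = 10), 0:9,
                  L = 50)
  # uniform periodic grid: trapezoid rule over the circle = plain mean
  r_row <- ky$r[5, ]
  trap <- (sum(r_row) / length(r_row))
  expect_equal(mean_rho(ky, 4), trap)
  ky$r[] <- 0.37
  expect_equal(mean_rho(ky, 2), 0.37)
})

test_that("an unstimulated activation protocol leaves the rest state", {
  gp <- gel_params(sigma_prime = 50, N = 100)
  res <- local_activation_experiment(gp, S_in = 0, t_off = 50, t_end = 200)
  expect_equal(res$label, "none")
  expect_lt(max(res$kymo$r), 1e-6)
})
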