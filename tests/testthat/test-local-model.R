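test_that("the mechanochemical steady state zeroes all derivatives", {
  p <- chem_params(S = 0.025)
  mp <- local_mech_params()
  fp <- find_fixed_points(p)[1, ]
  u_eq <- -mp$sigma_over_E * fp$m / (mp$m0 + fp$m)
  d <- local_rhs(c(fp$r, fp$m, u_eq), p, mp)
  expect_equal(d, c(0, 0, 0), tolerance = 1e-9)
})

test_that("with mechanics off the model reduces to pure kinetics", {
  p <- chem_params(S = 0.01)
  mp <- local_mech_params(sigma_over_E = 0)
  st <- c(0.4, 0.7, 0)
  d <- local_rhs(st, p, mp)
  expect_equal(d[3], 0)
  expect_equal(d[1], rr_rate(0.4, 0.7, p))
  expect_equal(d[2], rm_rate(0.4, 0.7, p))
})

test_that("right-hand side matches an independent re-evaluation", {
  p <- chem_params(S = 0.013)
  mp <- local_mech_params(sigma_over_E = 0.3, tau_local = 4, m0 = 0.8)
  for (st in list(c(0.2, 0.1, -0.05), c(1.1, 0.9, -0.15), c(0.01, 2, 0))) {
    r <- st[1]; m <- st[2]; u <- st[3]
    du <- (-0.3 * m / (0.8 + m) - u) / 4
    dr <- (0.013 + 0.1609 * r / (0.3833 + r) - 0.1787 * m * r / (0.01 + r)) -
      r * du / (1 + u)
    dm <- (0.0076 + 0.1408 * r^2 - 0.0828 * m) - m * du / (1 + u)
    expect_equal(local_rhs(st, p, mp), c(dr, dm, du), tolerance = 1e-12)
  }
  expect_error(local_rhs(c(1, 1, -1.2), p, mp), "breakdown")
})

test_that("pure dilution conserves c * (1 + u) along trajectories", {
  p <- chem_params()
  mp <- local_mech_params(sigma_over_E = 0.4)
  tr <- simulate_local(init = c(1, 2, 0), p = p, mp = mp, t_end = 200,
                       reactions = FALSE)
  expect_equal(tr$r * (1 + tr$u), rep(1, nrow(tr)), tolerance = 1e-7)
  expect_equal(tr$m * (1 + tr$u), rep(2, nrow(tr)), tolerance = 1e-7)
})

test_that("zero active stress reproduces the reaction-only ODE", {
  p <- chem_params(S = 0.02)
  mp <- local_mech_params(sigma_over_E = 0)
  tr <- simulate_local(init = c(0.1, 0.1, 0), p = p, mp = mp, t_end = 300)
  # independent two-variable reaction integration
  ref <- deSolve::ode(y = c(r = 0.1, m = 0.1), times = tr$time,
                      func = function(t, y, parms)
                        list(c(rr_rate(y[1], y[2], p),
                               rm_rate(y[1], y[2], p))),
                      parms = NULL, method = "ode45",
                      atol = 1e-10, rtol = 1e-8)
  expect_equal(tr$r, unname(ref[, "r"]), tolerance = 1e-6)
  expect_equal(tr$m, unname(ref[, "m"]), tolerance = 1e-6)
  expect_true(all(tr$u == 0))
})

test_that("strain stays within the active-compression bounds", {
  p <- chem_params(S = 0.05)
  mp <- local_mech_params(sigma_over_E = 0.25)
  tr <- simulate_local(p = p, mp = mp, t_end = 1000)
  expect_true(all(tr$u <= 1e-12))
  expect_true(all(tr$u > -mp$sigma_over_E))
})

test_that("trajectory classification identifies manufactured regimes", {
  p <- chem_params(S = 0.002)
  mk <- function(m, t = seq_along(m) - 1) {
    structure(data.frame(time = t, r = m, m = m, u = 0 * m),
              class = c("local_trajectory", "data.frame"),
              p = p, mp = local_mech_params())
  }
  # constant trajectory is quiescent
  expect_equal(classify_local(mk(rep(0.09, 400)))$label, "quiescent")
  # sustained oscillation around a level
  t <- seq(0, 999)
  expect_equal(classify_local(mk(0.5 + 0.3 * sin(t / 20)))$label, "pulsatile")
  # decaying oscillation onto the high branch
  expect_equal(classify_local(mk(1 + 0.5 * exp(-t / 120) * sin(t / 20)))$label,
               "contractile")
  # single pulse returning to the low branch
  pulse <- 0.09 + 0.9 * exp(-((t - 80) / 30)^2)
  expect_equal(classify_local(mk(pulse))$label, "excitable")
})

test_that("pulsatile classification is robust to the peak threshold", {
  tr <- simulate_local(p = chem_params(S = 0.025), t_end = 1500)
  for (thr in c(0.08, 0.1, 0.12))
    expect_equal(classify_local(tr, peak_threshold = thr)$label, "pulsatile")
  # and to halving the output cadence
  tr2 <- simulate_local(p = chem_params(S = 0.025), t_end = 1500, dt_out = 0.5)
  expect_equal(classify_local(tr2)$label, "pulsatile")
})

test_that("phase diagram cells equal standalone runs and map known regimes", {
  p <- chem_params()
  mp <- local_mech_params()
  pd <- phase_diagram_local(x_values = c(0.002, 0.025),
                            y_values = c(0, 0.2),
                            p = p, mp = mp, t_end = 1200)
  expect_equal(nrow(pd), 4)
  for (i in seq_len(nrow(pd))) {
    pi_ <- p; pi_$S <- pd$S[i]
    mpi <- mp; mpi$sigma_over_E <- pd$sigma_over_E[i]
    solo <- classify_local(simulate_local(p = pi_, mp = mpi, t_end = 1200))
    expect_equal(pd$label[i], solo$label)
  }
  # strong negative feedback quenches the circuit
  pg <- phase_diagram_local(x_param = "a", x_values = 0.05,
                            y_param = "g", y_values = 1.5,
                            p = chem_params(S = 0.025), t_end = 800)
  expect_equal(pg$label, "quiescent")
})
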