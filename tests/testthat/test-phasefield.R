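test_that("phase extraction recovers a synthetic oscillation phase", {
  N <- 32
  th <- matrix(seq(-pi + 0.01, pi, length.out = N * N), N, N)
  r <- 0.5 + 0.25 * sin(th)
  m <- 0.7 + 0.25 * cos(th)
  phi <- extract_phase(r, m, rbar = 0.5, mbar = 0.7)
  # atan2(sin, cos) recovers the angle exactly for a circular cycle
  expect_equal(as.vector(phi), as.vector(th), tolerance = 1e-12)
  # positive RhoA deviation at zero actomyosin deviation maps to pi/2
  phi2 <- extract_phase(matrix(1, 2, 2), matrix(0.3, 2, 2),
                        rbar = 0.4, mbar = 0.3)
  expect_equal(as.vector(phi2), rep(pi / 2, 4))
  # both deviations below threshold are masked
  phi3 <- extract_phase(matrix(0.4, 2, 2), matrix(0.3, 2, 2),
                        rbar = 0.4, mbar = 0.3)
  expect_true(all(is.na(phi3)))
})

test_that("the phase winds once per period on the ODE limit cycle", {
  tr <- simulate_local(p = chem_params(S = 0.025), t_end = 1200)
  w <- tr$time >= 400                    # settled limit cycle
  r <- tr$r[w]; m <- tr$m[w]
  phi <- atan2(r - mean(r), m - mean(m))
  dphi <- cortexgel:::wrap_angle(diff(phi))
  total_winding <- sum(dphi) / (2 * pi)
  n_periods <- length(cortexgel:::find_peaks_prominent(
    m, 0.2 * diff(range(m))))
  # one full 2*pi winding per oscillation period (edge periods may be cut)
  expect_lte(abs(abs(total_winding) - n_periods), 1)
  expect_gt(abs(total_winding), 10)
})

test_that("defect detection returns the canonical winding numbers", {
  phi <- make_fixture("single-vortex", N = 128, L = 128)
  d <- find_defects(phi, L = 128, periodic = FALSE)
  expect_equal(nrow(d), 1)
  expect_equal(d$charge, 1)
  expect_equal(c(d$x, d$y), c(64, 64), tolerance = 2)
  d_mirror <- find_defects(-phi, L = 128, periodic = FALSE)
  expect_equal(d_mirror$charge, -1)
  dp <- find_defects(make_fixture("vortex-pair", N = 128, L = 128))
  expect_equal(sort(dp$charge), c(-1, 1))
  expect_equal(attr(dp, "total_charge"), 0)
})

test_that("total charge vanishes on every periodic frame", {
  for (seed in 1:5) {
    phi <- random_phase_field(N = 64, seed = seed)
    d <- find_defects(phi)
    expect_equal(attr(d, "total_charge"), 0)
    expect_gt(nrow(d), 0)                 # the fields do contain defects
    expect_equal(sum(d$charge > 0), sum(d$charge < 0))
  }
})

test_that("defects are invariant under a global phase shift", {
  phi <- random_phase_field(N = 64, seed = 11)
  d0 <- find_defects(phi)
  for (c0 in c(0.7, -2.1, 3.0)) {
    d1 <- find_defects(cortexgel:::wrap_angle(phi + c0))
    expect_equal(d1$i, d0$i)
    expect_equal(d1$j, d0$j)
    expect_equal(d1$charge, d0$charge)
  }
})

test_that("phase velocity handles constants, ramps and the branch cut", {
  N <- 64; L <- 80
  vp0 <- phase_velocity(matrix(0.4, N, N), L)
  expect_equal(vp0$vx, matrix(0, N, N))
  expect_equal(vp0$vy, matrix(0, N, N))
  # linear phase ramp phi = q x (wrapped): gradient (q, 0) everywhere
  q <- 2 * pi * 3 / L
  phi <- make_fixture("plane-wave", N = N, L = L, q = q)
  vp <- phase_velocity(phi, L)
  expect_equal(vp$vx, matrix(q, N, N), tolerance = 1e-12)
  expect_equal(vp$vy, matrix(0, N, N))
  # smooth low-wavenumber phase: centred differences track the spectral
  # gradient closely
  ax <- (1:N - 0.5) * L / N
  psi <- 0.5 * outer(sin(2 * pi * ax / L), cos(2 * pi * ax / L))
  vps <- phase_velocity(psi, L)
  k1 <- cortexgel:::fft_wavenumbers_d1(N, L)
  gx <- Re(fft(1i * matrix(k1, N, N) * fft(psi), inverse = TRUE)) / N^2
  expect_lt(max(abs(vps$vx - gx)), 0.01 * max(abs(gx)))
})

test_that("vorticity is concentrated and positive at a +1 core", {
  phi <- make_fixture("vortex-pair", N = 96, L = 96)
  d <- find_defects(phi, L = 96)
  vp <- phase_velocity(phi, L = 96)
  om <- vorticity(vp)
  plus <- d[d$charge == 1, ]; minus <- d[d$charge == -1, ]
  expect_gt(om[plus$i, plus$j], 0)
  expect_lt(om[minus$i, minus$j], 0)
  # circulation oracle: integrated vorticity over a small disc around the
  # +1 core recovers the quantized circulation 2*pi
  ii <- (plus$i + (-3:4)) ; jj <- (plus$j + (-3:4))
  circ <- sum(om[ii, jj]) * 1^2
  expect_equal(circ, 2 * pi, tolerance = 0.15 * 2 * pi)
  # far from both cores the field is irrotational
  far <- om[((plus$i + 48 - 1) %% 96) + 1, ((plus$j + 20 - 1) %% 96) + 1]
  expect_lt(abs(far), 0.05)
})

test_that("energy and enstrophy obey the single-mode identity", {
  z <- list(vx = matrix(0, 32, 32), vy = matrix(0, 32, 32), dx = 1)
  expect_equal(unname(energy_enstrophy(z)), c(0, 0))
  N <- 128; L <- 100; k <- 2 * pi * 4 / L
  ax <- (1:N - 0.5) * L / N
  vp <- list(vx = matrix(cos(k * ax), N, N, byrow = TRUE),
             vy = matrix(0, N, N), dx = L / N)
  ee <- energy_enstrophy(vp, omega = vorticity(vp, method = "spectral"))
  expect_equal(ee[["enstrophy"]] / ee[["energy"]], k^2, tolerance = 1e-10)
})

test_that("the tail fitter recovers a known power law and rejects others", {
  set.seed(1)
  u <- runif(3e5)
  x <- (1 - u)^(-1 / 2)                  # density ~ x^-3 above 1
  ft <- speed_tail_exponent(x)
  expect_equal(ft$exponent, 3, tolerance = 2 * ft$se / 3 + 0.05)
  expect_false(ft$poor_fit)
  expect_false(ft$insufficient)
  # an exponential tail is flagged as a poor power-law fit
  fe <- speed_tail_exponent(rexp(3e5))
  expect_true(fe$poor_fit)
  # too few samples are reported, not silently extrapolated
  expect_warning(speed_tail_exponent((1 - runif(5e3))^(-1 / 2)),
                 "samples")
})

test_that("a decaying vortex pair annihilates while conserving charge", {
  # family of fields interpolating (in the complex order parameter) between
  # a +1/-1 pair and a uniform state: the pair must disappear together, and
  # the total charge must be zero in every intermediate frame
  N <- 64
  z_pair <- exp(1i * make_fixture("vortex-pair", N = N, L = N, sep = 12))
  counts <- integer(0)
  for (tt in seq(0, 1, by = 0.05)) {
    d <- find_defects(Arg((1 - tt) * z_pair + tt))
    expect_equal(attr(d, "total_charge"), 0)       # conserved throughout
    expect_true(nrow(d) %in% c(0L, 2L))            # paired disappearance
    counts <- c(counts, nrow(d))
  }
  expect_equal(counts[1], 2L)
  expect_equal(counts[length(counts)], 0L)
  expect_true(all(diff(counts) <= 0))              # no re-creation
})
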