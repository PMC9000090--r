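# Spectral helpers on the uniform periodic grid ------------------------------

# angular wavenumbers in fft ordering for a periodic box of length L
fft_wavenumbers <- function(N, L) {
  j <- c(0:(ceiling(N / 2) - 1), -(floor(N / 2):1))
  2 * pi * j / L
}

# first derivative wavenumbers: Nyquist mode zeroed so the derivative of a
# real field stays real and symmetric
fft_wavenumbers_d1 <- function(N, L) {
  k <- fft_wavenumbers(N, L)
  if (N %% 2 == 0) k[N / 2 + 1] <- 0
  k
}

spectral_deriv_1d <- function(f, L) {
  N <- length(f)
  k <- fft_wavenumbers_d1(N, L)
  Re(stats::fft(1i * k * stats::fft(f), inverse = TRUE)) / N
}

#' Periodic one-dimensional field
#'
#' Container for concentration and velocity fields on a uniform cell-centred
#' periodic grid over the half-open domain `[0, L)`.
#'
#' @param r,m,v numeric vectors of equal length `N` (RhoA, actomyosin,
#'   velocity). `r` and `m` must be non-negative.
#' @param L domain length, micrometres.
#' @return An object of class `field1d`: list with `x` (cell centres), `r`,
#'   `m`, `v`, `L`, `dx`.
#' @export
field1d <- function(r, m, v = NULL, L) {
  N <- length(r)
  if (is.null(v)) v <- numeric(N)
  stopifnot(length(m) == N, length(v) == N, L > 0)
  if (any(r < 0) || any(m < 0))
    stop("field1d: concentrations must be >= 0")
  dx <- L / N
  structure(list(x = (seq_len(N) - 0.5) * dx, r = r, m = m, v = v,
                 L = L, dx = dx, N = N), class = "field1d")
}

#' Default near-homogeneous initial field
#'
#' Builds the standard initial condition for continuum runs: the spatially
#' uniform low reaction fixed point for the background stimulus, a small
#' supra-threshold RhoA seed (`r_seed`, emulating the initial excitable pulse
#' from which patterns condense), and a multiplicative perturbation of
#' relative amplitude `amp` drawn from a seeded uniform distribution.
#'
#' @param gp a [gel_params()] object (supplies `N` and the box size).
#' @param p a [chem_params()] object.
#' @param S_background resting stimulus used for the base state (default the
#'   `S` in `p`).
#' @param amp relative perturbation amplitude (default 1e-2).
#' @param r_seed amplitude of an additional uniform-random RhoA seed in
#'   `[0, r_seed]` per cell (default 0). A value straddling the excitation
#'   threshold (e.g. 0.08) makes sub-populations of cells fire, seeding the
#'   condensation of localized patterns when the resting state is linearly
#'   stable (the zero-stimulus pattern-formation runs); the default relies on
#'   the linear instability of the base state to amplify the multiplicative
#'   noise.
#' @param seed RNG seed (integer) for reproducible noise; `NULL` leaves the
#'   RNG state alone.
#' @return A [field1d()] object.
#' @export
init_field_1d <- function(gp, p = chem_params(), S_background = p$S,
                          amp = 1e-2, r_seed = 0, seed = NULL) {
  N <- gp$N
  L <- gp$L_over_lam * gp$lam
  p0 <- p; p0$S <- S_background
  fp <- find_fixed_points(p0)
  st <- fp[fp$stability == "stable", , drop = FALSE]
  base <- if (nrow(st) > 0) st[which.min(st$r), ] else fp[which.min(fp$r), ]
  if (!is.null(seed)) set.seed(seed)
  noise <- function() 1 + amp * stats::runif(N, -1, 1)
  r <- pmax(base$r * noise(), 0) + r_seed * stats::runif(N)
  m <- pmax(base$m * noise(), 0)
  field1d(r = r, m = m, v = numeric(N), L = L)
}

# Velocity update -------------------------------------------------------------

#' One implicit step of the 1D gel velocity equation
#'
#' Advances the drag-scaled Maxwell velocity equation
#' \deqn{\tau \dot v = -v + \lambda^2 \partial_x^2 v +
#'       \sigma' \partial_x\!\big(m/(m_0+m)\big)}
#' by one backward-Euler step, solved exactly in Fourier space on the
#' periodic grid (the operator is diagonal there, so the solve cannot be
#' singular for `dt > 0`).
#'
#' @param v velocity field (um/s).
#' @param m actomyosin field, or a precomputed force density via `force`.
#' @param gp a [gel_params()] object.
#' @param dt time step, s.
#' @param L domain length (defaults to `gp$L_over_lam * gp$lam`).
#' @param force optional: prescribed active force density (the term
#'   `sigma' * d/dx f` evaluated already), overriding the `m`-derived force.
#'   Used for verification against closed-form solutions.
#' @return Updated velocity field.
#' @export
velocity_step_1d <- function(v, m, gp, dt, L = gp$L_over_lam * gp$lam,
                             force = NULL) {
  stopifnot(dt > 0)
  if (any(!is.finite(v)) || (is.null(force) && any(!is.finite(m))))
    stop("velocity_step_1d: non-finite input")
  N <- length(v)
  k <- fft_wavenumbers(N, L)
  k1 <- fft_wavenumbers_d1(N, L)
  fhat <- if (is.null(force)) {
    gp$sigma_prime * 1i * k1 * stats::fft(m / (gp$m0 + m))
  } else {
    stats::fft(force)
  }
  a <- gp$tau / dt
  vhat <- (a * stats::fft(v) + fhat) / (a + 1 + gp$lam^2 * k^2)
  Re(stats::fft(vhat, inverse = TRUE)) / N
}

# Transport -------------------------------------------------------------------

# conservative upwind (optionally van Leer MUSCL) advection step, flux form
advect_1d <- function(c, v, dt, dx, method = c("upwind", "vanleer")) {
  method <- match.arg(method)
  N <- length(c)
  ip <- c(2:N, 1)                      # index i+1 (periodic)
  vf <- 0.5 * (v + v[ip])              # face velocity at i+1/2
  if (method == "upwind") {
    cface <- ifelse(vf > 0, c, c[ip])
  } else {
    im <- c(N, 1:(N - 1))
    d_lo <- c - c[im]; d_hi <- c[ip] - c
    s <- ifelse(d_lo * d_hi > 0, 2 * d_lo * d_hi / (d_lo + d_hi), 0)
    cface <- ifelse(vf > 0, c + 0.5 * s, c[ip] - 0.5 * s[ip])
  }
  flux <- vf * cface
  im_face <- c(N, 1:(N - 1))           # face i-1/2 is face at previous index
  c - dt / dx * (flux - flux[im_face])
}

# backward-Euler diffusion via the discrete-Laplacian symbol: the exact FFT
# solve of (I - dt D Dxx) c_new = c, whose inverse is an M-matrix, so
# positivity is preserved (unlike the continuous spectral symbol)
diffuse_spectral_1d <- function(c, D, dt, L) {
  if (D == 0) return(c)
  N <- length(c)
  dx <- L / N
  k <- fft_wavenumbers(N, L)
  keff2 <- (2 - 2 * cos(k * dx)) / dx^2
  Re(stats::fft(stats::fft(c) / (1 + dt * D * keff2), inverse = TRUE)) / N
}

#' One transport step (advection + diffusion) of a 1D concentration field
#'
#' Conservative finite-volume update of `dc/dt + d(cv)/dx = D d2c/dx2` on
#' the periodic grid: explicit upwind (or van Leer limited) face fluxes for
#' advection, implicit spectral treatment of diffusion. Both parts conserve
#' the spatial mean to machine precision. Reactions are handled separately
#' by the simulation driver.
#'
#' @param c concentration field.
#' @param v velocity field (cell centres; faces by averaging).
#' @param D diffusivity, um^2/s.
#' @param dt time step, s (must satisfy the advective CFL condition).
#' @param L domain length, um.
#' @param method `"upwind"` (default, positivity-preserving) or `"vanleer"`.
#' @return Updated concentration field.
#' @export
transport_step_1d <- function(c, v, D, dt, L,
                              method = c("upwind", "vanleer")) {
  N <- length(c)
  dx <- L / N
  if (dt * max(abs(v)) > dx)
    stop("transport_step_1d: advective CFL violated (dt too large)")
  mass0 <- mean(c)
  out <- advect_1d(c, v, dt, dx, method)
  out <- diffuse_spectral_1d(out, D, dt, L)
  drift <- abs(mean(out) - mass0) / max(abs(mass0), 1e-300)
  if (drift > 1e-8)
    stop("transport_step_1d: mass conservation drift ", drift, " per step")
  out
}

# Simulation driver -----------------------------------------------------------

#' Simulate the one-dimensional active-gel model
#'
#' Integrates the coupled velocity / transport / reaction system on a
#' periodic box by operator splitting: (1) implicit spectral velocity step,
#' (2) conservative transport of RhoA and actomyosin (each advective term
#' individually switchable), (3) explicit reaction update using the local
#' stimulus `S(x, t)`. The inner time step is limited by the advective CFL
#' condition (Courant number 0.4) and by `dt_max`; output is recorded at the
#' fixed cadence `dt_out`.
#'
#' @param init a [field1d()], or `NULL` for [init_field_1d()] defaults.
#' @param p a [chem_params()] object (its `S` is ignored when `stim` is
#'   given; the stimulus supplies `S(x, t)`).
#' @param gp a [gel_params()] object.
#' @param stim a stimulus protocol; default uniform with rate `p$S`.
#' @param t_end simulated time, s.
#' @param dt_out output cadence, s (default 1).
#' @param advect_r,advect_m switch the advective term of each species
#'   (diffusion and reaction are always on); used for feedback dissection.
#' @param dt_max cap on the inner time step, s.
#' @param method advection discretization, see [transport_step_1d()].
#' @param record_from discard output before this time, s.
#' @param seed RNG seed forwarded to [init_field_1d()] when `init` is NULL.
#' @param r_seed,amp forwarded to [init_field_1d()] when `init` is NULL.
#' @return An object of class `kymograph`: list with `times`, `x`, and
#'   row-per-time matrices `r`, `m`, `v`, plus `p`, `gp`, `stim`, `seed`.
#' @examples
#' gp <- gel_params(N = 64, L_over_lam = 5)
#' ky <- simulate_1d(p = chem_params(S = 0.01), gp = gp, t_end = 50, seed = 1)
#' @export
simulate_1d <- function(init = NULL, p = chem_params(), gp = gel_params(),
                        stim = stimulus_uniform(p$S), t_end,
                        dt_out = 1, advect_r = TRUE, advect_m = TRUE,
                        dt_max = 0.25, method = "vanleer",
                        record_from = 0, seed = NULL, r_seed = 0,
                        amp = 1e-2) {
  stopifnot(t_end > 0, dt_out > 0)
  if (is.null(init))
    init <- init_field_1d(gp, p, S_background = stimulus_background(stim),
                          amp = amp, r_seed = r_seed, seed = seed)
  L <- init$L; N <- init$N; dx <- init$dx
  if (N != gp$N) gp$N <- N
  r <- init$r; m <- init$m; v <- init$v
  out_times <- seq(0, t_end, by = dt_out)
  keep <- out_times >= record_from
  nt <- sum(keep)
  R <- matrix(NA_real_, nt, N); M <- matrix(NA_real_, nt, N)
  V <- matrix(NA_real_, nt, N)
  row <- 0L
  undershoot <- FALSE
  record <- function() {
    row <<- row + 1L
    R[row, ] <<- r; M[row, ] <<- m; V[row, ] <<- v
  }
  if (keep[1]) record()
  t <- 0
  for (io in seq_along(out_times)[-1]) {
    t_target <- out_times[io]
    while (t < t_target - 1e-12) {
      cfl <- 0.4 * dx / max(max(abs(v)), 1e-12)
      dt <- min(dt_max, cfl, t_target - t)
      v <- velocity_step_1d(v, m, gp, dt, L)
      # re-check CFL against the fresh velocity
      vmax <- max(abs(v))
      if (dt * vmax > dx) dt <- 0.8 * dx / vmax
      if (advect_r) r <- advect_1d(r, v, dt, dx, method)
      if (advect_m) m <- advect_1d(m, v, dt, dx, method)
      r <- diffuse_spectral_1d(r, gp$D_r, dt, L)
      m <- diffuse_spectral_1d(m, gp$D_m, dt, L)
      if (any(r < -1e-12) || any(m < -1e-12)) undershoot <- TRUE
      r <- pmax(r, 0); m <- pmax(m, 0)
      S_loc <- stimulus_rate(stim, init$x, t + 0.5 * dt)
      rr <- S_loc + ifelse(r == 0 & p$n > 0, 0,
                           p$a * r^p$n / (p$r_a^p$n + r^p$n)) -
            p$g * m * r / (p$r_g + r)
      rm <- p$S_m + p$k_a * r^2 - p$k_d * m
      r <- pmax(r + dt * rr, 0)
      m <- pmax(m + dt * rm, 0)
      t <- t + dt
      if (max(r, m) > 1e6)
        stop("simulate_1d: blow-up detected at t = ", round(t, 2),
             " s (max field > 1e6); sigma_prime = ", gp$sigma_prime)
    }
    t <- t_target
    if (keep[io]) record()
  }
  if (undershoot)
    warning("simulate_1d: solver undershot below -1e-12; clipped at 0")
  structure(list(times = out_times[keep], x = init$x, r = R, m = M, v = V,
                 L = L, dx = dx, p = p, gp = gp, stim = stim, seed = seed),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat("kymograph:", length(x$times), "frames x", length(x$x), "cells,",
      "t in [", min(x$times), ",", max(x$times), "] s, L =", x$L, "um\n")
  invisible(x)
}

#' Strain-rate kymograph
#'
#' Spatial derivative of the velocity field, `dv/dx`, for each recorded
#' frame (spectral differentiation on the periodic grid).
#'
#' @param kymo a `kymograph` from [simulate_1d()].
#' @return Matrix of `dv/dx` with the shape of `kymo$v`.
#' @export
strain_rate_kymo <- function(kymo) {
  t(apply(kymo$v, 1, spectral_deriv_1d, L = kymo$L))
}

#' Export a kymograph as a long data.frame
#'
#' @param x a `kymograph`.
#' @param row.names,optional,... ignored (base generic signature).
#' @return data.frame with columns `time`, `x`, `r`, `m`, `v`.
#' @export
as.data.frame.kymograph <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(time = rep(x$times, times = length(x$x)),
             x = rep(x$x, each = length(x$times)),
             r = as.vector(x$r), m = as.vector(x$m), v = as.vector(x$v))
}
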