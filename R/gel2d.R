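# 2D spectral helpers: wavenumber matrices in fft ordering
fft_k_matrices <- function(N, L) {
  k <- fft_wavenumbers(N, L)
  k1 <- fft_wavenumbers_d1(N, L)
  list(kx = matrix(k, N, N), ky = matrix(k, N, N, byrow = TRUE),
       kx1 = matrix(k1, N, N), ky1 = matrix(k1, N, N, byrow = TRUE))
}

#' Periodic two-dimensional field
#'
#' Container for the 2D gel state on an `N x N` cell-centred periodic grid
#' over `[0, L) x [0, L)`. Matrix rows index `x`, columns index `y`.
#'
#' @param r,m `N x N` matrices of concentrations (>= 0).
#' @param vx,vy `N x N` velocity components (um/s); default zero.
#' @param L domain edge length, micrometres.
#' @return An object of class `field2d`.
#' @export
field2d <- function(r, m, vx = NULL, vy = NULL, L) {
  N <- nrow(r)
  if (is.null(vx)) vx <- matrix(0, N, N)
  if (is.null(vy)) vy <- matrix(0, N, N)
  stopifnot(ncol(r) == N, all(dim(m) == N), all(dim(vx) == N),
            all(dim(vy) == N), L > 0)
  if (any(r < 0) || any(m < 0))
    stop("field2d: concentrations must be >= 0")
  dx <- L / N
  ax <- (seq_len(N) - 0.5) * dx
  structure(list(x = ax, y = ax, r = r, m = m, vx = vx, vy = vy,
                 L = L, dx = dx, N = N), class = "field2d")
}

#' Default near-homogeneous 2D initial field
#'
#' Two-dimensional analogue of [init_field_1d()]: uniform low fixed point,
#' multiplicative noise of amplitude `amp`, optional per-cell uniform RhoA
#' seed in `[0, r_seed]`.
#'
#' @inheritParams init_field_1d
#' @return A [field2d()] object.
#' @export
init_field_2d <- function(gp, p = chem_params(), S_background = p$S,
                          amp = 1e-2, r_seed = 0, seed = NULL) {
  N <- gp$N
  L <- gp$L_over_lam * gp$lam
  p0 <- p; p0$S <- S_background
  fp <- find_fixed_points(p0)
  st <- fp[fp$stability == "stable", , drop = FALSE]
  base <- if (nrow(st) > 0) st[which.min(st$r), ] else fp[which.min(fp$r), ]
  if (!is.null(seed)) set.seed(seed)
  noise <- function() matrix(1 + amp * stats::runif(N * N, -1, 1), N, N)
  r <- pmax(base$r * noise(), 0) + r_seed * matrix(stats::runif(N * N), N, N)
  m <- pmax(base$m * noise(), 0)
  field2d(r = r, m = m, L = L)
}

#' One implicit step of the 2D gel velocity equation
#'
#' Advances the drag-scaled compressible Stokes-like Maxwell equation
#' \deqn{\tau \dot{\mathbf v} = -\mathbf v + \lambda_s^2 \nabla^2 \mathbf v
#'   + \lambda_b^2 \nabla(\nabla\cdot\mathbf v)
#'   + \sigma' \nabla\!\big(m/(m_0+m)\big)}
#' (with \eqn{\lambda_s^2 = \eta_s/\gamma}, \eqn{\lambda_b^2 =
#' \eta_b/\gamma}) by one backward-Euler step. On the periodic torus the
#' coupled operator is block-diagonal in Fourier space; each 2x2 block
#' `a I + b k k^T` is inverted in closed form, so the grad-div coupling is
#' treated exactly.
#'
#' @param vx,vy velocity components (`N x N` matrices).
#' @param m actomyosin field.
#' @param gp a [gel2d_params()] object.
#' @param dt time step, s.
#' @param L domain edge length (default from `gp`).
#' @return List with updated `vx`, `vy`.
#' @export
velocity_step_2d <- function(vx, vy, m, gp, dt, L = gp$L_over_lam * gp$lam) {
  stopifnot(dt > 0)
  N <- nrow(vx)
  km <- fft_k_matrices(N, L)
  lam_s2 <- gp$eta_s_frac * gp$lam^2
  lam_b2 <- gp$eta_b_frac * gp$lam^2
  fhat <- stats::fft(m / (gp$m0 + m))
  a0 <- gp$tau / dt
  rx <- a0 * stats::fft(vx) + gp$sigma_prime * 1i * km$kx1 * fhat
  ry <- a0 * stats::fft(vy) + gp$sigma_prime * 1i * km$ky1 * fhat
  K2 <- km$kx^2 + km$ky^2
  a <- a0 + 1 + lam_s2 * K2
  # (a I + b k k^T)^{-1} = (I - b k k^T / (a + b K2)) / a
  kdotr <- km$kx * rx + km$ky * ry
  fac <- lam_b2 * kdotr / (a * (a + lam_b2 * K2))
  vxh <- rx / a - km$kx * fac
  vyh <- ry / a - km$ky * fac
  list(vx = Re(stats::fft(vxh, inverse = TRUE)) / N^2,
       vy = Re(stats::fft(vyh, inverse = TRUE)) / N^2)
}

# 2D conservative advection: unsplit flux differencing with van Leer (or
# upwind) face states in each direction
advect_2d <- function(c, vx, vy, dt, dx, method = c("vanleer", "upwind")) {
  method <- match.arg(method)
  N <- nrow(c)
  ip <- c(2:N, 1); im <- c(N, 1:(N - 1))
  face_flux <- function(c, cp, cm, cpp, vf) {
    # cm = c[i-1], cp = c[i+1]; van Leer slope at i and i+1
    if (method == "upwind") {
      ifelse(vf > 0, c, cp) * vf
    } else {
      d_lo <- c - cm; d_hi <- cp - c
      s <- ifelse(d_lo * d_hi > 0, 2 * d_lo * d_hi / (d_lo + d_hi), 0)
      d_lo2 <- cp - c; d_hi2 <- cpp - cp
      s2 <- ifelse(d_lo2 * d_hi2 > 0, 2 * d_lo2 * d_hi2 / (d_lo2 + d_hi2), 0)
      ifelse(vf > 0, c + 0.5 * s, cp - 0.5 * s2) * vf
    }
  }
  # x-direction (rows index x): faces between row i and i+1
  vfx <- 0.5 * (vx + vx[ip, ])
  Fx <- face_flux(c, c[ip, ], c[im, ], c[ip, , drop = FALSE][ip, ], vfx)
  dFx <- Fx - Fx[im, ]
  # y-direction
  vfy <- 0.5 * (vy + vy[, ip])
  Fy <- face_flux(c, c[, ip], c[, im], c[, ip, drop = FALSE][, ip], vfy)
  dFy <- Fy - Fy[, im]
  c - dt / dx * (dFx + dFy)
}

diffuse_spectral_2d <- function(c, D, dt, L) {
  if (D == 0) return(c)
  N <- nrow(c)
  dx <- L / N
  k <- fft_wavenumbers(N, L)
  s1 <- (2 - 2 * cos(k * dx)) / dx^2
  sym <- outer(s1, s1, "+")
  Re(stats::fft(stats::fft(c) / (1 + dt * D * sym), inverse = TRUE)) / N^2
}

#' Divergence of a 2D velocity field
#'
#' Local strain rate `div v = dvx/dx + dvy/dy` by centred differences on
#' the periodic grid.
#'
#' @param vx,vy velocity components (`N x N`).
#' @param L domain edge length, um.
#' @return `N x N` matrix of the strain rate, 1/s.
#' @export
strain_rate_field <- function(vx, vy, L) {
  N <- nrow(vx)
  dx <- L / N
  ip <- c(2:N, 1); im <- c(N, 1:(N - 1))
  (vx[ip, ] - vx[im, ]) / (2 * dx) + (vy[, ip] - vy[, im]) / (2 * dx)
}

#' Simulate the two-dimensional active-gel model
#'
#' Two-dimensional analogue of [simulate_1d()]: operator-split stepping of
#' the implicit spectral velocity solve, conservative van Leer transport of
#' both species, implicit diffusion and explicit reactions with the local
#' stimulus. Frames are recorded at cadence `dt_out` from `record_from`
#' onwards.
#'
#' @param init a [field2d()], or `NULL` for [init_field_2d()] defaults.
#' @param p,gp,stim,t_end,dt_out,advect_r,advect_m,dt_max,method,record_from,seed,r_seed,amp
#'   as in [simulate_1d()]; `gp` must be a [gel2d_params()].
#' @param record_velocity record the velocity components of every frame
#'   (memory-heavier; the final frame's velocity is always kept).
#' @return An object of class `field_series`: list with `times`, `x`, `y`,
#'   arrays `r`, `m` of dimension `(time, N, N)`, final-frame `vx`, `vy`
#'   (or full arrays if `record_velocity`), and the run metadata.
#' @examples
#' gp <- gel2d_params(N = 32, L_over_lam = 4)
#' fs <- simulate_2d(p = chem_params(S = 0.01), gp = gp, t_end = 5, seed = 1)
#' @export
simulate_2d <- function(init = NULL, p = chem_params(), gp = gel2d_params(),
                        stim = stimulus_uniform(p$S), t_end, dt_out = 1,
                        advect_r = TRUE, advect_m = TRUE, dt_max = 0.25,
                        method = "vanleer", record_from = 0, seed = NULL,
                        r_seed = 0, amp = 1e-2, record_velocity = FALSE) {
  stopifnot(t_end > 0, dt_out > 0)
  if (!inherits(gp, "gel2d_params")) stop("simulate_2d: gp must be gel2d_params")
  if (is.null(init))
    init <- init_field_2d(gp, p, S_background = stimulus_background(stim),
                          amp = amp, r_seed = r_seed, seed = seed)
  L <- init$L; N <- init$N; dx <- init$dx
  r <- init$r; m <- init$m; vx <- init$vx; vy <- init$vy
  xg <- matrix(init$x, N, N)                    # boxcar acts along x
  out_times <- seq(0, t_end, by = dt_out)
  keep <- out_times >= record_from
  nt <- sum(keep)
  R <- array(NA_real_, c(nt, N, N)); M <- array(NA_real_, c(nt, N, N))
  if (record_velocity) { VX <- array(NA_real_, c(nt, N, N)); VY <- VX }
  row <- 0L
  undershoot <- FALSE
  record <- function() {
    row <<- row + 1L
    R[row, , ] <<- r; M[row, , ] <<- m
    if (record_velocity) { VX[row, , ] <<- vx; VY[row, , ] <<- vy }
  }
  if (keep[1]) record()
  t <- 0
  for (io in seq_along(out_times)[-1]) {
    t_target <- out_times[io]
    while (t < t_target - 1e-12) {
      vmax <- max(abs(vx) + abs(vy), 1e-12)
      dt <- min(dt_max, 0.4 * dx / vmax, t_target - t)
      vv <- velocity_step_2d(vx, vy, m, gp, dt, L)
      vx <- vv$vx; vy <- vv$vy
      vmax <- max(abs(vx) + abs(vy))
      if (dt * vmax > dx) dt <- 0.8 * dx / vmax
      if (advect_r) r <- advect_2d(r, vx, vy, dt, dx, method)
      if (advect_m) m <- advect_2d(m, vx, vy, dt, dx, method)
      r <- diffuse_spectral_2d(r, gp$D_r, dt, L)
      m <- diffuse_spectral_2d(m, gp$D_m, dt, L)
      if (any(r < -1e-12) || any(m < -1e-12)) undershoot <- TRUE
      r[r < 0] <- 0; m[m < 0] <- 0
      S_loc <- stimulus_rate(stim, xg, t + 0.5 * dt)
      auto <- p$a * r^p$n / (p$r_a^p$n + r^p$n)
      auto[r == 0] <- 0
      rr <- S_loc + auto - p$g * m * r / (p$r_g + r)
      rm <- p$S_m + p$k_a * r^2 - p$k_d * m
      r <- pmax(r + dt * rr, 0)
      m <- pmax(m + dt * rm, 0)
      t <- t + dt
      if (max(r, m) > 1e6)
        stop("simulate_2d: blow-up detected at t = ", round(t, 2), " s")
    }
    t <- t_target
    if (keep[io]) record()
  }
  if (undershoot)
    warning("simulate_2d: solver undershot below -1e-12; clipped at 0")
  out <- list(times = out_times[keep], x = init$x, y = init$y, r = R, m = M,
              vx = if (record_velocity) VX else vx,
              vy = if (record_velocity) VY else vy,
              record_velocity = record_velocity,
              L = L, dx = dx, p = p, gp = gp, stim = stim, seed = seed)
  class(out) <- "field_series"
  out
}

#' @export
print.field_series <- function(x, ...) {
  cat("field series:", length(x$times), "frames of",
      length(x$x), "x", length(x$y), "cells, t in [",
      min(x$times), ",", max(x$times), "] s, L =", x$L, "um\n")
  invisible(x)
}
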