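# wrap angles to the principal branch (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Extract the oscillation phase field
#'
#' Maps concentration fields on the limit cycle to a phase through the
#' four-quadrant arctangent of the deviations from the reference means,
#' `phi = atan2(r - rbar, m - mbar)` (RhoA deviation first, matching the
#' deviation ratio `(r - rbar)/(m - mbar)`; the four-quadrant form makes the
#' phase wind monotonically around the cycle). Cells where both deviations
#' are below `1e-12` in magnitude are undefined and masked as `NA`.
#'
#' @param r,m arrays of matching shape: either single `N x N` frames or
#'   `(time, N, N)` series.
#' @param means `"spacetime"` (default): `rbar`, `mbar` are the means over
#'   all supplied values; `"pixel"`: per-pixel temporal means (series input
#'   only).
#' @param rbar,mbar optionally override the reference means.
#' @return Array of phases in `(-pi, pi]` with the shape of `r`, with
#'   attributes `rbar`, `mbar`.
#' @export
extract_phase <- function(r, m, means = c("spacetime", "pixel"),
                          rbar = NULL, mbar = NULL) {
  means <- match.arg(means)
  if (!all(dim(r) == dim(m))) stop("extract_phase: shape mismatch")
  if (is.null(rbar) || is.null(mbar)) {
    if (means == "spacetime") {
      rbar <- mean(r); mbar <- mean(m)
    } else {
      if (length(dim(r)) != 3)
        stop("extract_phase: pixel means need a (time, N, N) series")
      rbar <- apply(r, c(2, 3), mean); mbar <- apply(m, c(2, 3), mean)
      rbar <- aperm(array(rbar, c(dim(r)[2:3], dim(r)[1])), c(3, 1, 2))
      mbar <- aperm(array(mbar, c(dim(m)[2:3], dim(m)[1])), c(3, 1, 2))
    }
  }
  dr <- r - rbar; dm <- m - mbar
  phi <- atan2(dr, dm)
  phi[abs(dr) < 1e-12 & abs(dm) < 1e-12] <- NA_real_
  attr(phi, "rbar") <- rbar; attr(phi, "mbar") <- mbar
  phi
}

#' Detect topological defects of a phase field
#'
#' Computes the winding number of every 2x2 plaquette of the periodic grid
#' as the closed-loop sum of branch-wrapped phase differences divided by
#' `2*pi`. A winding of +1 marks an anticlockwise phase spiral, -1 a
#' clockwise one. On the torus the total charge is identically zero (every
#' edge is traversed once in each direction over the full tiling).
#'
#' @param phi an `N x N` phase field in `(-pi, pi]` (rows = x, cols = y).
#' @param L domain edge length, um (for defect coordinates); default `N`
#'   grid units.
#' @param periodic treat the grid as a torus (default). Set `FALSE` for
#'   synthetic fields that are not periodic (e.g. a lone vortex, whose seam
#'   would otherwise carry compensating winding); only interior plaquettes
#'   are then scanned, and the zero-total-charge guarantee does not apply.
#' @return An object of class `defect_set`: data.frame with columns `x`,
#'   `y` (plaquette-centre coordinates), `i`, `j` (cell indices) and
#'   `charge`; total charge in attribute `total_charge`.
#' @export
find_defects <- function(phi, L = nrow(phi), periodic = TRUE) {
  N <- nrow(phi)
  stopifnot(ncol(phi) == N)
  dx <- L / N
  ip <- c(2:N, 1)
  # loop i,j -> i+1,j -> i+1,j+1 -> i,j+1 -> i,j (anticlockwise for
  # x right / y up)
  d1 <- wrap_angle(phi[ip, ] - phi)            # (i,j)   -> (i+1,j)
  d2 <- wrap_angle(phi[ip, ip] - phi[ip, ])    # (i+1,j) -> (i+1,j+1)
  d3 <- wrap_angle(phi[, ip] - phi[ip, ip])    # (i+1,j+1)-> (i,j+1)
  d4 <- wrap_angle(phi - phi[, ip])            # (i,j+1) -> (i,j)
  wind <- (d1 + d2 + d3 + d4) / (2 * pi)
  q <- round(wind)
  q[is.na(q)] <- 0L
  if (!periodic) q[N, ] <- q[, N] <- 0L   # drop seam plaquettes
  if (any(abs(q) >= 2))
    warning("find_defects: |winding| >= 2 on a plaquette; ",
            "field under-resolved near a singularity")
  idx <- which(q != 0, arr.ind = TRUE)
  out <- data.frame(x = (idx[, 1] - 0.5) * dx + 0.5 * dx,
                    y = (idx[, 2] - 0.5) * dx + 0.5 * dx,
                    i = idx[, 1], j = idx[, 2],
                    charge = q[idx])
  structure(out, class = c("defect_set", "data.frame"),
            total_charge = sum(out$charge))
}

#' Phase velocity field
#'
#' Gradient of the phase, computed with branch-aware centred differences:
#' each one-sided difference is wrapped to the principal branch before
#' averaging, so the gradient is correct across the phase cut away from
#' defect cores.
#'
#' @param phi `N x N` phase field.
#' @param L domain edge length, um.
#' @return List with `vx`, `vy` (`N x N` matrices, rad/um).
#' @export
phase_velocity <- function(phi, L = nrow(phi)) {
  N <- nrow(phi)
  dx <- L / N
  ip <- c(2:N, 1); im <- c(N, 1:(N - 1))
  vx <- (wrap_angle(phi[ip, ] - phi) + wrap_angle(phi - phi[im, ])) / (2 * dx)
  vy <- (wrap_angle(phi[, ip] - phi) + wrap_angle(phi - phi[, im])) / (2 * dx)
  list(vx = vx, vy = vy, dx = dx)
}

#' Vorticity of the phase-velocity field
#'
#' `omega = curl v_phi = dvy/dx - dvx/dy` by centred differences on the
#' periodic grid. Positive vorticity marks +1 (anticlockwise) defects.
#'
#' @param vphi a list with `vx`, `vy`, `dx` as returned by
#'   [phase_velocity()].
#' @param method `"centered"` (default; local, robust at defect cores) or
#'   `"spectral"` (exact for band-limited fields — a single Fourier mode
#'   satisfies `enstrophy/energy = k^2` to machine precision).
#' @return `N x N` matrix of the scalar vorticity.
#' @export
vorticity <- function(vphi, method = c("centered", "spectral")) {
  method <- match.arg(method)
  vx <- vphi$vx; vy <- vphi$vy; dx <- vphi$dx
  N <- nrow(vx)
  if (method == "centered") {
    ip <- c(2:N, 1); im <- c(N, 1:(N - 1))
    (vy[ip, ] - vy[im, ]) / (2 * dx) - (vx[, ip] - vx[, im]) / (2 * dx)
  } else {
    L <- N * dx
    k1 <- fft_wavenumbers_d1(N, L)
    kx <- matrix(k1, N, N); ky <- matrix(k1, N, N, byrow = TRUE)
    Re(stats::fft(1i * kx * stats::fft(vy) - 1i * ky * stats::fft(vx),
                  inverse = TRUE)) / N^2
  }
}

#' Effective kinetic energy and enstrophy of the phase flow
#'
#' `E = 0.5 * <|v_phi|^2>` and `Omega = 0.5 * <omega^2>`, the spatial means
#' over one frame. For a single-Fourier-mode field the ratio `Omega/E`
#' equals `k^2` exactly (in the continuum limit).
#'
#' @param vphi list with `vx`, `vy` ([phase_velocity()] output).
#' @param omega vorticity field; computed from `vphi` if missing.
#' @return Named numeric vector `c(energy =, enstrophy =)`.
#' @export
energy_enstrophy <- function(vphi, omega = NULL) {
  if (is.null(omega)) omega <- vorticity(vphi)
  c(energy = 0.5 * mean(vphi$vx^2 + vphi$vy^2, na.rm = TRUE),
    enstrophy = 0.5 * mean(omega^2, na.rm = TRUE))
}

#' Power-law tail exponent of a speed distribution
#'
#' Continuous maximum-likelihood fit of a power-law tail
#' `p(v) ~ v^(-alpha)` to speed samples normalized by their mean. The lower
#' cutoff is chosen by minimizing the Kolmogorov-Smirnov distance between
#' the empirical tail and the fitted Pareto form over a grid of candidate
#' quantiles inside the top `tail_fraction` of the data. The fit quality is
#' flagged poor when the optimal KS distance exceeds `1.5/sqrt(n_tail)`;
#' non-power-law tails (e.g. exponential) fail this, and so, mildly, do
#' tails truncated by the grid resolution (the steepening above the
#' resolution-limited speed is part of the data and is deliberately not
#' trimmed).
#'
#' @param speeds positive speed samples.
#' @param tail_fraction fraction of the largest samples considered for the
#'   fit (default 0.05).
#' @param n_candidates number of candidate lower cutoffs scanned.
#' @param min_samples minimum sample count demanded in the fit range
#'   (default 1e4; fewer give a warning and `insufficient = TRUE`).
#' @return List with `exponent` (alpha, magnitude of the density exponent),
#'   `se` (asymptotic standard error `(alpha-1)/sqrt(n)`), `xmin` (cutoff
#'   on the normalized scale), `ks`, `n_tail`, `poor_fit`, `insufficient`.
#' @export
speed_tail_exponent <- function(speeds, tail_fraction = 0.05,
                                n_candidates = 25, min_samples = 1e4) {
  s <- speeds[is.finite(speeds) & speeds > 0]
  s <- s / mean(s)
  probs <- seq(1 - tail_fraction, 0.995, length.out = n_candidates)
  cands <- unique(stats::quantile(s, probs, names = FALSE))
  n_range <- sum(s >= cands[1])
  best <- NULL
  for (xmin in cands) {
    tail <- s[s >= xmin]
    n <- length(tail)
    if (n < 10) next
    alpha <- 1 + n / sum(log(tail / xmin))
    q <- sort(tail)
    ks <- max(abs((seq_len(n) - 0.5) / n - (1 - (q / xmin)^(1 - alpha))))
    if (is.null(best) || ks < best$ks)
      best <- list(exponent = alpha, se = (alpha - 1) / sqrt(n),
                   xmin = xmin, ks = ks, n_tail = n)
  }
  if (is.null(best)) stop("speed_tail_exponent: no viable tail")
  best$insufficient <- n_range < min_samples
  if (best$insufficient)
    warning("speed_tail_exponent: only ", n_range,
            " samples in the fit range (< ", min_samples,
            "); exponent is unreliable")
  best$poor_fit <- best$ks > 1.5 / sqrt(best$n_tail)
  best
}

#' Defect census and phase statistics of a 2D run
#'
#' Convenience driver: extracts the phase from a [simulate_2d()] series,
#' finds per-frame defects, and accumulates phase-velocity statistics
#' (energy, enstrophy, speed samples).
#'
#' @param fs a `field_series` from [simulate_2d()].
#' @param frames indices of frames to analyse (default all).
#' @param means passed to [extract_phase()].
#' @param speed_type speed samples accumulated for the tail statistics:
#'   `"motion"` (default) is the local speed of phase-field motion,
#'   `|dphi/dt| / |grad phi|` (the front speed of the oscillation pattern;
#'   it diverges at the zeros of the phase gradient, producing the
#'   heavy-tailed statistics of defect-mediated turbulence); `"gradient"`
#'   is the magnitude `|grad phi|` of the phase velocity itself, whose
#'   largest values are bounded by the grid resolution at defect cores.
#' @return List with `defects` (data.frame: `time`, `x`, `y`, `charge`),
#'   `counts` (per frame: `n_plus`, `n_minus`, `total_charge`), `stats`
#'   (per frame: `energy`, `enstrophy` of the phase velocity), `speeds`
#'   (pooled samples per `speed_type`), and `phi` (the phase series).
#' @export
phase_turbulence_analysis <- function(fs, frames = NULL,
                                      means = "spacetime",
                                      speed_type = c("motion", "gradient")) {
  speed_type <- match.arg(speed_type)
  if (is.null(frames)) frames <- seq_along(fs$times)
  phi_all <- extract_phase(fs$r[frames, , , drop = FALSE],
                           fs$m[frames, , , drop = FALSE], means = means)
  L <- fs$L
  defects <- list(); counts <- list(); stats_l <- list(); speeds <- list()
  for (ii in seq_along(frames)) {
    phi <- phi_all[ii, , ]
    ds <- find_defects(phi, L)
    t_i <- fs$times[frames[ii]]
    if (nrow(ds) > 0)
      defects[[ii]] <- data.frame(time = t_i, x = ds$x, y = ds$y,
                                  charge = ds$charge)
    counts[[ii]] <- data.frame(time = t_i,
                               n_plus = sum(ds$charge > 0),
                               n_minus = sum(ds$charge < 0),
                               total_charge = attr(ds, "total_charge"))
    vp <- phase_velocity(phi, L)
    ee <- energy_enstrophy(vp)
    stats_l[[ii]] <- data.frame(time = t_i, energy = ee[["energy"]],
                                enstrophy = ee[["enstrophy"]])
    if (speed_type == "gradient") {
      speeds[[ii]] <- sqrt(vp$vx^2 + vp$vy^2)
    } else if (ii < length(frames)) {
      dt <- fs$times[frames[ii + 1]] - t_i
      dphit <- abs(wrap_angle(phi_all[ii + 1, , ] - phi)) / dt
      grad <- sqrt(vp$vx^2 + vp$vy^2)
      speeds[[ii]] <- dphit / pmax(grad, 1e-12)
    }
  }
  list(defects = do.call(rbind, defects),
       counts = do.call(rbind, counts),
       stats = do.call(rbind, stats_l),
       speeds = as.vector(unlist(speeds)),
       phi = phi_all)
}
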