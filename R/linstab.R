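#' Jacobian of the 1D gel model at wavenumber k
#'
#' Linearisation of the velocity / transport / reaction system about a
#' homogeneous fixed point `(r, m, v = 0)` for a perturbation `~ exp(ikx)`.
#' In drag-scaled units the 3x3 complex matrix is
#' \deqn{\begin{pmatrix}
#'   \partial_r R_r - D_r k^2 & \partial_m R_r & -ikr \\
#'   \partial_r R_m & -k_d - D_m k^2 & -ikm \\
#'   0 & ik\sigma' m_0/(\tau (m_0+m)^2) & -(1+\lambda^2 k^2)/\tau
#' \end{pmatrix}}
#' where the reaction derivatives come from [reaction_jacobian()]. The
#' viscosity in the damping entry is the network viscosity eta, entering as
#' `lam^2 = eta/gamma`.
#'
#' @param fp a one-row data.frame (or list) with fields `r`, `m` — a fixed
#'   point from [find_fixed_points()].
#' @param k wavenumber, 1/um.
#' @param p a [chem_params()] object.
#' @param gp a [gel_params()] object.
#' @return A 3x3 complex matrix.
#' @export
jacobian_k <- function(fp, k, p, gp) {
  r <- fp$r; m <- fp$m
  J2 <- reaction_jacobian(r, m, p)
  J <- matrix(0i, 3, 3)
  J[1, 1] <- J2[1, 1] - gp$D_r * k^2
  J[1, 2] <- J2[1, 2]
  J[1, 3] <- -1i * k * r
  J[2, 1] <- J2[2, 1]
  J[2, 2] <- J2[2, 2] - gp$D_m * k^2
  J[2, 3] <- -1i * k * m
  J[3, 2] <- 1i * k * gp$sigma_prime * gp$m0 / (gp$tau * (gp$m0 + m)^2)
  J[3, 3] <- -(1 + gp$lam^2 * k^2) / gp$tau
  J
}

# eigenvalues of jacobian_k sorted into continuous branches by eigenvector
# overlap with the previous k (greedy assignment)
branch_sorted_eigen <- function(fp, k_grid, p, gp) {
  nb <- 3L
  lam <- matrix(NA_complex_, length(k_grid), nb)
  prev_vec <- NULL
  for (i in seq_along(k_grid)) {
    e <- eigen(jacobian_k(fp, k_grid[i], p, gp))
    if (is.null(prev_vec)) {
      ord <- order(-Re(e$values))
    } else {
      ov <- abs(Conj(t(prev_vec)) %*% e$vectors)   # rows: prev branch
      ord <- integer(nb); used <- logical(nb)
      for (b in seq_len(nb)) {
        j <- which.max(ifelse(used, -1, ov[b, ]))
        ord[b] <- j; used[j] <- TRUE
      }
    }
    lam[i, ] <- e$values[ord]
    prev_vec <- e$vectors[, ord, drop = FALSE]
  }
  lam
}

#' Dispersion relation about a homogeneous fixed point
#'
#' Scans wavenumbers `k` in `(0, k_max]`, takes the eigenvalue of
#' [jacobian_k()] with the largest real part at each `k`, and reports the
#' fastest-growing mode `k_star`, its wavelength, frequency and wave speed.
#' The standard conventions are used: wavelength `2*pi/k_star`, frequency
#' `|Im lambda(k_star)|` (angular, 1/s), wave speed
#' `|Im lambda(k_star)|/k_star`. Set `printed_formulas = TRUE` to obtain in
#' addition the literal quantities `1/(2*pi*k_star)` and
#' `|Im lambda|/(2*pi*k_star)` under the names `wavelength_alt` and
#' `wave_speed_alt` (both parameterisations are carried in the result).
#'
#' If the growth-rate maximum sits at the lower end of the scan (no interior
#' maximum), the instability is homogeneous and `k_star = 0` is reported.
#'
#' @param fp fixed point (row of [find_fixed_points()] output).
#' @param p,gp parameter objects.
#' @param k_max largest wavenumber scanned, 1/um.
#' @param n_k number of scan points (>= 64).
#' @param printed_formulas also report the alternative printed
#'   parameterisation (see above).
#' @return An object of class `dispersion`: list with `k`, `lambda`
#'   (complex leading branch), `branches` (all three, branch-sorted),
#'   `k_star`, `max_growth`, `wavelength`, `frequency`, `wave_speed`,
#'   `unstable` (logical), and optionally the `_alt` fields.
#' @export
dispersion <- function(fp, p, gp, k_max = 1.5, n_k = 256,
                       printed_formulas = FALSE) {
  stopifnot(n_k >= 64, k_max > 0)
  k_grid <- seq(k_max / n_k, k_max, length.out = n_k)
  br <- branch_sorted_eigen(fp, k_grid, p, gp)
  lead_idx <- max.col(Re(br))
  lead <- br[cbind(seq_len(n_k), lead_idx)]
  i_star <- which.max(Re(lead))
  interior <- i_star > 1 && Re(lead[i_star]) > Re(lead[1]) + 1e-12
  k_star <- if (interior) k_grid[i_star] else 0
  lam_star <- lead[i_star]
  out <- list(k = k_grid, lambda = lead, branches = br,
              k_star = k_star,
              max_growth = Re(lam_star),
              wavelength = if (k_star > 0) 2 * pi / k_star else Inf,
              frequency = abs(Im(lam_star)),
              wave_speed = if (k_star > 0) abs(Im(lam_star)) / k_star else 0,
              unstable = Re(lam_star) > 0)
  if (printed_formulas) {
    out$wavelength_alt <- if (k_star > 0) 1 / (2 * pi * k_star) else Inf
    out$wave_speed_alt <- if (k_star > 0)
      abs(Im(lam_star)) / (2 * pi * k_star) else 0
  }
  class(out) <- "dispersion"
  out
}

#' @export
print.dispersion <- function(x, ...) {
  cat("dispersion relation: k in (0,", max(x$k), "] 1/um\n")
  cat(sprintf("  k* = %.4g 1/um, max growth = %.4g 1/s, %s\n",
              x$k_star, x$max_growth,
              if (x$unstable) "UNSTABLE" else "stable"))
  if (x$k_star > 0)
    cat(sprintf("  wavelength = %.3g um, frequency = %.3g 1/s, speed = %.3g um/s\n",
                x$wavelength, x$frequency, x$wave_speed))
  invisible(x)
}

# reference fixed point for stability analysis: the stable point with the
# lowest r (the branch the quiescent cortex sits on); falls back to the
# lowest-r point if none is stable
reference_fixed_point <- function(p) {
  fp <- find_fixed_points(p)
  st <- fp[fp$stability == "stable", , drop = FALSE]
  if (nrow(st) > 0) st[which.min(st$r), ] else fp[which.min(fp$r), ]
}

#' Linear-stability maps over stimulus and contractility
#'
#' Runs [dispersion()] about the reference homogeneous fixed point (the
#' stable point with lowest RhoA) for every combination of `S` and
#' `sigma_prime`, reporting growth rate, wavelength, frequency and wave
#' speed of the fastest-growing mode.
#'
#' @param S_values basal stimulus values, 1/s.
#' @param sigma_values sigma_prime values, um^2/s.
#' @param p,gp base parameter objects.
#' @param ... forwarded to [dispersion()].
#' @return data.frame with columns `S`, `sigma_prime`, `k_star`,
#'   `max_growth`, `wavelength`, `frequency`, `wave_speed`, `unstable`,
#'   `oscillatory` (finite frequency at `k_star`).
#' @export
stability_map <- function(S_values, sigma_values, p = chem_params(),
                          gp = gel_params(), ...) {
  grid <- expand.grid(S = S_values, sigma_prime = sigma_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pi_ <- p; pi_$S <- grid$S[i]
    gpi <- gp; gpi$sigma_prime <- grid$sigma_prime[i]
    fp <- reference_fixed_point(pi_)
    d <- dispersion(fp, pi_, gpi, ...)
    data.frame(S = pi_$S, sigma_prime = gpi$sigma_prime,
               k_star = d$k_star, max_growth = d$max_growth,
               wavelength = d$wavelength, frequency = d$frequency,
               wave_speed = d$wave_speed, unstable = d$unstable,
               oscillatory = d$frequency > 1e-10)
  })
  do.call(rbind, rows)
}
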