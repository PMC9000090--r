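#' RhoA-GTP production rate
#'
#' Net production rate of active RhoA: basal activation `S`, autocatalytic
#' Hill-type activation saturating at `r_a`, and actomyosin-dependent
#' inactivation saturating at `r_g`,
#' \deqn{R_r(r, m) = S + a \frac{r^n}{r_a^n + r^n} - g\,m \frac{r}{r_g + r}.}
#'
#' @param r RhoA concentration(s), >= 0 (vectorised).
#' @param m actomyosin concentration(s), >= 0 (vectorised).
#' @param p a [chem_params()] object.
#' @return Net rate, 1/s.
#' @export
rr_rate <- function(r, m, p) {
  if (any(r < 0) || any(m < 0)) stop("rr_rate: concentrations must be >= 0")
  auto <- ifelse(r == 0 & p$n > 0, 0, p$a * r^p$n / (p$r_a^p$n + r^p$n))
  p$S + auto - p$g * m * r / (p$r_g + r)
}

#' Actomyosin production rate
#'
#' Net actomyosin assembly rate: basal production `S_m`, RhoA-driven assembly
#' quadratic in `r`, and first-order disassembly,
#' \deqn{R_m(r, m) = S_m + k_a r^2 - k_d m.}
#'
#' @inheritParams rr_rate
#' @return Net rate, 1/s.
#' @export
rm_rate <- function(r, m, p) {
  if (any(r < 0) || any(m < 0)) stop("rm_rate: concentrations must be >= 0")
  p$S_m + p$k_a * r^2 - p$k_d * m
}

#' Nullclines of the reaction system
#'
#' Solves each reaction rate for `m` as a function of `r`. The RhoA
#' nullcline is `m = (S + a r^n/(r_a^n + r^n)) (r_g + r) / (g r)` and is
#' undefined at `r = 0` (returned as `NA` there); the actomyosin nullcline
#' is the parabola `m = (S_m + k_a r^2)/k_d`.
#'
#' @param p a [chem_params()] object.
#' @param r_grid strictly increasing vector of RhoA concentrations (>= 0).
#' @return A data.frame with columns `r`, `m_rr` (RhoA nullcline, `NA` at
#'   r = 0) and `m_rm` (actomyosin nullcline).
#' @export
nullclines <- function(p, r_grid = seq(0, 3, length.out = 301)) {
  if (any(r_grid < 0)) stop("nullclines: r_grid must be >= 0")
  auto <- ifelse(r_grid == 0 & p$n > 0, 0,
                 p$a * r_grid^p$n / (p$r_a^p$n + r_grid^p$n))
  m_rr <- ifelse(r_grid > 0,
                 (p$S + auto) * (p$r_g + r_grid) / (p$g * r_grid), NA_real_)
  m_rm <- (p$S_m + p$k_a * r_grid^2) / p$k_d
  data.frame(r = r_grid, m_rr = m_rr, m_rm = m_rm)
}

#' Jacobian of the reaction-only system
#'
#' The 2x2 Jacobian of `(R_r, R_m)` with respect to `(r, m)`, used for fixed
#' point stability and as the long-wavelength block of the spatial stability
#' problem.
#'
#' @inheritParams rr_rate
#' @return A 2x2 numeric matrix.
#' @export
reaction_jacobian <- function(r, m, p) {
  dauto <- if (r == 0) {
    if (p$n == 1) p$a / p$r_a else if (p$n > 1) 0 else Inf
  } else {
    p$a * p$n * r^(p$n - 1) * p$r_a^p$n / (p$r_a^p$n + r^p$n)^2
  }
  j11 <- dauto - p$g * m * p$r_g / (p$r_g + r)^2
  j12 <- -p$g * r / (p$r_g + r)
  j21 <- 2 * p$k_a * r
  j22 <- -p$k_d
  matrix(c(j11, j21, j12, j22), 2, 2)
}

#' Fixed points of the reaction system
#'
#' Finds all non-negative simultaneous roots of the two reaction rates by
#' substituting the actomyosin nullcline `m(r) = (S_m + k_a r^2)/k_d` into
#' the RhoA rate, bracketing sign changes of the resulting one-dimensional
#' function on a dense grid, and polishing each bracket with
#' [stats::uniroot()]. Stability is classified from the eigenvalues of the
#' 2x2 reaction Jacobian.
#'
#' Fixed points of the reaction system do not depend on any mechanical
#' parameter: strain feedback vanishes at mechanical equilibrium.
#'
#' @param p a [chem_params()] object.
#' @param r_max upper end of the search interval in `r` (default 10;
#'   all observed dynamics live at concentrations of order 1).
#' @param n_grid number of grid points for sign-change bracketing.
#' @param tol residual tolerance for root polishing.
#' @return A data.frame with one row per fixed point: `r`, `m`, `stability`
#'   (`"stable"`, `"unstable"` or `"saddle"`), `oscillatory` (complex
#'   eigenvalues), and eigenvalue real parts `re1`, `re2`. Ordered by `r`.
#' @examples
#' find_fixed_points(chem_params(S = 0.002))  # three fixed points
#' find_fixed_points(chem_params(S = 0.025))  # one fixed point
#' @export
find_fixed_points <- function(p, r_max = 10, n_grid = 4000, tol = 1e-10) {
  h <- function(r) rr_rate(r, (p$S_m + p$k_a * r^2) / p$k_d, p)
  rg <- seq(0, r_max, length.out = n_grid + 1)
  hv <- vapply(rg, h, numeric(1))
  roots <- numeric(0)
  if (abs(hv[1]) <= tol) roots <- c(roots, rg[1])
  sgn <- sign(hv)
  for (i in seq_len(n_grid)) {
    if (sgn[i] == 0 && rg[i] > 0) { roots <- c(roots, rg[i]); next }
    if (sgn[i] * sgn[i + 1] < 0) {
      root <- stats::uniroot(h, c(rg[i], rg[i + 1]), tol = 1e-14)$root
      roots <- c(roots, root)
    }
  }
  # merge duplicates closer than 1e-6
  roots <- sort(roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-6)]
  if (length(roots) == 0) return(
    data.frame(r = numeric(0), m = numeric(0), stability = character(0),
               oscillatory = logical(0), re1 = numeric(0), re2 = numeric(0)))
  out <- lapply(roots, function(r) {
    m <- (p$S_m + p$k_a * r^2) / p$k_d
    if (abs(rr_rate(r, m, p)) > 1e3 * tol)
      warning("find_fixed_points: root polishing left residual > tolerance")
    ev <- eigen(reaction_jacobian(r, m, p), only.values = TRUE)$values
    re <- Re(ev)
    stab <- if (all(re < 0)) "stable"
            else if (all(re > 0)) "unstable"
            else "saddle"
    data.frame(r = r, m = m, stability = stab,
               oscillatory = any(Im(ev) != 0),
               re1 = re[1], re2 = re[2])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
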