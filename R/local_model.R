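#' Right-hand side of the well-mixed mechanochemical model
#'
#' Couples the reaction circuit to a viscoelastic element with strain `u`.
#' Actomyosin compresses the element through a saturating active stress;
#' strain changes feed back on both concentrations through dilution
#' (conservation of mass: `c (1 + u)` is invariant under pure deformation):
#' \deqn{\dot u = (-\sigma_a/E \; m/(m_0+m) - u)/\tau_L,}
#' \deqn{\dot r = R_r(r,m) - r \dot u/(1+u), \quad
#'       \dot m = R_m(r,m) - m \dot u/(1+u).}
#'
#' @param state numeric vector `c(r, m, u)` with `1 + u > 0`.
#' @param p a [chem_params()] object.
#' @param mp a [local_mech_params()] object.
#' @param reactions if `FALSE`, the reaction terms are zeroed (pure
#'   mechanics/dilution; used for conservation checks).
#' @return Numeric vector `c(dr, dm, du)`.
#' @export
local_rhs <- function(state, p, mp, reactions = TRUE) {
  r <- state[[1]]; m <- state[[2]]; u <- state[[3]]
  if (1 + u <= 0) stop("local_rhs: 1 + u <= 0 (model breakdown)")
  du <- (-mp$sigma_over_E * m / (mp$m0 + m) - u) / mp$tau_local
  rc <- max(r, 0); mc <- max(m, 0)
  Rr <- if (reactions) rr_rate(rc, mc, p) else 0
  Rm <- if (reactions) rm_rate(rc, mc, p) else 0
  c(Rr - r * du / (1 + u),
    Rm - m * du / (1 + u),
    du)
}

#' Simulate the well-mixed mechanochemical model
#'
#' Integrates [local_rhs()] with an adaptive Runge-Kutta 4(5) scheme
#' (`deSolve::ode(method = "ode45")`) and samples the trajectory at a fixed
#' output cadence.
#'
#' @param init initial state `c(r, m, u)`. Default: an unstressed empty
#'   cortex `(0, 0, 0)`. Starting with no actomyosin lets basal RhoA
#'   production probe excitability (the inhibitor is initially absent), while
#'   at `S = 0` the state stays truly quiescent with actomyosin rising
#'   monotonically to its basal balance point `S_m/k_d`.
#' @param p a [chem_params()] object.
#' @param mp a [local_mech_params()] object.
#' @param t_end total simulated time, s.
#' @param dt_out output sampling interval, s.
#' @param reactions passed to [local_rhs()].
#' @param atol,rtol integrator tolerances.
#' @return An object of class `local_trajectory`: data.frame with columns
#'   `time`, `r`, `m`, `u`, with `p` and `mp` attached as attributes.
#' @examples
#' tr <- simulate_local(p = chem_params(S = 0.025), t_end = 500)
#' @export
simulate_local <- function(init = NULL, p = chem_params(),
                           mp = local_mech_params(), t_end = 2000,
                           dt_out = 1, reactions = TRUE,
                           atol = 1e-10, rtol = 1e-8) {
  stopifnot(t_end > 0, dt_out > 0)
  if (is.null(init)) init <- c(r = 0, m = 0, u = 0)
  if (length(init) != 3) stop("simulate_local: init must be c(r, m, u)")
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::ode(
    y = c(r = init[[1]], m = init[[2]], u = init[[3]]), times = times,
    func = function(t, y, parms) list(local_rhs(y, p, mp, reactions)),
    parms = NULL, method = "ode45", atol = atol, rtol = rtol)
  df <- as.data.frame(sol)
  if (nrow(df) < length(times))
    warning("simulate_local: integration stopped early at t = ",
            max(df$time), " s; returning partial trajectory")
  if (any(!is.finite(as.matrix(df[, c("r", "m", "u")]))))
    warning("simulate_local: non-finite values in trajectory")
  structure(df, class = c("local_trajectory", "data.frame"), p = p, mp = mp)
}

# Local maxima with a prominence filter. Prominence of a peak is the drop
# from the peak to the higher of the two bracketing minima, measured towards
# the nearest higher peak on each side (adequate for smooth ODE output).
find_peaks_prominent <- function(x, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  keep <- logical(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    # walk left until a value higher than x[i] (or the boundary); track min
    left_min <- x[i]; k <- i
    while (k > 1 && x[k] <= x[i]) { k <- k - 1; left_min <- min(left_min, x[k]) }
    right_min <- x[i]; k <- i
    while (k < n && x[k] <= x[i]) { k <- k + 1; right_min <- min(right_min, x[k]) }
    prom <- x[i] - max(left_min, right_min)
    keep[j] <- prom >= min_prominence
  }
  idx[keep]
}

#' Classify a well-mixed trajectory into a dynamic regime
#'
#' Assigns one of four regimes to a trajectory of the local model:
#' \describe{
#'   \item{quiescent}{monotone (or trivial) approach to a low-actomyosin
#'     steady state, with no large excursion;}
#'   \item{excitable}{a single large pulse, then settling to the
#'     low-concentration stable fixed point;}
#'   \item{pulsatile}{sustained non-decaying oscillations (at least three
#'     prominence-filtered actomyosin maxima after the transient);}
#'   \item{contractile}{settling (possibly via decaying oscillations) to the
#'     high-actomyosin state.}
#' }
#' The high/low branch is decided against the unstable middle fixed point
#' when the reaction system has three fixed points, and by excursion
#' detection otherwise.
#'
#' @param traj a `local_trajectory` from [simulate_local()].
#' @param transient time (s) discarded before analysis; default the first
#'   quarter of the trajectory.
#' @param peak_threshold minimum peak prominence as a fraction of the
#'   actomyosin range over the analysis window (default 0.1).
#' @return An object of class `local_regime`: list with `label` (one of
#'   `"quiescent"`, `"excitable"`, `"pulsatile"`, `"contractile"`),
#'   `confident` (logical) and diagnostic fields.
#' @export
classify_local <- function(traj, transient = NULL, peak_threshold = 0.1) {
  p <- attr(traj, "p")
  t <- traj$time; m <- traj$m; r <- traj$r
  if (is.null(transient)) transient <- 0.25 * max(t)
  if (max(t) <= transient)
    stop("classify_local: trajectory shorter than transient")
  w <- t >= transient
  mw <- m[w]
  rng <- diff(range(mw))
  n_tail <- max(5L, round(0.1 * length(mw)))
  m_final <- mean(utils::tail(mw, n_tail))
  r_final <- mean(utils::tail(r[w], n_tail))

  fp <- find_fixed_points(p)
  high_branch <- function() {
    if (nrow(fp) >= 3) {
      mid <- fp$m[order(fp$r)][2]
      m_final > mid
    } else {
      # single fixed point: high state if the settled actomyosin level is
      # well above the basal balance point S_m/k_d
      m_final > 4 * p$S_m / p$k_d + 0.1
    }
  }
  # large excursion: transient peak well above the settled level
  excursion <- max(m) > m_final + max(0.5 * m_final, 0.05) ||
               max(r) > r_final + max(0.5 * r_final, 0.2)

  settled <- rng < max(1e-6, 1e-3 * max(abs(mw)))
  label <- NULL; confident <- TRUE; n_pk <- 0L
  if (!settled) {
    pk <- find_peaks_prominent(mw, peak_threshold * rng)
    n_pk <- length(pk)
    if (n_pk >= 3) {
      prom_first <- mw[pk[1]] - min(mw[pk[1]:pk[2]])
      prom_last <- mw[pk[n_pk]] - min(mw[pk[n_pk - 1]:pk[n_pk]])
      if (prom_last >= 0.5 * prom_first) label <- "pulsatile"
      else label <- if (high_branch()) "contractile" else "excitable"
    } else {
      # 0-2 peaks in a non-flat window: settling tail of a pulse or decay;
      # decide by the state being approached
      half2 <- mw[seq(ceiling(length(mw) / 2), length(mw))]
      decaying <- diff(range(half2)) < 0.5 * rng
      if (!decaying) confident <- FALSE
      label <- if (high_branch()) "contractile"
               else if (excursion) "excitable" else "quiescent"
    }
  } else {
    label <- if (high_branch()) "contractile"
             else if (excursion) "excitable" else "quiescent"
  }
  structure(list(label = label, confident = confident, n_peaks = n_pk,
                 m_final = m_final, settled = settled),
            class = "local_regime")
}

#' @export
print.local_regime <- function(x, ...) {
  cat("local regime:", x$label,
      if (!x$confident) "(low confidence)" else "", "\n")
  invisible(x)
}

#' Phase diagram of the well-mixed model over two parameters
#'
#' Simulates and classifies the local model on a two-dimensional parameter
#' grid. Either axis may name any field of [chem_params()] (e.g. `"S"`,
#' `"a"`, `"g"`) or of [local_mech_params()] (e.g. `"sigma_over_E"`).
#'
#' @param x_param,y_param parameter names for the two axes.
#' @param x_values,y_values numeric vectors of axis values.
#' @param p,mp base parameter objects; axis values override their fields.
#' @param t_end,dt_out,init passed to [simulate_local()].
#' @param ... passed to [classify_local()].
#' @return A data.frame with columns `x`, `y` (axis values, named after the
#'   parameters), `label` and `confident`; one row per grid cell. Per-cell
#'   failures are recorded as label `"error"` rather than aborting the scan.
#' @export
phase_diagram_local <- function(x_param = "S", x_values,
                                y_param = "sigma_over_E", y_values,
                                p = chem_params(), mp = local_mech_params(),
                                t_end = 2000, dt_out = 1, init = NULL, ...) {
  stopifnot(length(x_values) > 0, length(y_values) > 0)
  set_par <- function(p, mp, name, value) {
    if (name %in% names(p)) p[[name]] <- value
    else if (name %in% names(mp)) mp[[name]] <- value
    else stop("phase_diagram_local: unknown parameter '", name, "'")
    list(p = p, mp = mp)
  }
  grid <- expand.grid(x = x_values, y = y_values)
  lab <- character(nrow(grid)); conf <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pm <- set_par(p, mp, x_param, grid$x[i])
    pm <- set_par(pm$p, pm$mp, y_param, grid$y[i])
    res <- tryCatch({
      tr <- simulate_local(init = init, p = pm$p, mp = pm$mp,
                           t_end = t_end, dt_out = dt_out)
      classify_local(tr, ...)
    }, error = function(e) list(label = "error", confident = FALSE))
    lab[i] <- res$label; conf[i] <- res$confident
  }
  out <- data.frame(grid$x, grid$y, label = lab, confident = conf)
  names(out)[1:2] <- c(x_param, y_param)
  out
}
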