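# circular displacement (in cells) between two frames maximizing correlation
circular_shift_of_max_cor <- function(a, b) {
  N <- length(a)
  # cross-correlation via FFT: c(s) = sum_i a_i b_{i+s}
  cc <- Re(stats::fft(Conj(stats::fft(a - mean(a))) *
                      stats::fft(b - mean(b)), inverse = TRUE)) / N
  s <- which.max(cc) - 1L
  if (s > N / 2) s <- s - N
  s
}

#' Classify the dynamic state of a 1D continuum run
#'
#' Decision tree on a kymograph, applied after discarding a transient:
#' \enumerate{
#'   \item the spatial coefficient of variation of actomyosin separates
#'     uniform states from patterned ones;
#'   \item for uniform states, the temporal dynamics of the spatial mean
#'     separates sustained oscillations (`"oscillatory"`), settling at high
#'     actomyosin (`"homogeneous-contractile"`) and pulse-then-rest
#'     (`"excitable"`);
#'   \item for patterned states, the space-time power spectrum of the
#'     actomyosin kymograph separates stationary peaks (fluctuation power
#'     concentrated at zero temporal frequency: `"localized-contraction"`),
#'     coherently travelling fronts (power concentrated on a few travelling
#'     modes: `"propagating-waves"`) and erratically appearing/disappearing
#'     foci (broadband power: `"pulsatile-flows"`).
#' }
#'
#' @param kymo a `kymograph` from [simulate_1d()].
#' @param transient time discarded before analysis (default: first half).
#' @param cv_threshold spatial coefficient of variation above which the
#'   state counts as patterned (default 0.05).
#' @param stationary_threshold minimum fraction of spatial-fluctuation power
#'   at zero temporal frequency for a stationary pattern (default 0.8).
#' @param coherence_threshold minimum fraction of travelling-fluctuation
#'   power in the four dominant space-time modes for coherent waves
#'   (default 0.2).
#' @return List with `label`, `confident`, and diagnostics (`cv_spatial`,
#'   `n_peaks`, `stationary_fraction`, `wave_coherence`).
#' @export
classify_spatial <- function(kymo, transient = NULL, cv_threshold = 0.05,
                             stationary_threshold = 0.8,
                             coherence_threshold = 0.2) {
  t <- kymo$times
  if (is.null(transient)) transient <- 0.5 * max(t)
  w <- t >= transient
  if (sum(w) < 10) stop("classify_spatial: too few frames past transient")
  M <- kymo$m[w, , drop = FALSE]
  nt <- nrow(M)
  cv_sp <- mean(apply(M, 1, function(z) stats::sd(z) / max(mean(z), 1e-12)))
  mbar <- rowMeans(M)
  label <- NULL; confident <- TRUE
  n_pk <- 0L; stat_frac <- NA_real_; coherence <- NA_real_
  if (cv_sp < cv_threshold) {
    rng <- diff(range(mbar))
    pk <- find_peaks_prominent(mbar, 0.1 * max(rng, 1e-12))
    n_pk <- length(pk)
    m_final <- mean(utils::tail(mbar, max(5, nt %/% 10)))
    if (n_pk >= 3 && rng > 0.05 * m_final) {
      label <- "oscillatory"
    } else {
      # settled uniform state: high branch -> contractile, else excitable
      p <- kymo$p
      high <- m_final > 4 * p$S_m / p$k_d + 0.1
      label <- if (high) "homogeneous-contractile" else "excitable"
      # full-record excursion check distinguishes a fired pulse from rest
      if (!high && max(rowMeans(kymo$m)) < m_final + 0.2) confident <- FALSE
    }
  } else {
    # patterned: space-time power spectrum of the centred kymograph window
    P <- Mod(stats::fft(M - mean(M)))^2
    Pnz <- P[2:(nt - 1), , drop = FALSE]        # temporal frequency != 0
    stat_frac <- sum(P[1, -1]) / (sum(P[1, -1]) + sum(Pnz[, -1]))
    srt <- sort(as.vector(Pnz), decreasing = TRUE)
    coherence <- sum(srt[1:4]) / sum(Pnz)       # wave + conjugate pairs
    if (stat_frac > stationary_threshold) {
      label <- "localized-contraction"
    } else if (coherence > coherence_threshold) {
      label <- "propagating-waves"
    } else {
      label <- "pulsatile-flows"
    }
    near <- function(x, thr) abs(x - thr) < 0.25 * thr
    if (near(stat_frac, stationary_threshold) ||
        (stat_frac <= stationary_threshold &&
         near(coherence, coherence_threshold))) confident <- FALSE
  }
  list(label = label, confident = confident, cv_spatial = cv_sp,
       n_peaks = n_pk, stationary_fraction = stat_frac,
       wave_coherence = coherence)
}

#' Local-activation (memory) experiment
#'
#' Starting from rest with no applied stimulus, applies a boxcar stimulus
#' `S_in` in a central region for a finite time and classifies the response:
#' \describe{
#'   \item{bistable-front}{the activity front propagates past the box and
#'     switches (most of) the domain to the high-RhoA state — spatial memory
#'     of the signal is lost;}
#'   \item{soliton}{two outgoing pulses leave the box and annihilate on the
#'     periodic domain, leaving no pattern — transient memory;}
#'   \item{stable-localized}{a stationary peak persists at the box centre
#'     after the stimulus ends — the location is remembered;}
#'   \item{none}{no pulse was ever excited.}
#' }
#'
#' @param gp a [gel_params()] object (`sigma_prime` is the control knob).
#' @param p a [chem_params()] object; the resting background has `S = 0`.
#' @param S_in stimulus rate inside the box, 1/s (default 0.03).
#' @param box numeric `c(x0, x1)`; default a centred box of width one
#'   hydrodynamic length `lam`.
#' @param t_on,t_off stimulus window, s (default 0 to 100).
#' @param t_end run length, s (default `t_off + 400`).
#' @param threshold RhoA level counting as "active" (default 0.1).
#' @param ... forwarded to [simulate_1d()].
#' @return List with `kymo`, `label`, `active_fraction_end`, `mean_rho`
#'   (spatial mean RhoA 300 s after stimulus onset) and `correlation`
#'   (input-output correlation, see [memory_correlation()]).
#' @export
local_activation_experiment <- function(gp, p = chem_params(S = 0),
                                        S_in = 0.03, box = NULL,
                                        t_on = 0, t_off = 100,
                                        t_end = t_off + 400,
                                        threshold = 0.1, ...) {
  L <- gp$L_over_lam * gp$lam
  if (is.null(box)) box <- (L / 2) + c(-0.5, 0.5) * gp$lam
  stim <- stimulus_boxcar(S_in = S_in, x0 = box[1], x1 = box[2],
                          t_on = t_on, t_off = t_off, S_out = 0)
  N <- gp$N
  rest <- field1d(r = numeric(N), m = rep(p$S_m / p$k_d, N), L = L)
  kymo <- simulate_1d(init = rest, p = p, gp = gp, stim = stim,
                      t_end = t_end, ...)
  r_end <- kymo$r[nrow(kymo$r), ]
  frac <- mean(r_end > threshold)
  ever <- max(kymo$r) > threshold
  label <- if (!ever) "none"
           else if (frac > 0.6) "bistable-front"
           else if (frac < 0.05) "soliton"
           else "stable-localized"
  list(kymo = kymo, label = label, active_fraction_end = frac,
       mean_rho = mean_rho(kymo, t_on + 300),
       correlation = memory_correlation(kymo, stim))
}

#' Input-output correlation of a local-activation run
#'
#' Pearson correlation between the spatial profile of time-averaged RhoA
#' over the final `window` seconds and the boxcar spatial indicator of the
#' stimulus. Returns 0 (by convention) when either signal has zero
#' variance.
#'
#' @param kymo a `kymograph`.
#' @param stim the stimulus protocol (default: the one stored in `kymo`).
#' @param window averaging window before the end of the run, s.
#' @return Correlation in `[-1, 1]`.
#' @export
memory_correlation <- function(kymo, stim = kymo$stim, window = 120) {
  t <- kymo$times
  if (diff(range(t)) < window)
    stop("memory_correlation: run shorter than averaging window")
  w <- t >= max(t) - window
  rprof <- colMeans(kymo$r[w, , drop = FALSE])
  ind <- if (stim$kind == "boxcar")
    as.numeric(kymo$x >= stim$x0 & kymo$x <= stim$x1)
  else rep(stim$S, length(kymo$x))
  if (stats::sd(rprof) == 0 || stats::sd(ind) == 0) return(0)
  stats::cor(rprof, ind)
}

#' Spatial mean RhoA at a given time
#'
#' @param kymo a `kymograph`.
#' @param t evaluation time, s (nearest recorded frame is used).
#' @return Spatial mean of the RhoA field (equals the trapezoidal-rule mean
#'   on the uniform periodic grid).
#' @export
mean_rho <- function(kymo, t) {
  i <- which.min(abs(kymo$times - t))
  mean(kymo$r[i, ])
}
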