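#' Stimulus protocols
#'
#' A stimulus protocol specifies the basal RhoA activation rate `S(x, t)`
#' applied during a continuum simulation. `stimulus_uniform()` applies a
#' constant rate everywhere; `stimulus_boxcar()` applies `S_in` inside the
#' interval `[x0, x1]` during `[t_on, t_off]` and `S_out` elsewhere and at
#' other times (the protocol of the local-activation experiments).
#'
#' @param S,S_in,S_out activation rates, 1/s (>= 0).
#' @param x0,x1 box edges, micrometres (`x0 < x1`).
#' @param t_on,t_off stimulus window, s (`t_on < t_off`).
#' @return An object of class `stimulus`.
#' @examples
#' st <- stimulus_boxcar(S_in = 0.03, x0 = 60, x1 = 80, t_on = 0, t_off = 100)
#' stimulus_rate(st, x = c(50, 70), t = 10)
#' @export
stimulus_uniform <- function(S = 0) {
  stopifnot(S >= 0)
  structure(list(kind = "uniform", S = S), class = "stimulus")
}

#' @rdname stimulus_uniform
#' @export
stimulus_boxcar <- function(S_in, x0, x1, t_on = 0, t_off = Inf, S_out = 0) {
  stopifnot(S_in >= 0, S_out >= 0, x0 < x1, t_on < t_off)
  structure(list(kind = "boxcar", S_in = S_in, S_out = S_out,
                 x0 = x0, x1 = x1, t_on = t_on, t_off = t_off),
            class = "stimulus")
}

#' Evaluate a stimulus protocol
#'
#' @param stim a `stimulus` object.
#' @param x positions (vector or matrix), micrometres. For two-dimensional
#'   runs the boxcar is applied along the first coordinate.
#' @param t time, s.
#' @return `S(x, t)` with the shape of `x`.
#' @export
stimulus_rate <- function(stim, x, t) {
  switch(stim$kind,
    uniform = array(stim$S, dim = if (is.null(dim(x))) length(x) else dim(x)),
    boxcar = {
      inside <- (x >= stim$x0) & (x <= stim$x1) &
        (t >= stim$t_on) & (t <= stim$t_off)
      out <- ifelse(inside, stim$S_in, stim$S_out)
      if (!is.null(dim(x))) dim(out) <- dim(x)
      out
    },
    stop("stimulus_rate: unknown stimulus kind '", stim$kind, "'"))
}

# background (resting) rate of a protocol, used for default initial fields
stimulus_background <- function(stim) {
  if (stim$kind == "uniform") stim$S else stim$S_out
}
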