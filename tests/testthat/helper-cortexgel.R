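# shared helpers for the test suite

# quiet wrappers: clipping warnings from sharp-peak states are expected in
# the strongly contractile regimes exercised here
sim1d_q <- function(...) suppressWarnings(simulate_1d(...))
sim2d_q <- function(...) suppressWarnings(simulate_2d(...))

# a smooth random periodic phase field built from a few Fourier modes of two
# independent scalar fields (its defect set is nonempty and charge-balanced)
random_phase_field <- function(N = 64, n_modes = 4, seed = 1) {
  set.seed(seed)
  ax <- (seq_len(N) - 0.5) / N
  f <- matrix(0, N, N); g <- matrix(0, N, N)
  for (i in seq_len(n_modes)) {
    kx <- sample(-3:3, 2, replace = TRUE); ky <- sample(-3:3, 2, replace = TRUE)
    ph <- runif(4, 0, 2 * pi)
    f <- f + outer(cos(2 * pi * kx[1] * ax + ph[1]),
                   cos(2 * pi * ky[1] * ax + ph[2]))
    g <- g + outer(cos(2 * pi * kx[2] * ax + ph[3]),
                   cos(2 * pi * ky[2] * ax + ph[4]))
  }
  atan2(f, g)
}

# manufactured kymograph with chosen space-time structure
fake_kymo <- function(m, times, L, p = chem_params()) {
  structure(list(times = times, x = (seq_len(ncol(m)) - 0.5) * L / ncol(m),
                 r = m, m = m, v = 0 * m, L = L, dx = L / ncol(m),
                 p = p, gp = gel_params(N = ncol(m)),
                 stim = stimulus_uniform(0), seed = NULL),
            class = "kymograph")
}
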