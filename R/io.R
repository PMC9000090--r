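# known keys per config section
config_schema <- function() {
  list(chemistry = names(chem_params()),
       local_mechanics = names(local_mech_params()),
       gel = names(gel_params()),
       gel2d = names(gel2d_params()),
       stimulus = c("kind", "S", "S_in", "S_out", "x0", "x1", "t_on", "t_off"),
       run = c("t_end", "dt_out", "seed", "r_seed", "amp", "method",
               "dt_max", "record_from"))
}

#' Load a run configuration
#'
#' Parses a plain-text key/value configuration with `[section]` headers
#' (sections: `chemistry`, `local_mechanics`, `gel`, `gel2d`, `stimulus`,
#' `run`; all optional). Unknown sections or keys are errors reported with
#' their line number. Values are numeric except `stimulus.kind` and
#' `run.method`. The parsed configuration round-trips losslessly through
#' [save_config()].
#'
#' @param path file path.
#' @return An object of class `run_config`: named list of section lists,
#'   with materialised parameter objects in attributes `p`, `mp`, `gp`,
#'   `gp2`, `stim`.
#' @export
load_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  schema <- config_schema()
  cfg <- stats::setNames(vector("list", length(schema)), names(schema))
  section <- NULL
  string_keys <- c("kind", "method")
  for (ln in seq_along(lines)) {
    raw <- sub("[#;].*$", "", lines[ln])
    s <- trimws(raw)
    if (s == "") next
    if (grepl("^\\[.*\\]$", s)) {
      section <- gsub("^\\[|\\]$", "", s)
      if (!section %in% names(schema))
        stop("load_config: unknown section '", section, "' at line ", ln)
      next
    }
    if (is.null(section))
      stop("load_config: key outside any [section] at line ", ln)
    kv <- strsplit(s, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("load_config: malformed 'key = value' at line ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% schema[[section]])
      stop("load_config: unknown key '", key, "' in [", section,
           "] at line ", ln)
    cfg[[section]][[key]] <-
      if (key %in% string_keys) val else as.numeric(val)
  }
  materialise_config(cfg)
}

materialise_config <- function(cfg) {
  `%||%` <- function(a, b) if (is.null(a)) b else a
  build <- function(ctor, args) do.call(ctor, args %||% list())
  p <- build(chem_params, cfg$chemistry)
  attr(cfg, "p") <- p
  attr(cfg, "mp") <- build(local_mech_params, cfg$local_mechanics)
  attr(cfg, "gp") <- build(gel_params, cfg$gel)
  attr(cfg, "gp2") <- build(gel2d_params, cfg$gel2d %||% cfg$gel)
  st <- cfg$stimulus
  attr(cfg, "stim") <- if (is.null(st) || identical(st$kind, "uniform")) {
    stimulus_uniform(st$S %||% p$S)
  } else {
    stimulus_boxcar(S_in = st$S_in, x0 = st$x0, x1 = st$x1,
                    t_on = st$t_on %||% 0, t_off = st$t_off %||% Inf,
                    S_out = st$S_out %||% 0)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration
#'
#' Writes a `run_config` (or a plain list of section lists) back to the
#' key/value text format read by [load_config()].
#'
#' @param cfg configuration object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- character(0)
  for (sec in names(cfg)) {
    if (is.null(cfg[[sec]])) next
    out <- c(out, paste0("[", sec, "]"))
    for (key in names(cfg[[sec]])) {
      v <- cfg[[sec]][[key]]
      out <- c(out, paste0(key, " = ",
                           if (is.character(v)) v else format(v, digits = 17)))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Save simulation outputs with provenance
#'
#' Writes a result object (kymograph, field series, trajectory, ...) as an
#' RDS container together with the fully resolved configuration and seed,
#' plus a tabular-text summary alongside (`<path>.tsv` for kymographs and
#' trajectories).
#'
#' @param result simulation output.
#' @param config the `run_config` (or `NULL`).
#' @param path output RDS path.
#' @return `path`, invisibly.
#' @export
save_run <- function(result, config, path) {
  saveRDS(list(result = result, config = config,
               seed = result$seed, package_version =
                 as.character(utils::packageVersion("cortexgel"))), path)
  if (inherits(result, "kymograph"))
    utils::write.table(as.data.frame(result),
                       paste0(path, ".tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (inherits(result, "local_trajectory"))
    utils::write.table(as.data.frame(unclass(result)),
                       paste0(path, ".tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthetic test fixtures
#'
#' Deterministic generator of the synthetic fields used throughout the test
#' suite and for detector validation:
#' \describe{
#'   \item{single-vortex}{phase field `atan2(y - y0, x - x0)`: one +1 defect
#'     (set `charge = -1` for the mirror image);}
#'   \item{vortex-pair}{superposition of a +1 and a -1 vortex (net charge 0,
#'     consistent with the torus);}
#'   \item{plane-wave}{phase `q x` wrapped to the principal branch;}
#'   \item{gaussian-bump}{1D concentration field with Gaussian actomyosin
#'     and RhoA bumps on a resting background;}
#'   \item{noisy-uniform}{1D uniform field with seeded multiplicative
#'     noise.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param N grid points per dimension.
#' @param L domain (edge) length, um.
#' @param seed RNG seed for the noisy kinds.
#' @param ... geometry parameters: `x0`, `y0`, `charge` (single-vortex);
#'   `sep` (vortex-pair); `q` (plane-wave, rad/um); `width`, `height`,
#'   `base_r`, `base_m` (gaussian-bump); `level_r`, `level_m`, `amp`
#'   (noisy-uniform).
#' @return A phase matrix (`phase_field` kinds) or a [field1d()].
#' @export
make_fixture <- function(kind = c("single-vortex", "vortex-pair",
                                  "plane-wave", "gaussian-bump",
                                  "noisy-uniform"),
                         N = 64, L = N, seed = 1, ...) {
  kind <- match.arg(kind)
  dots <- list(...)
  g <- function(name, default) if (is.null(dots[[name]])) default
                               else dots[[name]]
  dx <- L / N
  ax <- (seq_len(N) - 0.5) * dx
  switch(kind,
    "single-vortex" = {
      x0 <- g("x0", L / 2); y0 <- g("y0", L / 2); ch <- g("charge", 1)
      X <- matrix(ax, N, N); Y <- matrix(ax, N, N, byrow = TRUE)
      wrap_angle(ch * atan2(Y - y0, X - x0))
    },
    "vortex-pair" = {
      sep <- g("sep", L / 4)
      X <- matrix(ax, N, N); Y <- matrix(ax, N, N, byrow = TRUE)
      wrap_angle(atan2(Y - L / 2, X - (L / 2 - sep / 2)) -
                 atan2(Y - L / 2, X - (L / 2 + sep / 2)))
    },
    "plane-wave" = {
      q <- g("q", 2 * pi * 2 / L)
      X <- matrix(ax, N, N)
      wrap_angle(q * X)
    },
    "gaussian-bump" = {
      width <- g("width", L / 20); height <- g("height", 1)
      base_r <- g("base_r", 0); base_m <- g("base_m", 0.0918)
      r <- base_r + height * exp(-((ax - L / 2) / width)^2)
      m <- base_m + height * exp(-((ax - L / 2) / width)^2)
      field1d(r = r, m = m, L = L)
    },
    "noisy-uniform" = {
      level_r <- g("level_r", 0.5); level_m <- g("level_m", 0.5)
      amp <- g("amp", 1e-2)
      set.seed(seed)
      r <- level_r * (1 + amp * stats::runif(N, -1, 1))
      m <- level_m * (1 + amp * stats::runif(N, -1, 1))
      field1d(r = r, m = m, L = L)
    })
}
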