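#' Liquid construction hyperparameters
#'
#' Collects every knob that determines how a liquid (the fixed recurrent
#' reservoir) is realized: reservoir size and grid shape, the
#' excitatory/inhibitory split, the distance-dependent connectivity rule
#' `C[type] * exp(-(d / lambda)^2)`, per-type synaptic weight bounds and
#' transmission delays, the input fan-in, the relative strength of
#' input-to-inhibitory weights (the E/I balance knob), and the membrane /
#' adaptation time-constant regimes.
#'
#' Defaults reproduce the standard 2000-neuron cortical-microcircuit liquid:
#' 80% excitatory neurons, `lambda = 2` grid units, connection probability
#' scales `C = (EE 0.3, EI 0.2, IE 0.4, II 0.1)`, recurrent weight upper
#' bounds `(EE 0.6, EI 0.4, IE 1.2, II 0.4)` (uniform draws on `[0, upper]`),
#' delays of 1.0 ms (input), 1.5 ms (EE) and 0.8 ms (EI/IE/II), input fan-in
#' of 7 channels per neuron with weights `U[0, 0.4]` onto excitatory targets
#' and `U[0, inhib_factor * 0.4]` onto inhibitory targets
#' (`inhib_factor = 0.5` gives the classic `U[0, 0.2]`).
#'
#' @param n_neurons Number of liquid neurons.
#' @param dims Integer length-3 grid extents; `NULL` picks the smallest box
#'   with `prod(dims) >= n_neurons` closest to a 1:1:2 aspect ratio
#'   (`c(10, 10, 20)` for 2000 neurons).
#' @param exc_fraction Fraction of excitatory neurons (default 0.8).
#' @param lambda Connectivity length scale in grid units (default 2).
#' @param C Named numeric, connection-probability scale per recurrent synapse
#'   type (`EE`, `EI`, `IE`, `II`).
#' @param recurrent_weight_upper Named numeric, upper bound of the uniform
#'   weight distribution per recurrent synapse type.
#' @param delays_ms Named numeric delays in ms for `input`, `EE`, `EI`, `IE`,
#'   `II` synapses.
#' @param input_in_degree Exact number of distinct input channels feeding each
#'   liquid neuron (default 7).
#' @param input_exc_weight_upper Upper bound of input weights onto excitatory
#'   neurons (default 0.4).
#' @param inhib_factor Width of the input-to-inhibitory weight distribution
#'   relative to the excitatory one; the baseline ratio is 0.5.
#' @param tau_mode Membrane time-constant regime: `"fixed"` (30 ms
#'   everywhere) or `"uniform"` (i.i.d. `U[5, 55]` ms).
#' @param sfa_mode Spike-frequency adaptation regime for excitatory neurons:
#'   `"off"`, `"fixed"` (one `tau_sfa` for all), or `"uniform"`
#'   (i.i.d. `U[50, 1050]` ms).
#' @param tau_fixed_ms,sfa_tau_fixed_ms Values used by the fixed regimes.
#' @param tau_range_ms,sfa_tau_range_ms Ranges used by the uniform regimes.
#'
#' @return An object of class `liquid_spec` (a validated list).
#' @examples
#' spec <- liquid_spec(n_neurons = 100)
#' spec$dims
#' @export
liquid_spec <- function(n_neurons = 2000,
                        dims = NULL,
                        exc_fraction = 0.8,
                        lambda = 2,
                        C = c(EE = 0.3, EI = 0.2, IE = 0.4, II = 0.1),
                        recurrent_weight_upper = c(EE = 0.6, EI = 0.4,
                                                   IE = 1.2, II = 0.4),
                        delays_ms = c(input = 1.0, EE = 1.5, EI = 0.8,
                                      IE = 0.8, II = 0.8),
                        input_in_degree = 7L,
                        input_exc_weight_upper = 0.4,
                        inhib_factor = 0.5,
                        tau_mode = c("fixed", "uniform"),
                        sfa_mode = c("off", "fixed", "uniform"),
                        tau_fixed_ms = 30,
                        tau_range_ms = c(5, 55),
                        sfa_tau_fixed_ms = 550,
                        sfa_tau_range_ms = c(50, 1050)) {
  tau_mode <- match.arg(tau_mode)
  sfa_mode <- match.arg(sfa_mode)
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 1) abort("`n_neurons` must be a positive integer.")
  if (is.null(dims)) dims <- default_grid_dims(n_neurons)
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1)) {
    abort("`dims` must be three positive integers.")
  }
  if (prod(dims) < n_neurons) {
    abort(sprintf(
      "Grid too small: %d sites available on (%s) but %d neurons required.",
      prod(dims), paste(dims, collapse = "x"), n_neurons
    ))
  }
  if (exc_fraction < 0 || exc_fraction > 1) {
    abort("`exc_fraction` must lie in [0, 1].")
  }
  if (lambda <= 0) abort("`lambda` must be positive.")
  C <- C[REC_TYPES]
  recurrent_weight_upper <- recurrent_weight_upper[REC_TYPES]
  if (anyNA(C) || any(C < 0) || any(C > 1)) {
    abort("`C` must give probabilities in [0, 1] for EE, EI, IE, II.")
  }
  if (anyNA(recurrent_weight_upper) || any(recurrent_weight_upper < 0)) {
    abort("`recurrent_weight_upper` must be >= 0 for EE, EI, IE, II.")
  }
  delays_ms <- delays_ms[c("input", REC_TYPES)]
  if (anyNA(delays_ms) || any(delays_ms <= 0)) {
    abort("`delays_ms` must be positive for input, EE, EI, IE, II.")
  }
  if (input_in_degree < 0) abort("`input_in_degree` must be >= 0.")
  if (input_exc_weight_upper < 0 || inhib_factor < 0) {
    abort("Weight bounds must be >= 0.")
  }
  structure(
    list(
      n_neurons = n_neurons, dims = dims, exc_fraction = exc_fraction,
      lambda = lambda, C = C,
      recurrent_weight_upper = recurrent_weight_upper,
      delays_ms = delays_ms,
      input_in_degree = as.integer(input_in_degree),
      input_exc_weight_upper = input_exc_weight_upper,
      inhib_factor = inhib_factor,
      tau_mode = tau_mode, tau_fixed_ms = tau_fixed_ms,
      tau_range_ms = tau_range_ms,
      sfa_mode = sfa_mode, sfa_tau_fixed_ms = sfa_tau_fixed_ms,
      sfa_tau_range_ms = sfa_tau_range_ms
    ),
    class = "liquid_spec"
  )
}

#' @export
print.liquid_spec <- function(x, ...) {
  cat(sprintf(
    "<liquid_spec> %d neurons on %s grid, %.0f%% excitatory\n",
    x$n_neurons, paste(x$dims, collapse = "x"), 100 * x$exc_fraction
  ))
  cat(sprintf("  lambda = %g, C = [%s]\n", x$lambda,
              paste(sprintf("%s %.2g", names(x$C), x$C), collapse = ", ")))
  cat(sprintf("  input fan-in %d, inhib_factor %.3g, tau %s, SFA %s\n",
              x$input_in_degree, x$inhib_factor, x$tau_mode, x$sfa_mode))
  invisible(x)
}

# Smallest integer box with prod >= n whose aspect is nearest 1:1:2
# (a x a x 2a); yields c(10, 10, 20) for n = 2000.
default_grid_dims <- function(n) {
  a <- max(1L, floor((n / 2)^(1 / 3)))
  repeat {
    if (a * a * 2L * a >= n) break
    a <- a + 1L
  }
  best <- c(a, a, 2L * a)
  # shave the last axis if a flatter box still fits
  z <- ceiling(n / (a * a))
  if (a * a * z >= n && z <= 2L * a) best <- c(a, a, as.integer(z))
  as.integer(best)
}

#' Read or write a liquid specification as YAML
#'
#' @param spec A [liquid_spec()].
#' @param path File path.
#' @return `read_liquid_spec()` returns a `liquid_spec`;
#'   `write_liquid_spec()` returns `path` invisibly.
#' @export
write_liquid_spec <- function(spec, path) {
  stopifnot(inherits(spec, "liquid_spec"))
  x <- unclass(spec)
  x$C <- as.list(x$C)
  x$recurrent_weight_upper <- as.list(x$recurrent_weight_upper)
  x$delays_ms <- as.list(x$delays_ms)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_liquid_spec
#' @export
read_liquid_spec <- function(path) {
  x <- yaml::read_yaml(path)
  liquid_spec(
    n_neurons = x$n_neurons, dims = unlist(x$dims),
    exc_fraction = x$exc_fraction, lambda = x$lambda,
    C = unlist(x$C),
    recurrent_weight_upper = unlist(x$recurrent_weight_upper),
    delays_ms = unlist(x$delays_ms),
    input_in_degree = x$input_in_degree,
    input_exc_weight_upper = x$input_exc_weight_upper,
    inhib_factor = x$inhib_factor,
    tau_mode = x$tau_mode, tau_fixed_ms = x$tau_fixed_ms,
    tau_range_ms = unlist(x$tau_range_ms),
    sfa_mode = x$sfa_mode, sfa_tau_fixed_ms = x$sfa_tau_fixed_ms,
    sfa_tau_range_ms = unlist(x$sfa_tau_range_ms)
  )
}
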