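#' Place neurons on a 3D integer grid
#'
#' Fills lattice sites in deterministic raster order (x fastest, then y,
#' then z) so that neuron i always lands on the same site for given `dims`.
#'
#' @param n Number of neurons.
#' @param dims Integer length-3 grid extents (unit spacing).
#' @return A tibble with columns `id`, `x`, `y`, `z` (0-based coordinates).
#' @examples
#' place_on_grid(8, c(2, 2, 2))
#' @export
place_on_grid <- function(n, dims) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3)
  if (prod(dims) < n) {
    abort(sprintf(
      "Grid too small: %d neurons requested but only %d sites on (%s).",
      n, prod(dims), paste(dims, collapse = "x")
    ))
  }
  idx <- seq_len(n) - 1L
  tibble(
    id = seq_len(n),
    x = idx %% dims[1],
    y = (idx %/% dims[1]) %% dims[2],
    z = idx %/% (dims[1] * dims[2])
  )
}

#' Label neurons excitatory or inhibitory
#'
#' Exactly `round(n * exc_fraction)` neurons are excitatory; which ones is
#' randomized (no spatial clustering of the inhibitory population).
#'
#' @param n Number of neurons.
#' @param exc_fraction Fraction excitatory, in \[0, 1\].
#' @param seed Optional integer seed for the assignment.
#' @return Logical vector of length `n`, `TRUE` = excitatory.
#' @export
split_ei <- function(n, exc_fraction = 0.8, seed = NULL) {
  stopifnot(exc_fraction >= 0, exc_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_exc <- round(n * exc_fraction)
  is_exc <- rep(FALSE, n)
  is_exc[sample.int(n, n_exc)] <- TRUE
  is_exc
}

#' Distance-dependent connection probability
#'
#' The probability of a recurrent synapse from neuron i to neuron j is
#' `C[type] * exp(-(d / lambda)^2)` where `d` is the Euclidean distance
#' between their grid sites, clamped to \[0, 1\].
#'
#' @param d Euclidean distance(s) in grid units, `>= 0`.
#' @param syn_type One of `"EE"`, `"EI"`, `"IE"`, `"II"` (source, target).
#' @param lambda Length scale (> 0).
#' @param C Named probability scales as in [liquid_spec()].
#' @return Probability vector the length of `d`.
#' @examples
#' connection_probability(2, "EE", lambda = 2) # 0.3 * exp(-1)
#' @export
connection_probability <- function(d, syn_type, lambda = 2,
                                   C = c(EE = 0.3, EI = 0.2,
                                         IE = 0.4, II = 0.1)) {
  if (any(d < 0)) abort("`d` must be >= 0.")
  if (lambda <= 0) abort("`lambda` must be > 0.")
  if (!all(syn_type %in% REC_TYPES)) {
    abort(sprintf("Unknown synapse type: %s",
                  paste(setdiff(syn_type, REC_TYPES), collapse = ", ")))
  }
  pmin(pmax(unname(C[syn_type]) * exp(-(d / lambda)^2), 0), 1)
}

#' Sample a recurrent synaptic weight
#'
#' Weights are uniform on `[0, upper]` with the upper bound set by synapse
#' type. All weights are non-negative; the inhibitory effect of I-source
#' synapses is carried by the synapse type, not the sign.
#'
#' @param syn_type Recurrent synapse type(s).
#' @param upper Named upper bounds as in [liquid_spec()].
#' @param n Number of draws per element of `syn_type` recycled jointly.
#' @return Numeric weights.
#' @export
sample_recurrent_weight <- function(syn_type,
                                    upper = c(EE = 0.6, EI = 0.4,
                                              IE = 1.2, II = 0.4),
                                    n = length(syn_type)) {
  stopifnot(all(syn_type %in% REC_TYPES))
  runif(n) * unname(upper[syn_type])
}

# Pairwise squared Euclidean distance between grid sites (n x n dense).
pairwise_dist <- function(pos) {
  m <- as.matrix(pos[, c("x", "y", "z")])
  d2 <- outer(rowSums(m^2), rowSums(m^2), "+") - 2 * tcrossprod(m)
  sqrt(pmax(d2, 0))
}

rec_type_of <- function(pre_exc, post_exc) {
  paste0(ifelse(pre_exc, "E", "I"), ifelse(post_exc, "E", "I"))
}

#' Realize the recurrent synapse table
#'
#' Every ordered pair (i, j), i != j, becomes a synapse independently with
#' probability [connection_probability()]; weights are uniform draws bounded
#' per type and delays are the per-type constants. With `lambda = 2` and the
#' default `C`, a 2000-neuron liquid on a 10x10x20 grid realizes about 9.5
#' recurrent synapses per neuron.
#'
#' @param population Neuron tibble from [place_on_grid()] with an
#'   `is_excitatory` column.
#' @param spec A [liquid_spec()].
#' @param seed Optional seed.
#' @return Synapse tibble: `pre`, `post`, `weight`, `delay_ms`, `type`.
#' @export
build_recurrent_synapses <- function(population, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(population)
  d <- pairwise_dist(population)
  is_exc <- population$is_excitatory
  type_mat <- matrix(rec_type_of(rep(is_exc, times = n),
                                 rep(is_exc, each = n)),
                     nrow = n) # [pre, post]
  p <- matrix(connection_probability(as.vector(d), as.vector(type_mat),
                                     spec$lambda, spec$C), nrow = n)
  diag(p) <- 0 # no self-loops
  hit <- which(matrix(runif(n * n), n) < p)
  pre <- (hit - 1L) %% n + 1L
  post <- (hit - 1L) %/% n + 1L
  type <- type_mat[hit]
  tibble(
    pre = pre, post = post,
    weight = sample_recurrent_weight(type, spec$recurrent_weight_upper),
    delay_ms = unname(spec$delays_ms[type]),
    type = type
  )
}

#' Wire input channels into the liquid
#'
#' Each liquid neuron receives exactly `input_in_degree` synapses from
#' distinct, uniformly chosen input channels. Input synapses are always
#' excitatory-acting; weights are `U[0, 0.4]` onto excitatory targets and
#' `U[0, inhib_factor * 0.4]` onto inhibitory targets (the baseline
#' `inhib_factor = 0.5` gives `U[0, 0.2]`), delay 1 ms.
#'
#' @param n_channels Number of input channels available.
#' @param population Neuron tibble with `is_excitatory`.
#' @param spec A [liquid_spec()].
#' @param seed Optional seed.
#' @return Synapse tibble with `pre` = channel index (1-based), `type` in
#'   `"input-E"` / `"input-I"` (named for the target population).
#' @export
build_input_synapses <- function(n_channels, population, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- spec$input_in_degree
  if (k == 0) {
    return(tibble(pre = integer(), post = integer(), weight = numeric(),
                  delay_ms = numeric(), type = character()))
  }
  if (k > n_channels) {
    abort(sprintf(
      "Input in-degree %d exceeds the %d available channels.", k, n_channels
    ))
  }
  n <- nrow(population)
  pre <- as.integer(vapply(seq_len(n),
                           function(i) sample.int(n_channels, k),
                           integer(k)))
  post <- rep(population$id, each = k)
  target_exc <- rep(population$is_excitatory, each = k)
  upper <- ifelse(target_exc,
                  spec$input_exc_weight_upper,
                  spec$inhib_factor * spec$input_exc_weight_upper)
  tibble(
    pre = pre, post = post,
    weight = runif(n * k) * upper,
    delay_ms = unname(spec$delays_ms[["input"]]),
    type = ifelse(target_exc, "input-E", "input-I")
  )
}

#' Assign membrane and adaptation time constants
#'
#' Membrane time constants are either 30 ms everywhere (`"fixed"`) or
#' i.i.d. `U[5, 55]` ms (`"uniform"`, same 30 ms mean). Adaptation time
#' constants `tau_sfa` are assigned to excitatory neurons only: one shared
#' value (`"fixed"`) or i.i.d. `U[50, 1050]` ms (`"uniform"`); `NA` when
#' adaptation is off and for inhibitory neurons.
#'
#' @param population Neuron tibble with `is_excitatory`.
#' @param spec A [liquid_spec()] carrying the tau/SFA modes.
#' @param seed Optional seed.
#' @return `population` with `tau_m` and `tau_sfa` columns.
#' @export
assign_time_constants <- function(population, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(population)
  population$tau_m <- switch(spec$tau_mode,
    fixed = rep(spec$tau_fixed_ms, n),
    uniform = runif(n, spec$tau_range_ms[1], spec$tau_range_ms[2])
  )
  tau_sfa <- rep(NA_real_, n)
  if (spec$sfa_mode != "off") {
    e <- population$is_excitatory
    tau_sfa[e] <- switch(spec$sfa_mode,
      fixed = spec$sfa_tau_fixed_ms,
      uniform = runif(sum(e), spec$sfa_tau_range_ms[1],
                      spec$sfa_tau_range_ms[2])
    )
  }
  population$tau_sfa <- tau_sfa
  population
}

#' Build a complete liquid
#'
#' Runs the full construction pipeline: grid placement, E/I labeling,
#' time-constant assignment, recurrent wiring and input wiring. All
#' randomness flows from `seed`; the build is reproducible bit-for-bit.
#'
#' @param spec A [liquid_spec()].
#' @param n_channels Number of input channels the liquid will listen to.
#' @param seed Integer seed.
#' @return An object of class `elsm_liquid`: a list with `neurons` (tibble:
#'   `id`, `x`, `y`, `z`, `is_excitatory`, `tau_m`, `tau_sfa`), `synapses`
#'   (recurrent + input rows), `n_channels`, `spec`, `seed`.
#' @examples
#' liq <- build_liquid(liquid_spec(n_neurons = 50), n_channels = 10, seed = 1)
#' liq
#' @export
build_liquid <- function(spec, n_channels, seed = 1L) {
  stopifnot(inherits(spec, "liquid_spec"))
  set.seed(seed)
  neurons <- place_on_grid(spec$n_neurons, spec$dims)
  neurons$is_excitatory <- split_ei(spec$n_neurons, spec$exc_fraction)
  neurons <- assign_time_constants(neurons, spec)
  recurrent <- build_recurrent_synapses(neurons, spec)
  input <- build_input_synapses(n_channels, neurons, spec)
  structure(
    list(
      neurons = neurons,
      synapses = dplyr::bind_rows(input, recurrent),
      n_channels = as.integer(n_channels),
      spec = spec,
      seed = as.integer(seed)
    ),
    class = "elsm_liquid"
  )
}

#' @export
print.elsm_liquid <- function(x, ...) {
  n_rec <- sum(x$synapses$type %in% REC_TYPES)
  n_in <- nrow(x$synapses) - n_rec
  cat(sprintf(
    "<elsm_liquid> %d neurons (%d excitatory), %d channels\n",
    nrow(x$neurons), sum(x$neurons$is_excitatory), x$n_channels
  ))
  cat(sprintf("  %d recurrent synapses (%.2f per neuron), %d input synapses\n",
              n_rec, n_rec / nrow(x$neurons), n_in))
  cat(sprintf("  tau %s, SFA %s, inhib_factor %.3g, seed %d\n",
              x$spec$tau_mode, x$spec$sfa_mode, x$spec$inhib_factor, x$seed))
  invisible(x)
}

#' Mean number of recurrent synapses per neuron
#'
#' @param liquid An `elsm_liquid`.
#' @return Total recurrent synapse rows divided by the neuron count.
#' @export
recurrent_degree <- function(liquid) {
  sum(liquid$synapses$type %in% REC_TYPES) / nrow(liquid$neurons)
}

#' Rescale the input-to-inhibitory weight distribution
#'
#' Changes only the magnitudes of existing input synapses onto inhibitory
#' neurons, multiplying each by `factor / old_factor`. Because the original
#' draws are uniform on `[0, old_factor * 0.4]`, the rescaled weights
#' are exactly uniform on the new support: the liquid is identical to one
#' rebuilt from the same seed at the new factor, with topology, delays and
#' every other weight untouched.
#'
#' @param liquid An `elsm_liquid`.
#' @param factor New relative width of the input-inhibitory distribution.
#' @return The modified liquid.
#' @export
set_inhib_factor <- function(liquid, factor) {
  stopifnot(factor >= 0)
  old <- liquid$spec$inhib_factor
  sel <- liquid$synapses$type == "input-I"
  if (old == 0) {
    if (factor != 0 && any(sel)) {
      abort("Cannot rescale from inhib_factor 0; rebuild the liquid.")
    }
  } else {
    liquid$synapses$weight[sel] <- liquid$synapses$weight[sel] * factor / old
  }
  liquid$spec$inhib_factor <- factor
  liquid
}

# Upper bound of the sampling support for each synapse type in this liquid.
weight_upper_bounds <- function(spec) {
  c(
    `input-E` = spec$input_exc_weight_upper,
    `input-I` = spec$inhib_factor * spec$input_exc_weight_upper,
    spec$recurrent_weight_upper
  )
}

#' Quantize synaptic weights to a low-bit uniform grid
#'
#' Per synapse type, weights snap to the nearest of `2^bits` uniformly
#' spaced levels spanning `[0, upper]`, where `upper` is that type's
#' sampling bound. The mapping is idempotent and the rounding error is at
#' most `upper / (2 * (2^bits - 1))` per synapse. `bits >= 53` is treated
#' as full double precision (identity).
#'
#' @param liquid An `elsm_liquid` (or a bare synapse tibble plus `uppers`).
#' @param bits Number of weight bits (default 4).
#' @param uppers Optional named upper bounds; defaults to the liquid's own.
#' @return The liquid (or table) with quantized weights.
#' @examples
#' liq <- build_liquid(liquid_spec(n_neurons = 50), n_channels = 10, seed = 1)
#' q <- quantize_weights(liq, bits = 4)
#' length(unique(q$synapses$weight[q$synapses$type == "EE"])) <= 16
#' @export
quantize_weights <- function(liquid, bits = 4L, uppers = NULL) {
  stopifnot(bits >= 1)
  if (inherits(liquid, "elsm_liquid")) {
    liquid$synapses <- quantize_weights(liquid$synapses, bits,
                                        weight_upper_bounds(liquid$spec))
    return(liquid)
  }
  tab <- liquid
  if (bits >= 53) return(tab)
  if (is.null(uppers)) abort("`uppers` is required for a bare synapse table.")
  up <- unname(uppers[tab$type])
  if (anyNA(up)) abort("Missing upper bound for some synapse type.")
  n_levels <- 2^bits - 1
  w <- tab$weight
  q <- ifelse(up > 0, round(w / up * n_levels) / n_levels * up, 0)
  tab$weight <- q
  tab
}
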