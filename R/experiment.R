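#' End-to-end experiment configuration
#'
#' Bundles every stage of a full run: the liquid construction
#' hyperparameters, the synthetic dataset (or pre-made rasters), the
#' simulation clock, the balance sweep grid, and the readout grid. Stages
#' execute in the standard order: balance sweep first, then adaptation and
#' time-constant heterogeneity are switched on, then the readout is
#' trained.
#'
#' @param liquid A [liquid_spec()]. Its `sfa_mode` / `tau_mode` define the
#'   final (extended) configuration; the baseline stage always runs with
#'   adaptation off and fixed membrane time constants.
#' @param dataset A [template_dataset_spec()] or a ready dataset from
#'   [make_template_dataset()].
#' @param sim A [sim_config()].
#' @param balance_factors Factor grid for the sweep (`NULL` skips the
#'   sweep and keeps `liquid$inhib_factor`).
#' @param balance_seeds Liquid initializations per factor in the sweep.
#' @param n_probe Probe samples (taken from the training split) for the
#'   sweep.
#' @param reg_grid Readout inverse-regularization grid.
#' @param quantize_bits Optional weight resolution (e.g. 4); `NULL` keeps
#'   full precision.
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(liquid = liquid_spec(n_neurons = 500,
                                                   tau_mode = "uniform",
                                                   sfa_mode = "uniform"),
                              dataset = template_dataset_spec(),
                              sim = sim_config(),
                              balance_factors = c(0.5, 1, 2, 3),
                              balance_seeds = 2,
                              n_probe = 10,
                              reg_grid = c(0.01, 0.1, 1, 10),
                              quantize_bits = NULL,
                              seed = 1L) {
  structure(
    list(liquid = liquid, dataset = dataset, sim = sim,
         balance_factors = balance_factors,
         balance_seeds = balance_seeds, n_probe = n_probe,
         reg_grid = reg_grid, quantize_bits = quantize_bits,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# Simulate every raster of a split and return features + mean spikes/neuron.
simulate_split <- function(liquid, rasters, sim_cfg, seed) {
  exc_ids <- which(liquid$neurons$is_excitatory)
  spn <- numeric(length(rasters))
  feats <- matrix(0L, length(rasters), length(exc_ids))
  for (i in seq_along(rasters)) {
    cfg <- sim_cfg
    cfg$seed <- seed + i
    sim <- simulate_liquid(liquid, rasters[[i]], cfg)
    spn[i] <- spikes_per_neuron(sim)
    feats[i, ] <- extract_features(sim$raster, exc_ids)
  }
  list(features = feats, spikes_per_neuron = mean(spn))
}

# One build -> simulate -> train -> evaluate pass for a fixed spec.
run_pipeline <- function(spec, dataset, sim_cfg, reg_grid, seed,
                         quantize_bits = NULL) {
  liquid <- build_liquid(spec, dataset$spec$n_channels, seed = seed)
  if (!is.null(quantize_bits)) {
    liquid <- quantize_weights(liquid, bits = quantize_bits)
  }
  tr <- simulate_split(liquid, dataset$train$rasters, sim_cfg, seed)
  te <- simulate_split(liquid, dataset$test$rasters, sim_cfg,
                       seed + length(dataset$train$rasters))
  model <- fit_readout(tr$features, dataset$train$labels,
                       reg_grid = reg_grid, seed = seed)
  list(
    liquid = liquid, model = model,
    train_accuracy = evaluate_readout(model, tr$features,
                                      dataset$train$labels),
    test_accuracy = evaluate_readout(model, te$features,
                                     dataset$test$labels),
    spikes_per_neuron = mean(c(tr$spikes_per_neuron, te$spikes_per_neuron))
  )
}

variant_spec <- function(spec, variant, balanced_factor) {
  v <- spec
  if (variant %in% c("B")) v$inhib_factor <- 0.5
  if (variant %in% c("B+E/I", "B+E/I+SFA", "ELSM")) {
    v$inhib_factor <- balanced_factor
  }
  v$sfa_mode <- if (variant %in% c("B+E/I+SFA", "ELSM")) spec$sfa_mode
                else "off"
  if (v$sfa_mode == "off" && variant %in% c("B+E/I+SFA", "ELSM")) {
    v$sfa_mode <- "uniform"
  }
  v$tau_mode <- if (variant == "ELSM") spec$tau_mode else "fixed"
  if (variant == "ELSM" && v$tau_mode == "fixed") v$tau_mode <- "uniform"
  v
}

#' Run a full experiment
#'
#' Executes the pipeline in the standard order: (1) sweep the
#' input-inhibitory factor on probe samples and select the balanced value,
#' (2) build the requested model variants, (3) simulate the dataset,
#' train the spike-count readout and evaluate. `variants` defaults to the
#' full ablation: the baseline liquid (`"B"`), balanced inputs
#' (`"B+E/I"`), plus adaptation (`"B+E/I+SFA"`), plus heterogeneous
#' membrane time constants (`"ELSM"`).
#'
#' @param config An [experiment_config()].
#' @param variants Character subset of `c("B", "B+E/I", "B+E/I+SFA",
#'   "ELSM")`.
#' @return An `elsm_experiment` list: `report` (one tibble row per
#'   variant: `variant`, `test_accuracy`, `train_accuracy`,
#'   `spikes_per_neuron`, `inhib_factor`, `sfa_mode`, `tau_mode`, `seed`),
#'   `balance` (the sweep table, or `NULL`), `selected_factor`, `runs`
#'   (fitted models and liquids), and the config.
#' @examples
#' \donttest{
#' cfg <- experiment_config(
#'   liquid = liquid_spec(n_neurons = 120, tau_mode = "uniform",
#'                        sfa_mode = "uniform"),
#'   dataset = template_dataset_spec(n_train = 4, n_test = 2),
#'   balance_factors = c(0.5, 2), balance_seeds = 1, n_probe = 3
#' )
#' run_experiment(cfg, variants = c("B", "ELSM"))$report
#' }
#' @export
run_experiment <- function(config,
                           variants = c("B", "B+E/I", "B+E/I+SFA", "ELSM")) {
  stopifnot(inherits(config, "experiment_config"))
  variants <- match.arg(variants, several.ok = TRUE)
  dataset <- config$dataset
  if (inherits(dataset, "template_dataset_spec")) {
    dataset <- make_template_dataset(dataset)
  }
  balance <- NULL
  factor_sel <- config$liquid$inhib_factor
  if (!is.null(config$balance_factors)) {
    probes <- head(dataset$train$rasters,
                   min(config$n_probe, length(dataset$train$rasters)))
    sweep_spec <- config$liquid
    sweep_spec$sfa_mode <- "off" # balance is set before the other extensions
    sweep_spec$tau_mode <- "fixed"
    balance <- sweep_inhib_factor(
      sweep_spec, probes, factors = config$balance_factors,
      n_seeds = config$balance_seeds, config = config$sim,
      seeds = config$seed + seq_len(config$balance_seeds) - 1L
    )
    factor_sel <- select_balanced_factor(balance)
  }
  runs <- lapply(variants, function(v) {
    spec_v <- variant_spec(config$liquid, v, factor_sel)
    res <- run_pipeline(spec_v, dataset, config$sim, config$reg_grid,
                        config$seed, config$quantize_bits)
    res$variant <- v
    res$spec <- spec_v
    res
  })
  names(runs) <- variants
  report <- purrr::map_dfr(runs, function(r) {
    tibble(
      variant = r$variant,
      test_accuracy = r$test_accuracy,
      train_accuracy = r$train_accuracy,
      spikes_per_neuron = r$spikes_per_neuron,
      inhib_factor = r$spec$inhib_factor,
      sfa_mode = r$spec$sfa_mode,
      tau_mode = r$spec$tau_mode,
      seed = config$seed
    )
  })
  structure(
    list(report = report, balance = balance,
         selected_factor = factor_sel, runs = runs, config = config,
         dataset = dataset),
    class = "elsm_experiment"
  )
}

#' @export
print.elsm_experiment <- function(x, ...) {
  cat(sprintf("<elsm_experiment> selected inhib_factor %.3g, seed %d\n",
              x$selected_factor, x$config$seed))
  print(x$report)
  invisible(x)
}

#' @rdname run_experiment
#' @param x An `elsm_experiment`.
#' @param ... Unused.
#' @export
tidy.elsm_experiment <- function(x, ...) x$report

#' @rdname run_experiment
#' @export
glance.elsm_experiment <- function(x, ...) {
  tibble(
    n_variants = nrow(x$report),
    selected_factor = x$selected_factor,
    best_accuracy = max(x$report$test_accuracy),
    seed = x$config$seed
  )
}
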