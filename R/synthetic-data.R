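#' Specification of a class-structured synthetic spike dataset
#'
#' Describes a template-based generator for multi-channel spike patterns:
#' each class is one fixed random (channel, time) template; samples are the
#' template with Gaussian time jitter and independent event deletion. The
#' defaults produce a moderately hard 5-class task with the shape of
#' binned audio event data: 40 channels, 250 ms at millisecond resolution,
#' 120 events per template, 10 ms jitter, 20% event dropout, 12 training
#' and 6 test samples per class.
#'
#' @param n_classes,n_channels,duration_ms,events_per_template Structure of
#'   the templates.
#' @param jitter_sd_ms Gaussian jitter SD applied per event, ms (>= 0).
#' @param drop_prob Independent deletion probability per event, in `[0, 1)`.
#' @param n_train,n_test Samples per class.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `template_dataset_spec` list.
#' @export
template_dataset_spec <- function(n_classes = 5, n_channels = 40,
                                  duration_ms = 250,
                                  events_per_template = 120,
                                  jitter_sd_ms = 10, drop_prob = 0.2,
                                  n_train = 12, n_test = 6, seed = 1L) {
  stopifnot(jitter_sd_ms >= 0, drop_prob >= 0, drop_prob < 1,
            n_classes >= 1, n_channels >= 1, events_per_template >= 1)
  structure(
    list(n_classes = n_classes, n_channels = n_channels,
         duration_ms = duration_ms,
         events_per_template = events_per_template,
         jitter_sd_ms = jitter_sd_ms, drop_prob = drop_prob,
         n_train = n_train, n_test = n_test, seed = as.integer(seed)),
    class = "template_dataset_spec"
  )
}

sample_from_template <- function(template, spec) {
  keep <- runif(nrow(template)) >= spec$drop_prob
  ev <- template[keep, , drop = FALSE]
  t_j <- ev$t_ms + stats::rnorm(nrow(ev), 0, spec$jitter_sd_ms)
  ev$t_ms <- pmin(pmax(t_j, 0), spec$duration_ms)
  spike_raster(ev, n_sources = spec$n_channels,
               duration_ms = spec$duration_ms)
}

#' Generate a template-based synthetic spike dataset
#'
#' Draws one random template per class, then jittered/thinned samples for
#' the train and test splits. Identical `spec` (including its seed) gives
#' byte-identical datasets.
#'
#' @param spec A [template_dataset_spec()].
#' @return A list with `train` / `test` (each: `rasters` — list of
#'   [spike_raster()] — and `labels`, a factor), plus `templates` and the
#'   spec.
#' @examples
#' ds <- make_template_dataset(template_dataset_spec(n_train = 2, n_test = 1))
#' table(ds$train$labels)
#' @export
make_template_dataset <- function(spec = template_dataset_spec()) {
  set.seed(spec$seed)
  templates <- lapply(seq_len(spec$n_classes), function(cl) {
    tibble(
      source = sample.int(spec$n_channels, spec$events_per_template,
                          replace = TRUE),
      t_ms = runif(spec$events_per_template, 0, spec$duration_ms)
    )
  })
  draw_split <- function(n_per_class) {
    rasters <- list()
    labels <- integer(0)
    for (cl in seq_len(spec$n_classes)) {
      for (s in seq_len(n_per_class)) {
        rasters[[length(rasters) + 1L]] <-
          sample_from_template(templates[[cl]], spec)
        labels <- c(labels, cl)
      }
    }
    list(rasters = rasters, labels = factor(labels))
  }
  list(
    train = draw_split(spec$n_train),
    test = draw_split(spec$n_test),
    templates = templates,
    spec = spec
  )
}

#' Generate smooth random cochleogram-like signals
#'
#' Per channel: a Gaussian random walk smoothed by a moving average of
#' width `smoothness` frames, then rescaled to `[0, 1]` (constant channels
#' map to 0). Used as encoder test input.
#'
#' @param n_channels,n_frames Matrix shape (`n_frames >= 2`).
#' @param smoothness Moving-average window in frames; 0 or 1 leaves the
#'   raw walk.
#' @param seed Optional seed.
#' @return A channels x frames matrix with values in `[0, 1]`.
#' @export
make_float_signals <- function(n_channels = 8, n_frames = 100,
                               smoothness = 5, seed = NULL) {
  stopifnot(n_frames >= 2)
  if (!is.null(seed)) set.seed(seed)
  t(vapply(seq_len(n_channels), function(ch) {
    x <- cumsum(stats::rnorm(n_frames))
    if (smoothness > 1) {
      x <- as.numeric(stats::filter(x, rep(1 / smoothness, smoothness),
                                    sides = 2))
      x <- zoo_na_fill(x) # moving average leaves NAs at the edges
    }
    rng <- range(x)
    if (diff(rng) == 0) rep(0, n_frames) else (x - rng[1]) / diff(rng)
  }, numeric(n_frames)))
}

# fill leading/trailing NAs with nearest non-NA value
zoo_na_fill <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) == 0) return(rep(0, length(x)))
  x[seq_len(ok[1] - 1)] <- x[ok[1]]
  last <- ok[length(ok)]
  if (last < length(x)) x[(last + 1):length(x)] <- x[last]
  x
}
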