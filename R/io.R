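#' Serialize a realized liquid to a directory of plain-text files
#'
#' Writes `neurons.csv` (id, x, y, z, is_excitatory, tau_m, tau_sfa),
#' `synapses.csv` (pre, post, weight, delay_ms, type), `spec.yaml` and
#' `meta.yaml` (channel count, seed). `read_liquid()` restores an
#' identical `elsm_liquid`.
#'
#' @param liquid An `elsm_liquid`.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly / the restored liquid.
#' @export
write_liquid <- function(liquid, dir) {
  stopifnot(inherits(liquid, "elsm_liquid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(liquid$neurons),
            file.path(dir, "neurons.csv"), row.names = FALSE)
  write.csv(as.data.frame(liquid$synapses),
            file.path(dir, "synapses.csv"), row.names = FALSE)
  write_liquid_spec(liquid$spec, file.path(dir, "spec.yaml"))
  yaml::write_yaml(list(n_channels = liquid$n_channels, seed = liquid$seed),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_liquid
#' @export
read_liquid <- function(dir) {
  neurons <- as_tibble(read.csv(file.path(dir, "neurons.csv")))
  neurons$is_excitatory <- as.logical(neurons$is_excitatory)
  synapses <- as_tibble(read.csv(file.path(dir, "synapses.csv")))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  structure(
    list(neurons = neurons, synapses = synapses,
         n_channels = as.integer(meta$n_channels),
         spec = read_liquid_spec(file.path(dir, "spec.yaml")),
         seed = as.integer(meta$seed)),
    class = "elsm_liquid"
  )
}

#' Write a dataset of rasters to a directory
#'
#' One `sample_%04d.csv` per raster plus a `labels.csv` index — the
#' on-disk fixture format the command-line driver consumes.
#'
#' @param split A list with `rasters` and `labels` (one split of
#'   [make_template_dataset()]).
#' @param dir Output directory.
#' @return `dir` invisibly / the restored split.
#' @export
write_raster_dataset <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("sample_%04d.csv", seq_along(split$rasters))
  for (i in seq_along(split$rasters)) {
    write_raster_csv(split$rasters[[i]], file.path(dir, files[i]))
  }
  write.csv(data.frame(file = files, label = as.character(split$labels)),
            file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_raster_dataset
#' @export
read_raster_dataset <- function(dir) {
  idx <- read.csv(file.path(dir, "labels.csv"))
  list(
    rasters = lapply(file.path(dir, idx$file), read_raster_csv),
    labels = factor(idx$label)
  )
}
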