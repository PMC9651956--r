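#' Spike raster: a set of (source, time) events
#'
#' The universal event container: a tibble with columns `source` (1-based
#' integer id of the emitting unit — an input channel or a liquid neuron)
#' and `t_ms` (event time in ms), carrying `n_sources` and `duration_ms`
#' metadata. Events are kept time-sorted.
#'
#' @param events A data frame with columns `source` and `t_ms` (an empty
#'   raster is fine).
#' @param n_sources Number of source units the ids refer to.
#' @param duration_ms Nominal duration of the recording, ms.
#' @return A `spike_raster` tibble.
#' @examples
#' r <- spike_raster(data.frame(source = c(2, 1), t_ms = c(5, 3)),
#'                   n_sources = 4, duration_ms = 100)
#' n_sources(r)
#' @export
spike_raster <- function(events = NULL, n_sources, duration_ms) {
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble(source = integer(), t_ms = numeric())
  }
  events <- as_tibble(events)[, c("source", "t_ms")]
  events$source <- as.integer(events$source)
  if (nrow(events) > 0) {
    if (any(events$source < 1) || any(events$source > n_sources)) {
      abort("Event `source` ids must lie in [1, n_sources].")
    }
    if (any(events$t_ms < 0) || any(events$t_ms > duration_ms)) {
      abort("Event times must lie in [0, duration_ms].")
    }
    events <- dplyr::arrange(events, .data$t_ms, .data$source)
  }
  structure(events,
            n_sources = as.integer(n_sources),
            duration_ms = as.numeric(duration_ms),
            class = c("spike_raster", class(events)))
}

#' @rdname spike_raster
#' @param raster A `spike_raster`.
#' @export
n_sources <- function(raster) attr(raster, "n_sources")

#' @rdname spike_raster
#' @export
raster_duration <- function(raster) attr(raster, "duration_ms")

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d events, %d sources, %.0f ms\n",
              nrow(x), n_sources(x), raster_duration(x)))
  NextMethod()
}

#' Read or write a spike raster as two-column CSV
#'
#' The on-disk format is a plain CSV with header `source,t_ms`; metadata
#' travels in a comment-free sidecar-less way via explicit arguments on
#' read (or `# n_sources=.. duration_ms=..` header lines when
#' `with_header = TRUE`).
#'
#' @param raster A [spike_raster()].
#' @param path File path.
#' @param with_header Write/read metadata comment lines.
#' @param n_sources,duration_ms Metadata on read when `with_header = FALSE`.
#' @return The raster (read) or `path` invisibly (write).
#' @export
write_raster_csv <- function(raster, path, with_header = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (with_header) {
    writeLines(sprintf("# n_sources=%d duration_ms=%g",
                       n_sources(raster), raster_duration(raster)), con)
  }
  write.csv(as.data.frame(raster), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path, n_sources = NULL, duration_ms = NULL,
                            with_header = TRUE) {
  if (with_header) {
    hdr <- readLines(path, n = 1)
    m <- regmatches(hdr, regexec("n_sources=([0-9]+) duration_ms=([0-9.]+)",
                                 hdr))[[1]]
    if (length(m) == 3) {
      n_sources <- n_sources %||% as.integer(m[2])
      duration_ms <- duration_ms %||% as.numeric(m[3])
    }
    df <- read.csv(path, comment.char = "#")
  } else {
    df <- read.csv(path)
  }
  if (is.null(n_sources) || is.null(duration_ms)) {
    abort("`n_sources` and `duration_ms` are required (no metadata header).")
  }
  spike_raster(df, n_sources = n_sources, duration_ms = duration_ms)
}

#' Convert a binned binary raster back to discrete events
#'
#' Each active (channel, bin) cell becomes a single spike at the bin's
#' start time, the convention used to feed binned data into the simulator.
#'
#' @param binned A channels x bins binary matrix, as produced by
#'   [align_and_bin()] or [encode_cochleogram()].
#' @param bin_ms Bin width in ms.
#' @return A [spike_raster()] with `n_sources = nrow(binned)`.
#' @export
raster_from_binned <- function(binned, bin_ms) {
  stopifnot(is.matrix(binned), bin_ms > 0)
  hit <- which(binned != 0, arr.ind = TRUE)
  spike_raster(
    tibble(source = as.integer(hit[, 1]),
           t_ms = (hit[, 2] - 1) * bin_ms),
    n_sources = nrow(binned),
    duration_ms = ncol(binned) * bin_ms
  )
}
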