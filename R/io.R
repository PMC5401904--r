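# Plain-text readers and writers for the pipeline's standard artefacts.
# All files are self-describing: matrix CSVs carry a `# key=value` header
# line with the sampling interval and cluster label.

write_header <- function(path, fields) {
  line <- paste0("# ", paste(sprintf("%s=%s", names(fields),
                                     vapply(fields, format, "")),
                             collapse = " "))
  writeLines(line, path)
}

read_header <- function(path) {
  line <- readLines(path, n = 1L)
  if (!startsWith(line, "# ")) return(list())
  kv <- strsplit(strsplit(sub("^# ", "", line), " ")[[1]], "=")
  setNames(lapply(kv, function(p) p[2]), vapply(kv, function(p) p[1], ""))
}

write_matrix_csv <- function(m, path, fields) {
  write_header(path, fields)
  utils::write.table(m, path, append = TRUE, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

read_matrix_csv <- function(path) {
  h <- read_header(path)
  m <- as.matrix(utils::read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(m) <- NULL
  list(values = m, header = h)
}

#' Read and write fluorescence trace CSVs
#'
#' Traces are stored as rows = neurons, columns = frames, preceded by a
#' comment header carrying `dt_s` and the cluster label.
#'
#' @param recording A [fluorescence_recording()].
#' @param path File path.
#' @return `read_traces_csv()` returns a [fluorescence_recording()];
#'   `write_traces_csv()` returns `path` invisibly.
#' @export
write_traces_csv <- function(recording, path) {
  write_matrix_csv(recording$values, path,
                   list(dt_s = recording$dt_s,
                        cluster_id = recording$cluster_id %||% "NA"))
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  x <- read_matrix_csv(path)
  id <- x$header$cluster_id
  fluorescence_recording(
    x$values, dt_s = as.numeric(x$header$dt_s %||% 0.1),
    cluster_id = if (is.null(id) || identical(id, "NA")) NULL else id)
}

#' Read and write event raster CSVs
#'
#' Binary rasters stored like trace CSVs (rows = neurons).
#'
#' @param raster An [event_raster()].
#' @param path File path.
#' @return `read_raster_csv()` returns an [event_raster()].
#' @export
write_raster_csv <- function(raster, path) {
  write_matrix_csv(raster$onsets, path,
                   list(dt_s = raster$dt_s,
                        cluster_id = raster$cluster_id %||% "NA"))
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  x <- read_matrix_csv(path)
  id <- x$header$cluster_id
  event_raster(x$values, dt_s = as.numeric(x$header$dt_s %||% 0.1),
               cluster_id = if (is.null(id) || identical(id, "NA")) NULL
               else id)
}

#' Read and write paired ventral-root trace CSVs
#'
#' Two columns (`left`, `right`) preceded by a comment header with the
#' sample rate.
#'
#' @param pair A `vr_trace_pair` or list with `left`, `right`,
#'   `sample_rate_hz`.
#' @param path File path.
#' @return `read_vr_csv()` returns a list with `left`, `right`,
#'   `sample_rate_hz`, `duration_s`.
#' @export
write_vr_csv <- function(pair, path) {
  write_header(path, list(sample_rate_hz = pair$sample_rate_hz))
  # write.table warns when appending column names below a header line
  suppressWarnings(utils::write.table(
    data.frame(left = pair$left, right = pair$right), path, append = TRUE,
    sep = ",", row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' @rdname write_vr_csv
#' @export
read_vr_csv <- function(path) {
  h <- read_header(path)
  d <- utils::read.csv(path, comment.char = "#")
  sr <- as.numeric(h$sample_rate_hz %||% 1)
  list(left = d$left, right = d$right, sample_rate_hz = sr,
       duration_s = nrow(d) / sr)
}

#' Read and write adjacency matrices as edge lists
#'
#' Plain two-column whitespace edge list (`i j`, 1-based, one line per
#' undirected edge).
#'
#' @param adjacency Symmetric binary matrix.
#' @param path File path.
#' @param n_neurons Number of neurons (needed on read since isolated
#'   vertices carry no edges).
#' @return `read_edge_list()` returns the adjacency matrix.
#' @export
write_edge_list <- function(adjacency, path) {
  assert_adjacency(adjacency)
  e <- which(upper.tri(adjacency) & adjacency == 1, arr.ind = TRUE)
  utils::write.table(e, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, n_neurons) {
  adj <- matrix(0L, n_neurons, n_neurons)
  if (file.size(path) > 0) {
    e <- as.matrix(utils::read.table(path))
    adj[e] <- 1L
    adj[e[, 2:1, drop = FALSE]] <- 1L
  }
  adj
}

#' Read and write spot tables
#'
#' @param spots Tibble with at least `x_um`, `y_um`.
#' @param path File path.
#' @return `read_spots_csv()` returns a tibble.
#' @export
write_spots_csv <- function(spots, path) {
  readr::write_csv(spots, path)
  invisible(path)
}

#' @rdname write_spots_csv
#' @export
read_spots_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a ground-truth or QC report as JSON
#'
#' @param x A list (e.g. generator ground truth or a per-cluster QC
#'   summary).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Per-cluster detection quality-control summary
#'
#' @param raster An [event_raster()].
#' @return A one-row tibble: `cluster_id`, `n_neurons`, `n_frames`,
#'   `n_events`, `n_active`, `active_percent`.
#' @export
detection_qc <- function(raster) {
  m <- as_raster_matrix(raster)
  tibble(
    cluster_id = raster$cluster_id %||% NA,
    n_neurons = nrow(m), n_frames = ncol(m),
    n_events = sum(m), n_active = sum(rowSums(m) > 0),
    active_percent = active_fraction(m)
  )
}
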