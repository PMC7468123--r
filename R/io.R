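# Plain-text serialisation: panels as tab-delimited region x frame tables
# (node id in the first column), matrices as square tables with a node-id
# header, traces as single-column text, metadata as CSV, configs as YAML.
# Matrix values are written at 10 significant digits.

#' Write / read a regional time-series panel
#'
#' @param panel A \code{timeseries_panel}.
#' @param path Output file.
#' @export
write_panel <- function(panel, path) {
  panel <- as_panel(panel)
  df <- data.frame(node_id = panel$node_ids,
                   format(panel$values, digits = 10, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @param sampling_interval Sampling interval to attach on read.
#' @export
read_panel <- function(path, sampling_interval = 0.609) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  ids <- raw[[1L]]
  num <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell in %s at row %d, frame %d",
                 path, bad[1L], bad[2L]))
  }
  num <- matrix(num, nrow = nrow(raw))
  as_panel(num, sampling_interval = sampling_interval, node_ids = ids)
}

#' Write / read a connectivity matrix
#'
#' Square delimited text with a header row of node ids, plus a JSON sidecar
#' (\code{<path>.json}) recording filter, boundary policy, Welch parameters
#' and band.
#'
#' @param cm A \code{connectivity_matrix}.
#' @param path Output file.
#' @export
write_matrix <- function(cm, path) {
  W <- format(cm$weights, digits = 10, trim = TRUE)
  utils::write.table(rbind(cm$node_ids, W), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(cm$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  ids <- as.character(raw[1L, ])
  W <- apply(as.matrix(raw[-1L, , drop = FALSE]), c(1, 2), as.numeric)
  if (anyNA(W)) stop("non-numeric cell in ", path)
  dimnames(W) <- list(ids, ids)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(list(node_ids = ids, weights = W, meta = meta),
            class = "connectivity_matrix")
}

#' Write / read a motion trace
#'
#' One displacement value (mm) per line.
#'
#' @param trace Numeric vector.
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  writeLines(format(trace, digits = 10, trim = TRUE), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  x <- suppressWarnings(as.numeric(readLines(path)))
  if (anyNA(x)) stop("non-numeric value in ", path)
  x
}

#' Write / read the subject metadata table
#'
#' @param subjects Data frame of subject records.
#' @param path CSV file.
#' @export
write_metadata <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a pipeline configuration
#'
#' Structured key-value YAML; the seed is mandatory.
#'
#' @param config A \code{cohort_config} or full pipeline config list.
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must specify a seed")
  cfg
}
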