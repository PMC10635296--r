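# File readers/writers shared by the pipeline stages. Images, stacks and
# volumes travel as long-format CSV with a JSON sidecar for physical
# metadata (gate scheme, exposure, voxel size); tabular and summary
# outputs as CSV/JSON. Everything is plain text and diff-able.

#' Write / read a gated image stack
#'
#' Long-format CSV (`gate,row,col,counts`) plus a `<path>.json` sidecar
#' holding the gate sequence and exposure.
#'
#' @param stack a [td_stack()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_stack_csv <- function(stack, path) {
  stopifnot(inherits(stack, "td_stack"))
  d <- dim(stack$data)
  df <- data.frame(
    gate = rep(seq_len(d[1]), times = d[2] * d[3]),
    row = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    col = rep(seq_len(d[3]), each = d[1] * d[2]),
    counts = as.vector(stack$data))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(stack$gates[], list(exposure = stack$exposure, dims = d))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  d <- as.integer(meta$dims)
  data <- array(NA_real_, d)
  data[cbind(df$gate, df$row, df$col)] <- df$counts
  g <- gate_sequence(meta$gate_width, meta$step, meta$n_gates, meta$t0,
                     meta$irf_sigma)
  td_stack(data, g, exposure = meta$exposure)
}

#' Write / read a 2-D map as CSV
#'
#' Plain rectangular CSV of values (no header), `NA` for masked pixels.
#'
#' @param map numeric matrix.
#' @param path CSV file path.
#' @return `path` invisibly; `read_map_csv` returns the matrix.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(is.matrix(map))
  utils::write.table(map, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' Write tomographic per-pair time traces as CSV
#'
#' Columns: `source_id, detector_id, gate_index, t_ns, counts`.
#'
#' @param traces `n_pairs x n_gates` counts matrix.
#' @param geom an [sd_geometry()] providing the pairing.
#' @param gates a [gate_sequence()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, geom, gates, path) {
  stopifnot(nrow(traces) == nrow(geom$pairing),
            ncol(traces) == gates$n_gates)
  t_ns <- gate_times(gates)
  n_p <- nrow(traces); n_g <- ncol(traces)
  df <- data.frame(
    source_id = rep(geom$pairing[, 1], each = n_g),
    detector_id = rep(geom$pairing[, 2], each = n_g),
    gate_index = rep(seq_len(n_g), times = n_p),
    t_ns = rep(t_ns, times = n_p),
    counts = as.vector(t(traces)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  pair_key <- paste(df$source_id, df$detector_id)
  pairs <- unique(pair_key)
  n_g <- max(df$gate_index)
  traces <- matrix(NA_real_, length(pairs), n_g)
  traces[cbind(match(pair_key, pairs), df$gate_index)] <- df$counts
  traces
}

#' Write a run manifest
#'
#' JSON listing every artifact with its md5 checksum, plus the seed,
#' thresholds and package version — no silent defaults.
#'
#' @param files character vector of output paths.
#' @param params named list of every numeric parameter/threshold used.
#' @param path manifest path.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(files, params, path) {
  files <- files[file.exists(files)]
  manifest <- list(
    package = "tdflim",
    version = as.character(utils::packageVersion("tdflim")),
    params = params,
    artifacts = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
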