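# Result and connectivity I/O.
#
# Results round-trip through a plain-text directory: rasters and the Ca
# trajectory as CSV with full ("%.17g") precision so numeric values survive
# write/read bit for bit, connectivity as an attribute CSV, metrics and
# provenance as JSON, and the configuration as YAML.

fmt_full <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.17g", x) else x
}

write_full_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_full), stringsAsFactors = FALSE,
                       optional = TRUE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Export / import a connectivity table as CSV
#'
#' Columns `pre, post, w, delay, p, class, syn_id`; numeric columns are
#' written with full precision and round-trip exactly.
#'
#' @param syn a `glia_connectivity` table.
#' @param path CSV file path.
#' @return `load_connectivity` returns the `glia_connectivity` table.
#' @export
save_connectivity <- function(syn, path) {
  write_full_csv(syn, path)
  invisible(path)
}

#' @rdname save_connectivity
#' @export
load_connectivity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(pre = "integer", post = "integer",
                                       w = "numeric", delay = "numeric",
                                       p = "numeric", class = "character",
                                       syn_id = "integer"))
  class(df) <- c("glia_connectivity", "data.frame")
  df
}

#' Save / load a simulation result
#'
#' Writes a `glia_result` to a directory of plain-text files (rasters, Ca
#' trajectory, connectivity, metrics, provenance, configuration).
#' `load_result(save_result(x))` reproduces the rasters and matrices
#' bitwise.  The in-memory checkpoint is not serialized.
#'
#' @param result a `glia_result`.
#' @param path directory to create/fill.
#' @return `load_result` returns a `glia_result` (without checkpoint).
#' @export
save_result <- function(result, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_full_csv(as.data.frame(result$raster_e), file.path(path, "raster_e.csv"))
  write_full_csv(as.data.frame(result$raster_i), file.path(path, "raster_i.csv"))
  ca <- as.data.frame(result$ca)
  if (ncol(ca)) names(ca) <- paste0("a", seq_len(ncol(ca)))
  ca <- cbind(data.frame(t = result$ca_t), ca)
  write_full_csv(ca, file.path(path, "ca.csv"))
  save_connectivity(result$connectivity, file.path(path, "connectivity.csv"))
  jsonlite::write_json(result$metrics, file.path(path, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- result$provenance
  meta$N_e <- attr(result$raster_e, "N")
  meta$N_i <- attr(result$raster_i, "N")
  jsonlite::write_json(meta, file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  save_config(result$config, file.path(path, "config.yaml"))
  invisible(path)
}

#' @rdname save_result
#' @export
load_result <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "provenance.json"),
                              simplifyVector = TRUE)
  rd <- function(f) utils::read.csv(file.path(path, f),
                                    colClasses = c(cell = "integer", t = "numeric"))
  re <- rd("raster_e.csv"); ri <- rd("raster_i.csv")
  ca <- utils::read.csv(file.path(path, "ca.csv"), colClasses = "numeric")
  structure(list(
    raster_e = spike_raster(re$cell, re$t, meta$N_e, meta$t_end),
    raster_i = spike_raster(ri$cell, ri$t, meta$N_i, meta$t_end),
    ca = unname(as.matrix(ca[, -1L, drop = FALSE])),
    ca_t = ca$t,
    connectivity = load_connectivity(file.path(path, "connectivity.csv")),
    metrics = jsonlite::read_json(file.path(path, "metrics.json"),
                                  simplifyVector = TRUE),
    provenance = meta,
    checkpoint = NULL,
    config = load_config(file.path(path, "config.yaml"))
  ), class = "glia_result")
}

#' Write a metrics report for saved rasters
#'
#' Computes the population readouts (mean frequency, pairwise coherence)
#' from a raster CSV and writes them as JSON.
#'
#' @param raster_csv 2-column CSV (`cell`, `t`).
#' @param N population size.
#' @param T_total record duration (ms).
#' @param out output JSON path (`NULL` to return the list invisibly).
#' @param bin coherence bin width (ms).
#' @return the metrics list, invisibly.
#' @export
metrics_report <- function(raster_csv, N, T_total, out = NULL, bin = 2) {
  df <- utils::read.csv(raster_csv)
  r <- spike_raster(df$cell, df$t, N, T_total)
  m <- list(F = mean_frequency(r),
            synchronization = if (length(unique(r$cell)) >= 2)
              synchronization(r, bin) else NA)
  if (!is.null(out))
    jsonlite::write_json(m, out, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(m)
}
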