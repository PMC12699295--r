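#' Read and write the package's tabular formats
#'
#' Plain TSV/BED readers and writers for the pipeline's external
#' interfaces: per-read methylation calls (`read_id motif_id rel_pos call`
#' with call in `M`, `U`, `.`), BED6 motif tables, ChIP score tables,
#' traces (`time_s value channel`), trajectories
#' (`particle_id channel time_s pos_kb`) and unzipping curves
#' (`bp force_pN orientation condition`).  Writers prepend a provenance
#' comment line when `provenance` is supplied.
#'
#' @param path file path.
#' @name ctcfdyn_io
NULL

.read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}

.write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ctcfdyn_io
#' @export
read_calls_tsv <- function(path) {
  df <- .read_tsv(path, colClasses = c("character", "character", "integer",
                                       "character"))
  stopifnot(all(c("read_id", "motif_id", "rel_pos", "call") %in% names(df)))
  if (!all(df$call %in% c("M", "U", ".")))
    stop("call column must contain only M, U, .")
  df
}

#' @rdname ctcfdyn_io
#' @param calls data.frame of per-read calls.
#' @param provenance optional provenance string written as a comment.
#' @export
write_calls_tsv <- function(calls, path, provenance = NULL) {
  .write_tsv(calls[, c("read_id", "motif_id", "rel_pos", "call")], path,
             provenance)
}

#' @rdname ctcfdyn_io
#' @export
read_bed6 <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 6)
  names(df)[1:6] <- c("chrom", "start", "end", "motif_id", "score", "strand")
  # BED is 0-based half-open; the motif center rounds down for even widths
  df$center <- df$start + (df$end - df$start - 1L) %/% 2L
  df
}

#' @rdname ctcfdyn_io
#' @param motifs data.frame with chrom, start, end, motif_id, score, strand.
#' @export
write_bed6 <- function(motifs, path, provenance = NULL) {
  .write_tsv_noheader <- function(df, path, provenance) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  .write_tsv_noheader(motifs[, c("chrom", "start", "end", "motif_id",
                                 "score", "strand")], path, provenance)
  invisible(path)
}

#' @rdname ctcfdyn_io
#' @export
read_chip_tsv <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("motif_id", "score") %in% names(df)))
  df
}

#' @rdname ctcfdyn_io
#' @export
read_trace_tsv <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("time_s", "value", "channel") %in% names(df)))
  dt <- diff(df$time_s)
  if (length(dt) && (max(dt) - min(dt)) > 1e-9 * max(abs(dt)))
    warning("trace sampling is not uniform")
  attr(df, "sample_rate_hz") <- 1 / stats::median(dt)
  df
}

#' @rdname ctcfdyn_io
#' @param trace data.frame `time_s, value, channel`.
#' @export
write_trace_tsv <- function(trace, path, provenance = NULL) {
  .write_tsv(trace[, c("time_s", "value", "channel")], path, provenance)
}

#' @rdname ctcfdyn_io
#' @export
read_trajectories_tsv <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("particle_id", "channel", "time_s", "pos_kb") %in%
                  names(df)))
  df
}

#' @rdname ctcfdyn_io
#' @param trajectories data.frame `particle_id, channel, time_s, pos_kb`.
#' @export
write_trajectories_tsv <- function(trajectories, path, provenance = NULL) {
  .write_tsv(trajectories[, c("particle_id", "channel", "time_s", "pos_kb")],
             path, provenance)
}

#' @rdname ctcfdyn_io
#' @export
read_curves_tsv <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("bp", "force_pN") %in% names(df)))
  df
}

#' @rdname ctcfdyn_io
#' @param curves data.frame `bp, force_pN[, orientation, condition]`.
#' @export
write_curves_tsv <- function(curves, path, provenance = NULL) {
  .write_tsv(curves, path, provenance)
}

#' Write a result list as JSON
#'
#' @param x a list of results (data.frames become row-wise records).
#' @param path output path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
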