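#' Fragment TSV reader/writer
#'
#' Five columns — chrom, start, end, barcode, count — 0-based half-open, no
#' header; `.gz` paths are handled transparently.
#'
#' @param path file path.
#' @param fragments fragment table; a missing `count` column is written as 1.
#' @return `read_fragments`: a `data.table`; `write_fragments`: `path`,
#'   invisibly.
#' @export
read_fragments <- function(path) {
  fr <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path)
    on.exit(close(con), add = TRUE)
    data.table::fread(text = readLines(con), header = FALSE)
  } else {
    data.table::fread(path, header = FALSE)
  }
  data.table::setnames(fr, c("chrom", "start", "end", "barcode",
                             "count")[seq_len(ncol(fr))])
  if (any(fr$end <= fr$start))
    stop("end <= start found; input may be 1-based — expected BED-style ",
         "0-based half-open coordinates")
  fr
}

#' @rdname read_fragments
#' @export
write_fragments <- function(fragments, path) {
  fr <- data.table::as.data.table(fragments)
  if (!"count" %in% names(fr)) fr$count <- 1L
  data.table::fwrite(fr[, c("chrom", "start", "end", "barcode", "count"),
                        with = FALSE],
                     path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' narrowPeak reader/writer
#'
#' Ten-column BED6+4; the summit is `start + column 10` and the q-value is
#' recovered from column 9 (`-log10(q)`).
#'
#' @param path file path.
#' @param sub_peaks table with `chrom`, `start`, `end`, `summit`, `q`.
#' @return `read_narrowpeak`: data.frame with `chrom`, `start`, `end`,
#'   `summit`, `q`; `write_narrowpeak`: `path`, invisibly.
#' @export
read_narrowpeak <- function(path) {
  np <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(np) < 10) stop("narrowPeak requires 10 columns")
  data.frame(chrom = np[[1]], start = np[[2]], end = np[[3]],
             summit = np[[2]] + np[[10]], q = 10^(-np[[9]]),
             stringsAsFactors = FALSE)
}

#' @rdname read_narrowpeak
#' @export
write_narrowpeak <- function(sub_peaks, path) {
  sp <- as.data.frame(sub_peaks)
  out <- data.frame(sp$chrom, sp$start, sp$end,
                    name = sprintf("peak_%d", seq_len(nrow(sp))),
                    score = 0L, strand = ".", signal = 0,
                    p = -1, q = -log10(sp$q),
                    summit_offset = sp$summit - sp$start)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' BED reader/writer (first three columns plus optional extras)
#'
#' @param path file path.
#' @param x table whose first columns are `chrom`, `start`, `end`; extra
#'   columns are written as additional BED fields.
#' @param col_names names for any columns beyond the first three when
#'   reading.
#' @return `read_bed`: data.frame; `write_bed`: `path`, invisibly.
#' @export
read_bed <- function(path, col_names = NULL) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (!is.null(col_names) && ncol(bed) >= 3 + length(col_names))
    names(bed)[3 + seq_along(col_names)] <- col_names
  bed
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Sparse matrix MTX triplet reader/writer with barcode/feature sidecars
#'
#' Writes `<prefix>.mtx`, `<prefix>.barcodes.txt`, `<prefix>.features.txt`;
#' reading reassembles the dimnamed sparse matrix.
#'
#' @param m sparse cell x feature matrix.
#' @param prefix path prefix.
#' @return `read_mtx`: sparse matrix; `write_mtx`: `prefix`, invisibly.
#' @export
write_mtx <- function(m, prefix) {
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), paste0(prefix, ".mtx"))
  writeLines(rownames(m), paste0(prefix, ".barcodes.txt"))
  writeLines(colnames(m), paste0(prefix, ".features.txt"))
  invisible(prefix)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(prefix) {
  m <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(prefix, ".barcodes.txt")),
                      readLines(paste0(prefix, ".features.txt")))
  m
}

#' Results TSV with a metadata header
#'
#' Key-value metadata (seed, thresholds, config hash) is stored in `# key=
#' value` comment lines above the table so every result file names the
#' parameters that produced it.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param metadata named list written as header comments.
#' @return `read_results_tsv`: the data.frame with a `"metadata"` attribute;
#'   `write_results_tsv`: `path`, invisibly.
#' @export
write_results_tsv <- function(df, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s=%s", k, format(metadata[[k]], digits = 15)),
               con)
  utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- strsplit(sub("^# ", "", l), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- paste(kv[-1], collapse = "=")
  }
  df <- utils::read.table(text = lines[setdiff(seq_along(lines), hdr)],
                          sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  attr(df, "metadata") <- meta
  df
}

#' Bedgraph writer
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Pipeline configuration serialization
#'
#' Round-trips a [synth_config()] (plus any stage parameters) through JSON
#' losslessly; the config hash embedded in output files comes from the
#' serialized form.
#'
#' @param config a `synth_config` or plain named list.
#' @param path JSON path.
#' @return `read_run_config`: the config list; `write_run_config`: `path`,
#'   invisibly; `config_hash`: a short md5 string.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (all(c("n_samples", "states_per_class") %in% names(cfg)))
    cfg <- do.call(synth_config, cfg)
  cfg
}

#' @rdname write_run_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
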