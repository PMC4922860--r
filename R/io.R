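fmt_num <- function(x) sprintf("%.6g", x)

#' Write a current trace to an ATF or CSV text file
#'
#' ATF (Axon Text File) 1.0 dialect: magic line `ATF<TAB>1.0`, a record
#' count line, quoted `key=value` header records carrying the trace
#' metadata, a column-title line, then tab-separated data with a time
#' column and one column per sweep. CSV carries the same metadata as
#' leading `# key=value` comment lines. Numbers are formatted `%.6g`, so
#' output bytes are deterministic for a given trace.
#'
#' @param trace a [current_trace()].
#' @param path output file path.
#' @param format `"atf"` or `"csv"` (default from the file extension).
#' @param overwrite allow clobbering an existing file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = NULL, overwrite = FALSE) {
  stopifnot(inherits(trace, "current_trace"))
  if (file.exists(path) && !overwrite)
    stop(sprintf("'%s' exists; pass overwrite = TRUE to replace it", path))
  if (is.null(format))
    format <- if (grepl("\\.atf$", path, ignore.case = TRUE)) "atf" else "csv"
  format <- match.arg(format, c("atf", "csv"))
  n <- length(trace$sweeps[[1]])
  tms <- (seq_len(n) - 1L) * trace$sample_interval
  mat <- cbind(tms, do.call(cbind, trace$sweeps))
  md <- c(list(sample_interval = trace$sample_interval,
               n_sweeps = length(trace$sweeps)),
          Filter(function(x) is.atomic(x) && length(x) == 1L, trace$metadata))
  body <- apply(mat, 1L, function(row) paste(fmt_num(row), collapse = "\t"))
  titles <- c("Time (s)", sprintf("Trace #%d (pA)", seq_along(trace$sweeps)))
  if (format == "atf") {
    recs <- sprintf("\"%s=%s\"", names(md),
                    vapply(md, function(x) as.character(x), ""))
    lines <- c("ATF\t1.0",
               sprintf("%d\t%d", length(recs), ncol(mat)),
               recs,
               paste(sprintf("\"%s\"", titles), collapse = "\t"),
               body)
  } else {
    recs <- sprintf("# %s=%s", names(md),
                    vapply(md, function(x) as.character(x), ""))
    lines <- c(recs, paste(titles, collapse = ","),
               gsub("\t", ",", body, fixed = TRUE))
  }
  writeLines(lines, path)
  invisible(path)
}

parse_meta_value <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) num else x
}

#' Read a current trace from an ATF or CSV text file
#'
#' Inverse of [write_trace()]: values round-trip within the `%.6g`
#' formatting; metadata records are restored (numeric where possible).
#' Malformed headers raise an error naming the offending line.
#'
#' @param path input file path.
#' @param format `"atf"` or `"csv"` (default from the extension).
#' @return a [current_trace()] (without protocol).
#' @export
read_trace <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  if (is.null(format))
    format <- if (grepl("\\.atf$", path, ignore.case = TRUE)) "atf" else "csv"
  format <- match.arg(format, c("atf", "csv"))
  lines <- readLines(path)
  md <- list()
  if (format == "atf") {
    if (length(lines) < 4L || !identical(strsplit(lines[1], "\t")[[1]][1:2], c("ATF", "1.0")))
      stop("line 1: not an ATF 1.0 file (magic line 'ATF\\t1.0' missing)")
    hdr <- strsplit(lines[2], "\t")[[1]]
    nrec <- suppressWarnings(as.integer(hdr[1]))
    ncol_declared <- suppressWarnings(as.integer(hdr[2]))
    if (is.na(nrec) || is.na(ncol_declared))
      stop("line 2: malformed ATF record-count line")
    recs <- lines[2L + seq_len(nrec)]
    for (k in seq_along(recs)) {
      r <- gsub('^"|"$', "", recs[k])
      kv <- strsplit(r, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2L)
        stop(sprintf("line %d: malformed header record '%s'", 2L + k, recs[k]))
      md[[kv[1]]] <- parse_meta_value(paste(kv[-1], collapse = "="))
    }
    data_lines <- lines[(4L + nrec):length(lines)]
    mat <- do.call(rbind, lapply(seq_along(data_lines), function(k) {
      v <- suppressWarnings(as.numeric(strsplit(data_lines[k], "\t")[[1]]))
      if (anyNA(v) || length(v) != ncol_declared)
        stop(sprintf("line %d: malformed data row", 3L + nrec + k))
      v
    }))
  } else {
    is_meta <- grepl("^#", lines)
    for (r in sub("^#\\s*", "", lines[is_meta])) {
      kv <- strsplit(r, "=", fixed = TRUE)[[1]]
      if (length(kv) >= 2L) md[[kv[1]]] <- parse_meta_value(paste(kv[-1], collapse = "="))
    }
    body <- lines[!is_meta]
    ncol_declared <- length(strsplit(body[1], ",")[[1]])
    mat <- do.call(rbind, lapply(seq_along(body[-1]), function(k) {
      v <- suppressWarnings(as.numeric(strsplit(body[k + 1L], ",")[[1]]))
      if (anyNA(v) || length(v) != ncol_declared)
        stop(sprintf("line %d: malformed data row (expected %d columns)",
                     sum(is_meta) + 1L + k, ncol_declared))
      v
    }))
  }
  if (ncol(mat) < 2L) stop("trace file has no sweep columns")
  tms <- mat[, 1]
  if (any(diff(tms) <= 0)) stop("time column is not strictly increasing")
  dt <- md$sample_interval
  if (is.null(dt)) dt <- stats::median(diff(tms))
  md$sample_interval <- NULL
  md$n_sweeps <- NULL
  sweeps <- lapply(seq_len(ncol(mat) - 1L), function(j) mat[, j + 1L])
  current_trace(sweeps, dt, metadata = md)
}

run_config_keys <- c("solutions", "protocol", "gating", "buffers",
                     "thresholds", "seed", "output")

#' Write / read a run configuration
#'
#' A run configuration names the solution preset, protocol preset, gating
#' parameter set, buffer list, QC thresholds, seed and output paths for a
#' simulated experiment. Serialized as YAML; unknown top-level keys are
#' rejected on read, and a write/read cycle is the identity.
#'
#' @param config named list using keys from
#'   `solutions, protocol, gating, buffers, thresholds, seed, output`.
#' @param path file path.
#' @return `read_run_config`: the config list; `write_run_config`: `path`.
#' @export
write_run_config <- function(config, path) {
  bad <- setdiff(names(config), run_config_keys)
  if (length(bad))
    stop(sprintf("unknown run-config keys: %s", paste(bad, collapse = ", ")))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  config <- yaml::read_yaml(path)
  bad <- setdiff(names(config), run_config_keys)
  if (length(bad))
    stop(sprintf("unknown run-config keys: %s", paste(bad, collapse = ", ")))
  config
}
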