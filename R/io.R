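#' Read a bedGraph track
#'
#' Four whitespace-delimited columns (chrom, start, end, value; 0-based,
#' half-open). Comment and `track` lines are skipped. Intervals are
#' collapsed to start-position probes. Unsorted input is sorted with a
#' warning; a malformed line raises an error naming the line number.
#'
#' @param path File path.
#' @return Data frame: `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- idx[which(nf != 4L)[1]]
    stop("malformed bedGraph line ", bad, " in ", path,
         " (expected 4 columns)")
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  df <- data.frame(chrom = m[, 1],
                   start = as.numeric(m[, 2]),
                   end = as.numeric(m[, 3]),
                   value = as.numeric(m[, 4]),
                   stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end)) stop("non-numeric coordinates in ", path)
  o <- order(match(df$chrom, unique(df$chrom)), df$start)
  if (!identical(o, seq_len(nrow(df)))) {
    warning("unsorted bedGraph input in ", path, "; sorting")
    df <- df[o, ]
    rownames(df) <- NULL
  }
  df
}

#' Write a bedGraph track
#'
#' @param track Data frame with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  lines <- sprintf("%s\t%.0f\t%.0f\t%s", track$chrom, track$start,
                   track$end, sprintf("%.17g", track$value))
  writeLines(lines, path)
  invisible(path)
}

#' Write per-sample probe tracks as bedGraph files
#'
#' One file `<sample>.bedgraph` per sample; probes become unit-width
#' intervals at the probe position.
#'
#' @param pm A [probe_matrix()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_probe_tracks <- function(pm, dir) {
  stopifnot(inherits(pm, "probe_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_len(ncol(pm$values)), function(j) {
    s <- colnames(pm$values)[j]
    path <- file.path(dir, paste0(s, ".bedgraph"))
    write_bedgraph(data.frame(chrom = pm$chrom, start = pm$pos,
                              end = pm$pos + 1, value = pm$values[, j]),
                   path)
    path
  }, "")
  names(paths) <- colnames(pm$values)
  invisible(paths)
}

#' Assemble a probe matrix from per-sample bedGraph tracks
#'
#' @param tracks Named list of [read_bedgraph()] data frames, one per
#'   sample; all must share identical probe coordinates.
#' @param samples Sample sheet (`sample`, `condition`, `replicate`) whose
#'   `sample` entries name the tracks.
#' @return A [probe_matrix()].
#' @export
probe_matrix_from_tracks <- function(tracks, samples) {
  stopifnot(all(samples$sample %in% names(tracks)))
  ref <- tracks[[samples$sample[1]]]
  values <- vapply(samples$sample, function(s) {
    tr <- tracks[[s]]
    if (!identical(tr$chrom, ref$chrom) || !identical(tr$start, ref$start)) {
      stop("track '", s, "' does not share the reference probe coordinates")
    }
    tr$value
  }, numeric(nrow(ref)))
  probe_matrix(ref$chrom, ref$start, values, samples)
}

#' Read / write a sample sheet
#'
#' Tab-separated with header columns `sample`, `condition`, `replicate`.
#'
#' @param path File path.
#' @return Data frame sample sheet.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition", "replicate") %in% names(df))) {
    stop("sample sheet needs columns sample, condition, replicate")
  }
  df
}

#' @rdname read_sample_sheet
#' @param samples Sample sheet data frame.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Deterministic numeric formatting for TSV artifacts.
.fmt_num <- function(x, digits = 6) {
  out <- sprintf(paste0("%.", digits, "g"), x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a window or call table as TSV
#'
#' Numeric columns are written with fixed 6-significant-digit formatting so
#' identical runs produce byte-identical files.
#'
#' @param wt Window table / call table data frame.
#' @param path Output path.
#' @export
write_window_table <- function(wt, path) {
  out <- as.data.frame(wt)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called windows as BED6
#'
#' Called windows only; `name` is the switch direction and `score` is
#' `round(-10 * log10(q))` capped at 1000.
#'
#' @param calls A call table with `chrom`, `start`, `end`, `q`, `direction`.
#' @param path Output path.
#' @export
write_calls_bed <- function(calls, path) {
  sel <- calls$direction %in% c("EtoL", "LtoE")
  x <- calls[sel, , drop = FALSE]
  score <- pmin(round(-10 * log10(pmax(x$q, 1e-100))), 1000)
  lines <- sprintf("%s\t%.0f\t%.0f\t%s\t%d\t.", x$chrom, x$start, x$end,
                   x$direction, as.integer(score))
  writeLines(lines, path)
  invisible(path)
}

#' Write classified domain segments as BED6
#'
#' `name` is the segment class, `score` the mean dRT scaled by 100 (rounded,
#' clamped to [-1000, 1000]).
#'
#' @param segments Output of [classify_segments()].
#' @param path Output path.
#' @export
write_segments_bed <- function(segments, path) {
  score <- pmax(pmin(round(100 * segments$mean_dRT), 1000), -1000)
  lines <- sprintf("%s\t%.0f\t%.0f\t%s\t%d\t.", segments$chrom,
                   segments$start, segments$end, segments$class,
                   as.integer(score))
  writeLines(lines, path)
  invisible(path)
}

#' Write injected ground-truth domains as BED6
#'
#' `name` is the switch direction, `score` the signed effect in log2 units.
#'
#' @param truth A `sim_truth` data frame.
#' @param path Output path.
#' @export
write_truth_bed <- function(truth, path) {
  lines <- sprintf("%s\t%.0f\t%.0f\t%s\t%s\t.", truth$chrom, truth$start,
                   truth$end, truth$direction, .fmt_num(truth$effect, 4))
  writeLines(lines, path)
  invisible(path)
}

# Format sanity check used by tests: BED/bedGraph-style coordinates are
# 0-based half-open with start < end and non-negative starts.
.validate_bed_coords <- function(path, n_fields) {
  fields <- strsplit(readLines(path), "\t")
  stopifnot(all(lengths(fields) == n_fields))
  start <- as.numeric(vapply(fields, `[[`, "", 2))
  end <- as.numeric(vapply(fields, `[[`, "", 3))
  all(start >= 0 & end > start)
}
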