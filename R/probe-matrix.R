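#' Construct a probe matrix
#'
#' The probe matrix is the carrier of raw and smoothed replication-timing
#' signal: ordered probe coordinates plus one log2(early/late) value per
#' sample, together with the sample sheet assigning samples to conditions and
#' replicates.
#'
#' @param chrom Character vector, chromosome of each probe.
#' @param pos Numeric vector, probe position in bp (0-based). Must be
#'   strictly increasing within each chromosome.
#' @param values Numeric matrix, probes x samples; column names are sample
#'   ids. Missing values allowed.
#' @param samples Data frame with columns `sample`, `condition`, `replicate`;
#'   one row per value column.
#' @return A `probe_matrix` object (list with elements `chrom`, `pos`,
#'   `values`, `samples`).
#' @export
probe_matrix <- function(chrom, pos, values, samples) {
  values <- as.matrix(values)
  if (length(chrom) != length(pos) || nrow(values) != length(pos)) {
    stop("chrom, pos and rows of values must have equal length")
  }
  if (!all(c("sample", "condition", "replicate") %in% names(samples))) {
    stop("sample sheet needs columns sample, condition, replicate")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(colnames(values))) colnames(values) <- samples$sample
  if (!identical(colnames(values), as.character(samples$sample))) {
    stop("value columns must match sample sheet order")
  }
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (any(diff(p) <= 0)) {
      stop("probe positions must be strictly increasing within chromosome ", cc)
    }
  }
  structure(list(chrom = as.character(chrom), pos = as.numeric(pos),
                 values = values, samples = samples),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("probe_matrix: %d probes on %d chromosome(s), %d sample(s)\n",
              length(x$pos), length(unique(x$chrom)), ncol(x$values)))
  cat("samples:\n")
  print(x$samples, row.names = FALSE)
  invisible(x)
}

# Columns of the value matrix belonging to each condition, in sheet order.
.condition_columns <- function(pm, conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(pm$samples$condition)
  if (length(conditions) < 2L) stop("need two conditions")
  conditions <- conditions[1:2]
  cols <- lapply(conditions, function(cond) {
    which(pm$samples$condition == cond)
  })
  names(cols) <- conditions
  if (any(lengths(cols) == 0L)) stop("condition label not present in sample sheet")
  cols
}
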