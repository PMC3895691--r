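#' Define a genome layout
#'
#' A genome layout is the ordered set of chromosomes (name and length in bp)
#' on which probes, windows and domains live. It stands in for an array
#' design's chromosome table.
#'
#' @param chromosomes Either a named numeric vector of chromosome lengths in
#'   bp, or a data frame with columns `chrom` and `length`.
#' @return A `genome_layout` data frame with columns `chrom` (character) and
#'   `length` (numeric, bp).
#' @examples
#' make_genome_layout(c(chr1 = 50e6, chr2 = 50e6))
#' @export
make_genome_layout <- function(chromosomes) {
  if (is.data.frame(chromosomes)) {
    if (!all(c("chrom", "length") %in% names(chromosomes))) {
      stop("chromosome data frame needs columns 'chrom' and 'length'")
    }
    layout <- data.frame(chrom = as.character(chromosomes$chrom),
                         length = as.numeric(chromosomes$length),
                         stringsAsFactors = FALSE)
  } else {
    if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes)))) {
      stop("chromosome lengths must be named")
    }
    layout <- data.frame(chrom = names(chromosomes),
                         length = as.numeric(chromosomes),
                         stringsAsFactors = FALSE)
  }
  if (nrow(layout) < 1L) stop("at least one chromosome is required")
  if (anyDuplicated(layout$chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(layout$length)) || any(layout$length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  class(layout) <- c("genome_layout", "data.frame")
  layout
}

#' Fixed-position tile frame for a genome layout
#'
#' Tiles every chromosome from coordinate 0 into consecutive windows of
#' `window_bp` (0-based, half-open). The terminal tile of a chromosome may be
#' partial; it is kept and clipped to the chromosome end.
#'
#' @param layout A [make_genome_layout()] object.
#' @param window_bp Tile width in bp (default 200 kb).
#' @return Data frame with columns `chrom`, `start`, `end`, `tile`
#'   (genome-wide 1-based tile index).
#' @export
genome_tiles <- function(layout, window_bp = 200000L) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.finite(window_bp) || window_bp <= 0) stop("window_bp must be positive")
  pieces <- lapply(seq_len(nrow(layout)), function(i) {
    n <- ceiling(layout$length[i] / window_bp)
    start <- (seq_len(n) - 1) * window_bp
    data.frame(chrom = layout$chrom[i],
               start = start,
               end = pmin(start + window_bp, layout$length[i]),
               stringsAsFactors = FALSE)
  })
  tiles <- do.call(rbind, pieces)
  tiles$tile <- seq_len(nrow(tiles))
  rownames(tiles) <- NULL
  tiles
}

# Genome-wide tile index of a position (internal). Positions must lie within
# the chromosome; callers validate.
.tile_index <- function(chrom, pos, layout, window_bp) {
  n_tiles <- ceiling(layout$length / window_bp)
  offset <- c(0, cumsum(n_tiles))[match(chrom, layout$chrom)]
  offset + floor(pos / window_bp) + 1L
}

#' Derive reproducible stage seeds from one top-level seed
#'
#' One top-level seed deterministically yields a stream of sub-seeds so that
#' pipeline stages (simulation, segmentation permutations, overlap
#' permutations) are independently reproducible. The caller's RNG state is
#' restored on exit.
#'
#' @param seed Integer top-level seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of `n` seeds, each below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}
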