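# Shared in-code fixtures for the suite. Everything is generated, nothing
# read from disk.

tiny_layout <- function(lengths = c(chr1 = 1e6)) {
  make_genome_layout(lengths)
}

two_by_two_sheet <- function(conditions = c("control", "treatment")) {
  data.frame(sample = paste0(rep(conditions, each = 2), "_r", 1:2),
             condition = rep(conditions, each = 2),
             replicate = rep(1:2, times = 2),
             stringsAsFactors = FALSE)
}

# Probe matrix on a uniform grid of one chromosome with externally supplied
# per-sample values (probes x 4 matrix) or a generator function.
make_pm <- function(values, spacing = 5500, chrom = "chr1",
                    sheet = two_by_two_sheet()) {
  n <- nrow(values)
  probe_matrix(rep(chrom, n), seq(0, by = spacing, length.out = n),
               values, sheet)
}
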