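# Shared in-code fixtures. Everything is generated programmatically; no
# binary or stored data.

# A small deterministic genome for reader tests.
toy_genome <- function() {
  methven:::new_genome(c(chr1 = "ACGTACGTACGTACGTACGT",
                         chr2 = "GGGGCCCCAAAATTTTGGCC",
                         chrM = "ACGT"))
}

# Memoized small synthetic dataset shared across test files (SMALL-only).
.sim_cache <- new.env(parent = emptyenv())
tiny_sim <- function(seed = 11L, n_snps = 40L) {
  key <- paste0("s", seed, "_", n_snps)
  if (is.null(.sim_cache[[key]])) {
    cfg <- synthetic_config(seed = seed, n_chroms = 2L, chrom_len = 200000L,
                            n_snps = n_snps, pairs_per_snp = 3L,
                            distance_range = c(300L, 9500L))
    .sim_cache[[key]] <- synthetic_generate(cfg)
  }
  .sim_cache[[key]]
}

# First SMALL labeled pair of a simulated dataset.
build_and_pick <- function(sim) {
  pairs <- suppressMessages(build_pairs(sim$meqtl))
  pairs[which(pairs$size_class == "SMALL")[1L], , drop = FALSE]
}

# Write lines to a temp file and return its path.
tmpfile <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
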