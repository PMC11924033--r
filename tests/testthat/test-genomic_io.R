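test_that("FASTA reading normalizes case and masks ambiguity codes", {
  g <- read_fasta(tmpfile(c(">chr1", "acgt"), ".fa"))
  expect_equal(unname(g[["chr1"]]), "ACGT")
  expect_equal(unname(genome_lengths(g)["chr1"]), 4L)

  g2 <- read_fasta(tmpfile(c(">c extra header tokens", "ACGRT"), ".fa"))
  expect_equal(unname(g2[["c"]]), "ACGNT")

  gu <- read_fasta(tmpfile(c(">u", "acgu"), ".fa"))
  expect_equal(unname(gu[["u"]]), "ACGT")

  expect_error(read_fasta(tmpfile(c(">a", "AC", ">a", "GG"), ".fa")),
               "duplicate")
  expect_error(read_fasta(tmpfile(character(0), ".fa")))
})

test_that("FASTA writing round-trips a multi-record genome", {
  g <- tiny_sim()$genome
  path <- tempfile(fileext = ".fa")
  write_fasta(g, path)
  g2 <- read_fasta(path)
  expect_identical(as.character(g2), as.character(g))
  expect_identical(genome_lengths(g2), genome_lengths(g))
})

test_that("interval queries return exact lengths and reject out-of-bounds", {
  g <- toy_genome()
  set.seed(42)
  for (i in 1:50) {
    len <- unname(genome_lengths(g)["chr1"])
    a <- sample.int(len, 1L) - 1L
    b <- a + sample.int(len - a, 1L)
    expect_equal(nchar(genome_slice(g, "chr1", a, b)), b - a)
  }
  expect_error(genome_slice(g, "chr1", -1, 3), "out of bounds")
  expect_error(genome_slice(g, "chr1", 0, 21), "out of bounds")
  expect_error(genome_slice(g, "chr1", 5, 5), "out of bounds")
  expect_error(genome_slice(g, "nope", 0, 1), "unknown chromosome")
})

test_that("bedGraph expansion, empty tracks, and error handling", {
  g <- toy_genome()
  tr <- read_atac_bedgraph(tmpfile("chr1\t0\t3\t2.0", ".bedgraph"), g)
  expect_equal(tr[["chr1"]], c(2, 2, 2, rep(0, 17)))
  expect_equal(atac_slice(tr, "chr1", 1, 4), c(2, 2, 0))

  empty <- read_atac_bedgraph(tmpfile(character(0), ".bedgraph"), g)
  expect_true(all(unlist(empty) == 0))

  expect_error(read_atac_bedgraph(tmpfile("chr1\t0\t99\t1", ".bedgraph"), g),
               "out of bounds")
  expect_error(read_atac_bedgraph(tmpfile("chr1\t0\t3\t-1", ".bedgraph"), g),
               "finite and >= 0")
  expect_warning(read_atac_bedgraph(
    tmpfile(c("chr1\t0\t5\t1", "chr1\t3\t8\t2"), ".bedgraph"), g),
    "last-writer-wins")
})

test_that("bedGraph mass is conserved through write/read", {
  sim <- tiny_sim()
  path <- tempfile(fileext = ".bedgraph")
  write_atac_bedgraph(sim$atac_control, path)
  bg <- read.delim(path, header = FALSE)
  independent_mass <- sum(bg$V4 * (bg$V3 - bg$V2))
  expect_equal(sum(unlist(sim$atac_control)), independent_mass)
  tr2 <- read_atac_bedgraph(path, sim$genome)
  expect_equal(unclass(tr2), unclass(sim$atac_control), ignore_attr = TRUE)
})

test_that("meQTL table parsing validates schema and chromosomes", {
  header <- paste(methven:::meqtl_required_cols, collapse = "\t")
  row1 <- "rs1\tchr1\t5\tA\tG\tcg1\tchr1\t505\t0.4\t1e-8"
  df <- read_meqtl_table(tmpfile(c(header, row1), ".tsv"))
  expect_equal(nrow(df), 1L)
  expect_equal(df$distance, 500L)

  mism <- "rs2\tchr1\t5\tA\tG\tcg2\tchr2\t505\t0.4\t1e-8"
  expect_message(df2 <- read_meqtl_table(tmpfile(c(header, row1, mism), ".tsv")),
                 "dropped 1")
  expect_equal(nrow(df2), 1L)

  expect_error(read_meqtl_table(tmpfile(c("snp_id\tsnp_pos", "a\t1"), ".tsv")),
               "missing columns")
})

test_that("generator meQTL tables round-trip planted slopes", {
  sim <- tiny_sim()
  path <- tempfile(fileext = ".tsv")
  write_meqtl_table(sim$meqtl, path)
  df <- read_meqtl_table(path, genome = sim$genome)
  expect_equal(nrow(df), nrow(sim$meqtl))
  expect_equal(df$slope, sim$truth$slope[match(df$cpg_id, sim$truth$cpg_id)])
  expect_equal(df$distance, abs(df$snp_pos - df$cpg_pos))
})

test_that("BED annotation reading enforces the closed vocabulary", {
  ann <- read_bed_annotations(
    tmpfile("chr1\t10\t20\tStrong_Enhancer", ".bed"))
  expect_equal(ann$end0 - ann$start0, 10)
  expect_error(read_bed_annotations(tmpfile("chr1\t1\t5\tNot_A_Type", ".bed")),
               "Not_A_Type")
  expect_error(read_bed_annotations(tmpfile("chr1\t9\t3\tInsulator", ".bed")),
               "line 1")
})

test_that("per-type region coverage matches generator bookkeeping", {
  sim <- tiny_sim()
  path <- tempfile(fileext = ".bed")
  write.table(sim$regions, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ann <- read_bed_annotations(path)
  cov <- tapply(ann$end0 - ann$start0, ann$region_type, sum)
  expect_equal(cov[names(sim$region_coverage)], sim$region_coverage,
               ignore_attr = TRUE)
})

test_that("TSS BED reading takes the 5' end per strand", {
  tss <- read_tss_bed(tmpfile(c("chr1\t99\t100\tgA\t0\t+",
                                "chr1\t199\t200\tgB\t0\t-"), ".bed"))
  expect_equal(tss$tss_pos, c(100L, 200L))
  expect_error(read_tss_bed(tmpfile("chr1\t1\t2\tg\t0\t*", ".bed")), "strand")
})
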