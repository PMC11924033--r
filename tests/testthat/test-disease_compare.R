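# Independent nested-if oracle for the affect-change rule, written from the
# decision semantics: Reduced takes precedence once the delta threshold is
# crossed, then the control slope's sign separates the enhancement classes.
affect_oracle <- function(case, ctrl, thr = 0.5) {
  if (abs(case - ctrl) <= thr) return("UNAFFECTED")
  if (abs(case) < abs(ctrl)) return("REDUCED")
  if (ctrl >= 0) return("UP_ENHANCED")
  "DOWN_ENHANCED"
}

test_that("the rs968567 -> cg06781209 worked example is categorized REDUCED", {
  expect_equal(categorize_affect(0.09, -1.19), "REDUCED")
})

test_that("categorization matches the oracle on the full 7 x 7 grid", {
  vals <- c(-2, -0.6, -0.3, 0, 0.3, 0.6, 2)
  grid <- expand.grid(case = vals, ctrl = vals)
  got <- categorize_affect(grid$case, grid$ctrl)
  want <- mapply(affect_oracle, grid$case, grid$ctrl)
  expect_equal(got, unname(want))
  expect_setequal(unique(got), c("UNAFFECTED", "REDUCED", "UP_ENHANCED",
                                 "DOWN_ENHANCED"))
})

test_that("equal slopes and the 0.5 delta boundary are UNAFFECTED", {
  for (x in c(-3, -0.2, 0, 1.7))
    expect_equal(categorize_affect(x, x), "UNAFFECTED")
  expect_equal(categorize_affect(1.0, 0.5), "UNAFFECTED")    # delta exactly 0.5
  expect_equal(categorize_affect(1.01, 0.5), "UP_ENHANCED")  # just over
})

test_that("the category rule partitions a dense slope plane", {
  s <- seq(-2, 2, by = 0.1)
  grid <- expand.grid(case = s, ctrl = s)
  got <- categorize_affect(grid$case, grid$ctrl)
  expect_true(all(got %in% c("UNAFFECTED", "REDUCED", "UP_ENHANCED",
                             "DOWN_ENHANCED")))
  delta <- abs(grid$case - grid$ctrl)
  expect_equal(got == "UNAFFECTED", delta <= 0.5)
})

test_that("top-CpG ranking is a stable sort-then-slice", {
  set.seed(40)
  df <- data.frame(cpg_id = sprintf("cg%03d", 1:30),
                   slope_case = rnorm(30, 0, 2), slope_control = rnorm(30, 0, 2))
  df$category <- categorize_affect(df$slope_case, df$slope_control)
  ranked <- rank_top_cpgs(df, per_category_k = 3L)
  expect_false("UNAFFECTED" %in% names(ranked))
  for (cat in names(ranked)) {
    sub <- df[df$category == cat, ]
    delta <- abs(sub$slope_case - sub$slope_control)
    want <- sub$cpg_id[order(-delta, sub$cpg_id)][seq_len(min(3, nrow(sub)))]
    expect_equal(ranked[[cat]]$cpg_id, want)
  }
  # whole category returned when k exceeds its size; permutation stable
  all_ranked <- rank_top_cpgs(df, per_category_k = 1000L)
  expect_equal(sum(vapply(all_ranked, nrow, integer(1))),
               sum(df$category != "UNAFFECTED"))
  perm <- rank_top_cpgs(df[sample.int(30), ], per_category_k = 3L)
  expect_equal(perm, ranked)
})

test_that("promoter mapping finds the nearest TSS with signed distances", {
  set.seed(41)
  tss <- data.frame(chrom = "chr1",
                    tss_pos = sort(sample.int(100000, 20)),
                    gene_id = sprintf("g%02d", 1:20),
                    strand = sample(c("+", "-"), 20, TRUE))
  cpgs <- data.frame(cpg_id = sprintf("cg%02d", 1:25), chrom = "chr1",
                     cpg_pos = sample.int(100000, 25))
  hits <- map_to_promoters(cpgs, tss)
  for (i in seq_len(nrow(cpgs))) {
    d_all <- abs(cpgs$cpg_pos[i] - tss$tss_pos)
    cand <- which(d_all == min(d_all))
    cand <- cand[order(tss$gene_id[cand])][1]   # exhaustive minimization
    expect_equal(hits$gene_id[i], tss$gene_id[cand])
    want <- if (tss$strand[cand] == "+") cpgs$cpg_pos[i] - tss$tss_pos[cand]
            else tss$tss_pos[cand] - cpgs$cpg_pos[i]
    expect_equal(hits$distance[i], want)
    expect_equal(hits$retained[i], abs(want) <= 2000)
  }
  # retention is monotone in the promoter window
  w1 <- map_to_promoters(cpgs, tss, window_bp = 1000L)
  w5 <- map_to_promoters(cpgs, tss, window_bp = 5000L)
  expect_true(all(w5$retained[w1$retained]))
})

test_that("promoter mapping edge cases behave as documented", {
  tss <- data.frame(chrom = "chr1", tss_pos = c(5000L, 9000L),
                    gene_id = c("gB", "gA"), strand = c("+", "+"))
  at_tss <- map_to_promoters(
    data.frame(cpg_id = "cg1", chrom = "chr1", cpg_pos = 5000L), tss)
  expect_equal(at_tss$distance, 0L)
  expect_true(at_tss$retained)
  away <- map_to_promoters(
    data.frame(cpg_id = "cg2", chrom = "chr1", cpg_pos = 5000L + 2001L),
    tss[1, , drop = FALSE])
  expect_false(away$retained)
  expect_equal(away$distance, 2001L)
  # equidistant tie broken by lexicographic gene id
  tie <- map_to_promoters(
    data.frame(cpg_id = "cg3", chrom = "chr1", cpg_pos = 7000L), tss)
  expect_equal(tie$gene_id, "gA")
  expect_error(map_to_promoters(
    data.frame(cpg_id = "cg", chrom = "chr1", cpg_pos = 1L), tss[0, ]),
    "empty")
})

test_that("SNP retention near peaks matches brute-force interval checks", {
  set.seed(42)
  peaks <- data.frame(chrom = "chr1",
                      start0 = c(1000L, 8000L, 20000L, 35000L, 60000L))
  peaks$end0 <- peaks$start0 + c(500L, 300L, 1000L, 200L, 800L)
  snps <- data.frame(snp_id = sprintf("rs%02d", 1:50), snp_chrom = "chr1",
                     snp_pos = sample.int(70000, 50))
  kept <- filter_snps_near_peaks(snps, radius_bp = 1000L, peaks = peaks)
  manual <- vapply(seq_len(50), function(i) {
    any(snps$snp_pos[i] - 1L >= peaks$start0 - 1000L &
        snps$snp_pos[i] - 1L < peaks$end0 + 1000L)
  }, logical(1))
  expect_equal(kept$snp_id, snps$snp_id[manual])
  expect_equal(nrow(filter_snps_near_peaks(snps, peaks = peaks[0, ])), 0L)
})

test_that("the fallback peak caller finds planted high-signal runs", {
  v <- numeric(5000)
  v[1001:1400] <- 5                               # a real peak
  v[3001:3020] <- 5                               # too short
  v[4001:4500] <- 0.1                             # below threshold
  track <- structure(list(chr1 = v), class = "atac_track")
  pk <- call_atac_peaks(track, quantile_cut = 0.9, min_len = 50L)
  expect_equal(nrow(pk), 1L)
  expect_equal(c(pk$start0, pk$end0), c(1000L, 1400L))
  # a SNP inside the peak is retained through the caller path
  snps <- data.frame(snp_id = "rs1", snp_chrom = "chr1", snp_pos = 1200L)
  expect_equal(nrow(filter_snps_near_peaks(snps, track, radius_bp = 0L)), 1L)
})

test_that("condition prediction is deterministic and track-sensitive only", {
  sim <- tiny_sim()
  plan <- plan_cuts("SMALL")
  pair <- build_and_pick(sim)
  cfg <- model_config("REGRESS", recurrent_hidden = 4L, fc_sizes = c(6L, 4L),
                      max_epochs = 2L, min_epochs = 0L, seed = 5)
  suppressMessages(pairs <- build_pairs(sim$meqtl))
  f <- suppressWarnings(featurize_pairs(pairs[1:30, ], sim$genome,
                                        sim$atac_control, plan))
  mdl <- build_model(cfg, dim(f$x)[2:3])
  mdl <- train_model(mdl, f$x[1:20, , , drop = FALSE], pairs$slope[f$kept][1:20],
                     f$x[21:30, , , drop = FALSE], pairs$slope[f$kept][21:30])
  same <- predict_conditions(mdl, pair, sim$atac_control, sim$atac_control,
                             sim$genome, plan)
  expect_identical(same$slope_case, same$slope_control)
  again <- predict_conditions(mdl, pair, sim$atac_control, sim$atac_control,
                              sim$genome, plan)
  expect_identical(same, again)
  diff <- predict_conditions(mdl, pair, sim$atac_case, sim$atac_control,
                             sim$genome, plan)
  expect_true(is.finite(diff$slope_case) && is.finite(diff$slope_control))
})
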