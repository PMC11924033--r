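# Independent enumeration oracle for the rank-sum test: two-sided p over all
# group assignments of the pooled values.
mw_enum_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(ii) sum(r[ii]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  mu <- nx * length(y) / 2
  us <- apply(combn(length(pooled), nx), 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

test_that("the U statistic behaves at its symmetry point and extremes", {
  same <- mann_whitney_u(c(3, 1, 2), c(2, 3, 1))
  expect_equal(same$u, 4.5)                       # nx * ny / 2
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$u, 0)
  expect_equal(sep$p_value, 0.1)                  # 2 / choose(6, 3) tails
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("exact p-values match R's rank-sum test without ties", {
  set.seed(50)
  for (i in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(seq(0.01, 0.99, by = 0.01), nx + ny)   # no ties
    x <- v[1:nx]; y <- v[-(1:nx)]
    mine <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE, correct = FALSE))
    expect_equal(mine$u, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-3)
  }
})

test_that("exact p-values match enumeration when ties are present", {
  set.seed(51)
  for (i in 1:25) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:4, nx, TRUE); y <- sample(1:4, ny, TRUE)
    mine <- mann_whitney_u(x, y)
    expect_equal(mine$method, "exact enumeration")
    expect_equal(mine$p_value, mw_enum_oracle(x, y), tolerance = 1e-3)
  }
})

test_that("the normal approximation matches the tie-corrected reference", {
  set.seed(52)
  x <- round(rnorm(60), 1)
  y <- round(rnorm(70, 0.3), 1)
  mine <- mann_whitney_u(x, y)
  expect_equal(mine$method, "normal approximation")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(mine$u, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("activation profiles summarize hidden states per cut", {
  sim <- tiny_sim()
  plan <- plan_cuts("SMALL")
  suppressMessages(pairs <- build_pairs(sim$meqtl))
  f <- suppressWarnings(featurize_pairs(pairs[1:6, ], sim$genome,
                                        sim$atac_control, plan))
  used <- pairs[1:6, ][f$kept, ]
  windows <- lapply(seq_len(nrow(used)), function(i)
    suppressWarnings(extract_window(sim$genome, sim$atac_control,
                                    used[i, , drop = FALSE], plan)))
  cfg <- model_config("CLASSIFY", recurrent_hidden = 3L, fc_sizes = c(4L, 3L),
                      seed = 6)
  mdl <- build_model(cfg, dim(f$x)[2:3])
  prof <- activation_profile(mdl, f$x, windows, plan)
  expect_equal(length(prof$a), 41L)
  expect_true(all(prof$a >= 0 & is.finite(prof$a)))
  # the summary equals a hand computation over the raw hidden tensor
  h <- hidden_states(mdl, f$x)
  expect_equal(prof$a, vapply(1:41, function(t) mean(abs(h[, t, ])), numeric(1)))
  # cut intervals align to each window's absolute coordinates
  expect_equal(prof$cut_intervals[[1]]$start0,
               windows[[1]]$window_start0 + plan$cuts$start0)
  # undefined under the dense ablation
  dense_cfg <- model_config("CLASSIFY", use_recurrent = FALSE, seed = 6)
  dense <- build_model(dense_cfg, dim(f$x)[2:3])
  expect_error(activation_profile(dense, f$x, windows, plan), "dense")
})

test_that("region comparisons use exact interval intersection", {
  plan <- plan_cuts("SMALL")
  prof <- structure(list(
    a = seq_len(41) / 41,
    cut_intervals = list(data.frame(chrom = "chr1",
                                    start0 = 100000L + plan$cuts$start0,
                                    end0 = 100000L + plan$cuts$end0)),
    plan = plan), class = "activation_profile")
  ann <- data.frame(chrom = "chr1",
                    start0 = c(100000L, 110200L),
                    end0 = c(100250L, 110400L),
                    region_type = c("Active_Promoter", "Strong_Enhancer"))
  out <- compare_regions(prof, ann)
  # brute-force membership per type
  for (k in seq_len(nrow(out))) {
    sub <- ann[ann$region_type == out$region_type[k], ]
    inside <- vapply(seq_len(41), function(t) {
      any(pmin(100000L + plan$cuts$end0[t], sub$end0) -
          pmax(100000L + plan$cuts$start0[t], sub$start0) >= 1L)
    }, logical(1))
    expect_equal(out$n_in[k], sum(inside))
    expect_equal(out$n_in[k] + out$n_out[k], 41L)
    mw <- mann_whitney_u(prof$a[inside], prof$a[!inside])
    expect_equal(out$u[k], mw$u)
    expect_equal(out$p_value[k], mw$p_value)
  }
  expect_equal(out$p_adjusted, p.adjust(out$p_value, "BH"))

  # degenerate annotations are skipped with a reason
  whole <- data.frame(chrom = "chr1", start0 = 0L, end0 = 300000L,
                      region_type = "Heterochrom_lo")
  expect_message(empty <- compare_regions(prof, whole), "skipped")
  expect_equal(nrow(empty), 0L)
  off_chrom <- data.frame(chrom = "chr9", start0 = 1L, end0 = 10L,
                          region_type = "Insulator")
  expect_message(none <- compare_regions(prof, off_chrom), "skipped")
  expect_equal(nrow(none), 0L)
})
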