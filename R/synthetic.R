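# Seeded synthetic datasets: genome, CpG sites, SNPs, accessibility tracks,
# and meQTL slopes with planted structure, emulating the statistical shape of
# real cis-meQTL inputs so that every pipeline stage is testable offline.
#
# Planted effect model for a SNP-CpG pair at distance d:
#   slope = s * base_effect * exp(-distance_decay * d) * (1 + atac_weight * abar) + eps
# where s = -1 if the SNP disrupts a planted motif occurrence (C->T at the
# motif's CpG) and +1 otherwise, abar is the mean control accessibility in
# the cut containing the SNP, and eps ~ Normal(0, noise_sd^2).
# Down-regulating pairs carry two sequence signatures: the SNP sits in a
# planted motif copy that its alt allele disrupts (C->T), and the effect CpG
# is flanked by a compact tandem block of motif copies (a binding-site
# cluster at the CpG), so the effect direction is visible both to the
# substitution channel and to the central-cut base composition after
# pooling.

#' Configuration for the synthetic generator
#'
#' @param seed Integer seed; fully determines every output byte.
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param gc_content Background GC fraction.
#' @param n_snps Number of SNPs.
#' @param pairs_per_snp CpG sites paired with each SNP.
#' @param motif Fixed 8-mer planted around motif-disrupting SNPs; must
#'   contain a CG dinucleotide (its C is the disrupted base).
#' @param motif_copies Copies of the motif planted in a tandem block
#'   immediately flanking each down-regulated CpG (half upstream, half
#'   downstream), emulating a binding-site cluster at the CpG whose base
#'   composition is visible to pooled sequence features.
#' @param base_effect Effect-size scale (slope magnitude at distance 0 with
#'   zero accessibility).
#' @param distance_decay Exponential decay rate of effect with distance
#'   (per bp).
#' @param atac_weight Multiplicative weight of mean accessibility in the
#'   SNP's cut.
#' @param noise_sd Standard deviation of the additive slope noise.
#' @param condition_shift Relative accessibility change near each SNP in the
#'   case track: signal is scaled by `1 +/- condition_shift`.
#' @param distance_range SNP-CpG distance range (bp); distances are
#'   log-uniform over it, concentrating pairs near the CpG as in cis-meQTL
#'   tables.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_chroms = 3L, chrom_len = 600000L,
                             gc_content = 0.42, n_snps = 300L,
                             pairs_per_snp = 3L, motif = "GCCACGCG",
                             motif_copies = 16L, base_effect = 2.0,
                             distance_decay = 1 / 30000, atac_weight = 1.0,
                             noise_sd = 0.3, condition_shift = 0.5,
                             distance_range = c(300L, 100000L)) {
  if (!grepl("CG", motif)) stop("motif must contain a CG dinucleotide")
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_len = as.integer(chrom_len), gc_content = gc_content,
              n_snps = as.integer(n_snps), pairs_per_snp = as.integer(pairs_per_snp),
              motif = motif, motif_copies = as.integer(motif_copies),
              base_effect = base_effect, distance_decay = distance_decay,
              atac_weight = atac_weight, noise_sd = noise_sd,
              condition_shift = condition_shift,
              distance_range = as.integer(distance_range))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Noise-free, large-effect variant for learnability tests
#'
#' Same planted structure with `noise_sd = 0` and `base_effect = 5`, so the
#' effect direction is a deterministic function of the planted motif
#' disruption.
#'
#' @param config A `synthetic_config`.
#' @return Modified `synthetic_config`.
#' @export
make_separable <- function(config = synthetic_config()) {
  config$noise_sd <- 0
  config$base_effect <- 5
  config
}

plan_radius <- function(d) if (d < 10000L) 10000L else 100000L

#' Generate a synthetic dataset
#'
#' Emits (when `out_dir` is given) a genome FASTA, control and case bedGraph
#' accessibility tracks, a meQTL table, a TSS BED6, a functional-region BED4
#' over the eight region types, and the ground-truth table; all files are
#' parseable by the package readers and every emitted pair survives window
#' bounds checks. The same seed yields a byte-identical file set.
#'
#' @param config A `synthetic_config`.
#' @param out_dir Output directory, or `NULL` to generate in memory only.
#' @return List with `genome`, `atac_control`, `atac_case`, `meqtl`
#'   (records data.frame), `truth` (ground-truth data.frame), `tss`,
#'   `regions`, `region_coverage` (per-type planted base coverage), `config`,
#'   and `files` (paths, when written).
#' @export
synthetic_generate <- function(config = synthetic_config(), out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  dmax <- max(config$distance_range)
  # every SNP must have at least one feasible CpG side at the largest
  # distance, and SMALL windows must always fit around the SNP
  needed <- max(2L * (plan_radius(dmax) + dmax) + 1L, 60000L)
  if (config$chrom_len < needed)
    stop("chrom_len too short for the requested distance range: need >= ", needed)
  res <- with_seed(config$seed, generate_impl(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      genome = file.path(out_dir, "genome.fa"),
      atac_control = file.path(out_dir, "atac_control.bedgraph"),
      atac_case = file.path(out_dir, "atac_case.bedgraph"),
      meqtl = file.path(out_dir, "meqtl.tsv"),
      tss = file.path(out_dir, "tss.bed"),
      regions = file.path(out_dir, "regions.bed"),
      truth = file.path(out_dir, "truth.tsv"))
    write_fasta(res$genome, files$genome)
    write_atac_bedgraph(res$atac_control, files$atac_control)
    write_atac_bedgraph(res$atac_case, files$atac_case)
    write_meqtl_table(res$meqtl, files$meqtl)
    write.table(res$tss_bed, files$tss, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(res$regions, files$regions, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(res$truth, files$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$files <- files
  }
  res
}

generate_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  bases <- c("A", "C", "G", "T")
  p <- c((1 - cfg$gc_content) / 2, cfg$gc_content / 2,
         cfg$gc_content / 2, (1 - cfg$gc_content) / 2)
  seqs <- setNames(vapply(chroms, function(ch)
    paste(sample(bases, cfg$chrom_len, replace = TRUE, prob = p),
          collapse = ""), character(1)), chroms)

  # --- SNPs: evenly spread with jitter, alternating chromosomes; the edge
  #     margin keeps every SMALL window in bounds on either side ---
  snp_chrom <- chroms[(seq_len(cfg$n_snps) - 1L) %% cfg$n_chroms + 1L]
  lo <- 20001L
  hi <- cfg$chrom_len - 20000L
  snp_pos <- integer(cfg$n_snps)
  for (ch in chroms) {
    idx <- which(snp_chrom == ch)
    grid <- round(seq(lo, hi, length.out = length(idx) + 2L))[-c(1L, length(idx) + 2L)]
    snp_pos[idx] <- as.integer(grid + sample(-200:200, length(idx), replace = TRUE))
  }
  in_motif <- as.logical(rbinom(cfg$n_snps, 1L, 0.5))
  cond_sign <- ifelse(rbinom(cfg$n_snps, 1L, 0.5) == 1L, 1L, -1L)

  mlen <- nchar(cfg$motif)
  c_off <- as.integer(regexpr("CG", cfg$motif))  # 1-based C position in motif

  # --- pairs: log-uniform distances; the CpG side is chosen among the
  #     sides whose window stays within the chromosome ---
  n_pairs <- cfg$n_snps * cfg$pairs_per_snp
  pair_snp <- rep(seq_len(cfg$n_snps), each = cfg$pairs_per_snp)
  dr <- cfg$distance_range
  dist <- as.integer(round(exp(runif(n_pairs, log(dr[1]), log(dr[2])))))
  dist <- pmax(dr[1], pmin(dr[2], dist))
  cpg_pos <- integer(n_pairs)
  for (j in seq_len(n_pairs)) {
    sp <- snp_pos[pair_snp[j]]
    rad <- plan_radius(dist[j])
    plus_ok <- sp + dist[j] + rad + 1L <= cfg$chrom_len
    minus_ok <- sp - dist[j] - rad >= 1L
    side <- if (plus_ok && minus_ok) sample(c(-1L, 1L), 1L)
            else if (plus_ok) 1L else -1L
    cpg_pos[j] <- sp + side * dist[j]
  }

  # --- plant sequence signatures of down-regulating pairs: a tandem block
  #     of motif copies flanking the CpG (binding-site cluster), then the
  #     CG dinucleotide at every CpG, then the disrupting motif copy at the
  #     SNP (written last so its C, the SNP base, is intact) ---
  n_up <- ceiling(cfg$motif_copies / 2)
  n_down <- cfg$motif_copies - n_up
  for (j in which(in_motif[pair_snp])) {
    ch <- snp_chrom[pair_snp[j]]
    starts <- c(cpg_pos[j] - 1L - mlen * seq_len(n_up),
                cpg_pos[j] + 2L + mlen * (seq_len(n_down) - 1L))
    for (st in starts) substr(seqs[[ch]], st, st + mlen - 1L) <- cfg$motif
  }
  for (j in seq_len(n_pairs)) {
    ch <- snp_chrom[pair_snp[j]]
    substr(seqs[[ch]], cpg_pos[j], cpg_pos[j] + 1L) <- "CG"
  }
  for (i in which(in_motif)) {
    ch <- snp_chrom[i]
    st <- snp_pos[i] - c_off + 1L
    substr(seqs[[ch]], st, st + mlen - 1L) <- cfg$motif
  }

  # --- alleles from the final genome (rare collisions drop the SNP) ---
  ref <- vapply(seq_len(cfg$n_snps), function(i)
    substr(seqs[[snp_chrom[i]]], snp_pos[i], snp_pos[i]), character(1))
  alt <- character(cfg$n_snps)
  ok_snp <- rep(TRUE, cfg$n_snps)
  for (i in seq_len(cfg$n_snps)) {
    if (in_motif[i]) {
      if (ref[i] != "C") { ok_snp[i] <- FALSE; next }
      alt[i] <- "T"
    } else {
      alt[i] <- sample(setdiff(bases, ref[i]), 1L)
    }
  }
  if (any(!ok_snp))
    msg("dropped ", sum(!ok_snp), " synthetic SNPs with clobbered motif base")

  genome <- new_genome(seqs)

  # --- accessibility: background peaks plus one planted peak per SNP ---
  add_peak <- function(v, center, width, height) {
    st <- max(1L, center - width %/% 2L)
    en <- min(length(v), center + width %/% 2L)
    v[st:en] <- v[st:en] + height
    v
  }
  # sparse low background peaks plus one dominant peak over every SNP (the
  # SNPs emulate variants selected near regulatory peak regions), so the
  # accessibility that modulates the planted effect is the strongest
  # accessibility feature of each window
  control <- lapply(setNames(chroms, chroms), function(ch) numeric(cfg$chrom_len))
  for (ch in chroms) {
    n_bg <- max(1L, cfg$chrom_len %/% 20000L)
    centers <- sample.int(cfg$chrom_len, n_bg)
    widths <- sample(300:1000, n_bg, replace = TRUE)
    heights <- round(exp(rnorm(n_bg, log(0.5), 0.4)), 4)
    for (b in seq_len(n_bg))
      control[[ch]] <- add_peak(control[[ch]], centers[b], widths[b], heights[b])
  }
  snp_peak_height <- round(exp(rnorm(cfg$n_snps, log(2), 0.7)), 4)
  for (i in seq_len(cfg$n_snps)) {
    ch <- snp_chrom[i]
    control[[ch]] <- add_peak(control[[ch]],
                              snp_pos[i] + sample(-50:50, 1L),
                              sample(700:900, 1L),
                              snp_peak_height[i])
  }
  # co-accessibility: each paired CpG carries a peak whose height tracks its
  # SNP's peak (SNP and CpG sit in one regulatory unit)
  for (j in seq_len(cfg$n_snps * cfg$pairs_per_snp)) {
    i <- pair_snp[j]
    control[[snp_chrom[i]]] <- add_peak(
      control[[snp_chrom[i]]], cpg_pos[j], sample(500:700, 1L),
      round(snp_peak_height[i] * exp(rnorm(1L, 0, 0.05)), 4))
  }
  # the case condition rescales the whole regulatory unit of each SNP: the
  # SNP peak and the linked CpG peaks
  case <- control
  scale_near <- function(v, center, factor, radius = 500L) {
    st <- max(1L, center - radius)
    en <- min(length(v), center + radius)
    v[st:en] <- v[st:en] * factor
    v
  }
  for (i in seq_len(cfg$n_snps)) {
    ch <- snp_chrom[i]
    fac <- 1 + cond_sign[i] * cfg$condition_shift
    case[[ch]] <- scale_near(case[[ch]], snp_pos[i], fac)
    for (j in which(pair_snp == i))
      case[[ch]] <- scale_near(case[[ch]], cpg_pos[j], fac)
  }
  atac_control <- structure(control, class = "atac_track")
  atac_case <- structure(case, class = "atac_track")

  # --- planted slopes ---
  plans <- list(SMALL = plan_cuts("SMALL"), LARGE = plan_cuts("LARGE"))
  abar_in_cut <- function(track, ch, snp, cpg, d) {
    plan <- if (d < 10000L) plans$SMALL else plans$LARGE
    rad <- (plan$window_len - 1L) %/% 2L
    wstart0 <- cpg - 1L - rad
    ci <- cut_index_of(plan, snp - 1L - wstart0)
    mean(track[[ch]][(wstart0 + plan$cuts$start0[ci] + 1L):(wstart0 + plan$cuts$end0[ci])])
  }
  keep_pair <- ok_snp[pair_snp]
  pair_snp <- pair_snp[keep_pair]
  dist <- dist[keep_pair]
  cpg_pos <- cpg_pos[keep_pair]
  n_pairs <- length(pair_snp)
  s <- ifelse(in_motif[pair_snp], -1, 1)
  abar_ctrl <- abar_case <- numeric(n_pairs)
  snp_cut <- integer(n_pairs)
  for (j in seq_len(n_pairs)) {
    i <- pair_snp[j]
    ch <- snp_chrom[i]
    abar_ctrl[j] <- abar_in_cut(control, ch, snp_pos[i], cpg_pos[j], dist[j])
    abar_case[j] <- abar_in_cut(case, ch, snp_pos[i], cpg_pos[j], dist[j])
    plan <- if (dist[j] < 10000L) plans$SMALL else plans$LARGE
    rad <- (plan$window_len - 1L) %/% 2L
    snp_cut[j] <- cut_index_of(plan, snp_pos[i] - cpg_pos[j] + rad)
  }
  decay <- exp(-cfg$distance_decay * dist)
  noise <- rnorm(n_pairs, 0, cfg$noise_sd)
  slope_nf <- s * cfg$base_effect * decay * (1 + cfg$atac_weight * abar_ctrl)
  slope_case_nf <- s * cfg$base_effect * decay * (1 + cfg$atac_weight * abar_case)
  slope <- round(slope_nf + noise, 6)

  meqtl <- data.frame(
    snp_id = paste0("snp", sprintf("%04d", pair_snp)),
    snp_chrom = snp_chrom[pair_snp],
    snp_pos = snp_pos[pair_snp],
    ref = ref[pair_snp],
    alt = alt[pair_snp],
    cpg_id = paste0("cg", sprintf("%06d", seq_len(n_pairs))),
    cpg_chrom = snp_chrom[pair_snp],
    cpg_pos = cpg_pos,
    slope = slope,
    pvalue = signif(10^-runif(n_pairs, 4, 12), 3),
    stringsAsFactors = FALSE)
  meqtl$distance <- dist

  truth <- data.frame(
    snp_id = meqtl$snp_id, cpg_id = meqtl$cpg_id,
    distance = dist,
    sign = s,
    in_motif = in_motif[pair_snp],
    snp_cut = snp_cut,
    abar_control = round(abar_ctrl, 6),
    abar_case = round(abar_case, 6),
    condition_sign = cond_sign[pair_snp],
    slope_noise_free = round(slope_nf, 6),
    slope_case_noise_free = round(slope_case_nf, 6),
    slope = slope,
    stringsAsFactors = FALSE)

  # --- TSS annotations (point genes, random strand) ---
  n_genes_per <- max(3L, cfg$chrom_len %/% 20000L)
  tss <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(sample.int(cfg$chrom_len - 1L, n_genes_per))
    data.frame(chrom = ch, tss_pos = pos,
               gene_id = paste0("gene_", ch, "_", sprintf("%03d", seq_along(pos))),
               strand = sample(c("+", "-"), n_genes_per, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  tss_bed <- data.frame(chrom = tss$chrom,
                        start0 = ifelse(tss$strand == "+", tss$tss_pos - 1L, tss$tss_pos - 1L),
                        end0 = tss$tss_pos,
                        gene_id = tss$gene_id, score = 0L, strand = tss$strand)

  # --- functional-region annotations over the eight types ---
  types <- functional_region_types()
  regions <- do.call(rbind, lapply(chroms, function(ch) {
    m <- max(8L, cfg$chrom_len %/% 40000L)
    st <- sort(sample.int(cfg$chrom_len - 5000L, m))
    wd <- sample(500:5000, m, replace = TRUE)
    data.frame(chrom = ch, start0 = st - 1L,
               end0 = pmin(st - 1L + wd, cfg$chrom_len),
               region_type = sample(types, m, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  region_coverage <- vapply(split(regions$end0 - regions$start0, regions$region_type),
                            sum, numeric(1))

  list(genome = genome, atac_control = atac_control, atac_case = atac_case,
       meqtl = meqtl, truth = truth, tss = tss, tss_bed = tss_bed,
       regions = regions, region_coverage = region_coverage, config = cfg)
}
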