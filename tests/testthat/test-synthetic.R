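test_that("simulated annotations respect spacing, capacity and determinism", {
  cfg <- sim_config(n_genes = 100, chrom_sizes = c(chr1 = 1e7), seed = 1)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann), 100)
  expect_true(all(diff(sort(ann$tss)) >= 2000))
  expect_true(all(ann$tss >= 0 & ann$tss < 1e7))

  again <- simulate_annotation(cfg)
  expect_identical(ann, again)

  big <- sim_config(n_genes = 10000, chrom_sizes = c(chr1 = 1e6), seed = 1)
  expect_error(simulate_annotation(big), "too small")
})

test_that("planted effects follow the class definitions", {
  one_class <- function(cls) {
    fr <- stats::setNames(rep(0, 7),
                          c("suppressed_activated", "suppressed_repressed",
                            "induced_activated", "induced_repressed",
                            "colonization_only", "genotype_only", "null"))
    fr[cls] <- 1
    fr
  }
  cfg <- sim_config(n_genes = 50, chrom_sizes = c(chr1 = 1e6), seed = 2,
                    class_fractions = one_class("suppressed_activated"),
                    effect_size = 2)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  expect_true(all(sim$truth$col_effect == 2))   # higher germ-free
  expect_true(all(sim$truth$geno_effect == 2))  # higher wild-type

  null_cfg <- sim_config(n_genes = 50, chrom_sizes = c(chr1 = 1e6), seed = 2,
                         class_fractions = one_class("null"))
  null_sim <- simulate_counts(simulate_annotation(null_cfg), null_cfg)
  expect_true(all(null_sim$truth$col_effect == 0))
  expect_true(all(null_sim$truth$geno_effect == 0))

  zero <- sim_config(n_genes = 50, chrom_sizes = c(chr1 = 1e6), seed = 2,
                     effect_size = 0)
  zsim <- simulate_counts(simulate_annotation(zero), zero)
  expect_true(all(zsim$truth$col_effect == 0))
  expect_true(all(zsim$truth$geno_effect == 0))
})

test_that("simulated counts reproduce the NB mean-variance relation", {
  # mu = 50, alpha = 0.1: mean 50, variance 50 + 0.1*50^2 = 300
  set.seed(11)
  draws <- stats::rnbinom(5000, mu = 50, size = 1 / 0.1)
  expect_lt(abs(mean(draws) - 50), 1)
  expect_lt(abs(var(draws) - 300) / 300, 0.15)

  # and end to end through the simulator: a null gene's counts pool to the
  # planted baseline within sampling error
  cfg <- sim_config(n_genes = 400, chrom_sizes = c(chr1 = 2e6), seed = 12,
                    effect_size = 0, depth_log_sd = 0, dispersion = 0.1)
  sim <- simulate_counts(simulate_annotation(cfg), cfg)
  m_obs <- rowMeans(sim$counts$counts)
  m_exp <- 2^sim$truth$base_log2_mean
  expect_gt(stats::cor(log(m_obs + 1), log(m_exp)), 0.98)
})

test_that("class fractions of the emitted truth match the config", {
  cfg <- sim_config(seed = 13)
  sim <- simulate_counts(simulate_annotation(cfg), cfg)
  counts <- table(factor(sim$truth$class, names(cfg$class_fractions)))
  gof <- suppressWarnings(
    stats::chisq.test(counts, p = cfg$class_fractions))
  expect_gt(gof$p.value, 0.001)
})

test_that("peak condition-specificity follows expression direction and bias", {
  cfg <- sim_config(n_genes = 500, chrom_sizes = c(chr1 = 5e7), seed = 14,
                    peak_gf_bias = 1, background_peak_rate = 0)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  pk <- simulate_peaks(ann, sim$truth, cfg)
  spec <- pk$peak_truth$specificity
  col <- sim$truth$col_effect[pk$peak_truth$gene_id]
  expect_true(all(spec[col > 0] == "GF"))
  expect_true(all(spec[col < 0] == "CV"))
  expect_true(all(spec[col == 0] == "shared"))

  cfg0 <- sim_config(n_genes = 500, chrom_sizes = c(chr1 = 5e7), seed = 14,
                     peak_gf_bias = 0, background_peak_rate = 0)
  pk0 <- simulate_peaks(ann, sim$truth, cfg0)
  expect_identical(as.data.frame(pk0$peaks_gf)[, 1:4],
                   as.data.frame(pk0$peaks_cv)[, 1:4])
})

test_that("every planted peak summit lies within 10 kb of its gene's TSS", {
  cfg <- sim_config(seed = 15)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  pk <- simulate_peaks(ann, sim$truth, cfg)
  planted <- !is.na(pk$peak_truth$gene_id)
  pt <- pk$peak_truth[planted, ]
  all_pk <- union_peak_sets(pk$peaks_gf, pk$peaks_cv)
  m <- match(pt$name, all_pk$name)
  summit <- all_pk$start[m] + all_pk$summit_offset[m]
  tss <- ann$tss[match(pt$gene_id, ann$gene_id)]
  expect_true(all(abs(summit - tss) <= 10000))
})

test_that("coverage tracks are valid and carry condition-scaled bumps", {
  cfg <- sim_config(n_genes = 200, chrom_sizes = c(chr1 = 2e7), seed = 16)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  pk <- simulate_peaks(ann, sim$truth, cfg)
  iv <- pk$track_gf$intervals
  expect_true(all(iv$value >= 0))
  by_chr <- split(iv, iv$chrom)
  for (b in by_chr) {
    expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  # GF-specific sites must have more GF than CV signal at the summit
  gf_only <- pk$peak_truth$name[pk$peak_truth$specificity == "GF"]
  sites <- pk$peaks_gf[pk$peaks_gf$name %in% gf_only, , drop = FALSE]
  skip_if(nrow(sites) < 5)
  p_gf <- mean_profile(flanking_signal_matrix(sites, pk$track_gf))
  p_cv <- mean_profile(flanking_signal_matrix(sites, pk$track_cv))
  centre <- which.min(abs(p_gf$bin_center))
  expect_gt(p_gf$mean[centre], p_cv$mean[centre])
})

test_that("ortholog tables honor dropout and paralog settings", {
  base <- list(n_genes = 300, chrom_sizes = c(chr1 = 2e6), seed = 17)
  clean <- do.call(sim_config, c(base, list(ortholog_dropout = 0,
                                            paralog_rate = 0)))
  ann <- simulate_annotation(clean)
  orth <- simulate_ortholog_tables(ann, clean)
  expect_equal(nrow(orth$human_mouse), 300)
  expect_equal(nrow(one_to_one_filter(orth$human_mouse)), 300)
  expect_equal(nrow(orth$true_pairs), 300)

  par1 <- do.call(sim_config, c(base, list(ortholog_dropout = 0,
                                           paralog_rate = 1)))
  orth1 <- simulate_ortholog_tables(ann, par1)
  expect_equal(nrow(one_to_one_filter(orth1$human_mouse)), 0)

  again <- simulate_ortholog_tables(ann, clean)
  expect_identical(orth$human_mouse, again$human_mouse)
})

test_that("disease lists encode the planted slope and a coherent direction mask", {
  cfg <- sim_config(n_genes = 800, chrom_sizes = c(chr1 = 5e6), seed = 18)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(ann, cfg)
  orth <- simulate_ortholog_tables(ann, cfg)
  ds <- simulate_disease_list(sim$truth, orth, cfg)
  x_star <- attr(ds, "x_star")
  expect_true(all(is.na(ds$direction[x_star == 0])))
  lab <- !is.na(ds$direction)
  expect_true(all((ds$log2fc[lab] > 0) == (ds$direction[lab] == "up")))

  # near-zero noise puts every point on the planted line
  tight <- sim_config(n_genes = 300, chrom_sizes = c(chr1 = 2e6), seed = 19,
                      disease_noise_sd_x = 1e-8, disease_noise_sd_y = 1e-8,
                      disease_true_slope = 0.8)
  ann2 <- simulate_annotation(tight)
  sim2 <- simulate_counts(ann2, tight)
  orth2 <- simulate_ortholog_tables(ann2, tight)
  ds2 <- simulate_disease_list(sim2$truth, orth2, tight)
  xs <- attr(ds2, "x_star")
  expect_lt(max(abs(ds2$log2fc - 0.8 * xs)), 1e-6)

  # slope 0: disease values uncorrelated with the planted effects
  flat <- sim_config(n_genes = 500, chrom_sizes = c(chr1 = 3e6), seed = 20,
                     disease_true_slope = 0)
  ann3 <- simulate_annotation(flat)
  sim3 <- simulate_counts(ann3, flat)
  orth3 <- simulate_ortholog_tables(ann3, flat)
  ds3 <- simulate_disease_list(sim3$truth, orth3, flat)
  fit <- deming_fit(data.frame(x = attr(ds3, "x_observed"), y = ds3$log2fc))
  expect_lt(abs(fit$slope), 0.1)
})

test_that("Deming recovery from the generator's own x/y channels", {
  set.seed(21)
  hits <- 0
  runs <- 60
  for (r in 1:runs) {
    x_star <- stats::rnorm(100)
    x <- x_star + stats::rnorm(100, 0, 0.3)
    y <- 0.8 * x_star + stats::rnorm(100, 0, 0.3)
    fit <- deming_fit(data.frame(x = x, y = y))
    if (abs(fit$slope - 0.8) <= 0.1) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.90)
})

test_that("dataset directories round-trip through the readers deterministically", {
  cfg <- sim_config(n_genes = 150, chrom_sizes = c(chr1 = 2e6, chr2 = 1e6),
                    seed = 22)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  ds <- load_dataset(d1)
  expect_equal(nrow(ds$annotation), 150)
  expect_s3_class(ds$counts, "count_matrix")
  expect_equal(ds$peaks$track_gf$library_size,
               sum(ds$peaks$track_gf$intervals$value *
                     (ds$peaks$track_gf$intervals$end -
                        ds$peaks$track_gf$intervals$start)))
  unlink(c(d1, d2), recursive = TRUE)
})
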