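#' Simulation configuration
#'
#' Defines the planted structure of a synthetic gnotobiotic 2x2 experiment:
#' a gene annotation, a negative-binomial count matrix with class-determined
#' additive log2 effects, condition-specific binding peaks with coverage
#' tracks, ortholog tables with dropout/paralog noise, and a disease
#' differential-gene list tied to the planted genotype effects by a true
#' slope.
#'
#' Gene classes combine a microbiota axis (suppressed: higher germ-free;
#' induced: higher conventionalized) with a genotype axis (activated: higher
#' wild-type; repressed: higher mutant):
#' `suppressed_activated`, `suppressed_repressed`, `induced_activated`,
#' `induced_repressed`, plus single-axis `colonization_only` and
#' `genotype_only` (random effect sign) and `null`.
#'
#' @param n_genes number of genes.
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param n_reps named integer vector of replicates per design cell
#'   (`WTGF`, `WTCV`, `MutGF`, `MutCV`), each >= 2. Default mirrors a
#'   3/3/2/2 design.
#' @param class_fractions named proportions over the seven gene classes;
#'   must sum to 1.
#' @param effect_size planted |log2 fold change| for each active axis.
#' @param interaction extra log2 effect in the WT x GF cell (default 0, i.e.
#'   purely additive axes).
#' @param dispersion NB dispersion alpha (variance = mu + alpha*mu^2).
#' @param base_mean_log_range range of the log2 baseline mean, drawn
#'   uniformly per gene.
#' @param depth_log_sd standard deviation of per-sample log depth factors.
#' @param peak_gf_bias probability that a planted-class gene's peak is
#'   specific to its expression-concordant condition (GF-specific for genes
#'   higher in GF, CV-specific for genes higher in CV); otherwise the peak is
#'   shared. Genotype-only genes get shared peaks.
#' @param background_peak_rate probability that a null gene contributes a
#'   background peak at a random genomic position (present in both
#'   conditions).
#' @param peak_width_range range of peak widths in bp.
#' @param peak_height per-base signal height of the triangular bump planted
#'   at each peak summit, above a flat background of 1.
#' @param ortholog_dropout probability a gene lacks an ortholog in a pairwise
#'   table.
#' @param paralog_rate probability a gene gains a conflicting second mapping
#'   partner (removed later by the one-to-one filter).
#' @param disease_true_slope planted slope relating disease log2FC to the
#'   planted mutant-vs-wild-type (MutCV/WTCV) log2FC.
#' @param disease_noise_sd_x,disease_noise_sd_y noise SDs on the observed
#'   ortholog-comparison axis and the disease axis.
#' @param seed RNG seed; every generator derives its substream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       chrom_sizes = c(chr1 = 60e6, chr2 = 40e6, chr3 = 25e6),
                       n_reps = c(WTGF = 3, WTCV = 3, MutGF = 2, MutCV = 2),
                       class_fractions = c(suppressed_activated = 0.045,
                                           suppressed_repressed = 0.005,
                                           induced_activated = 0.010,
                                           induced_repressed = 0.040,
                                           colonization_only = 0.100,
                                           genotype_only = 0.100,
                                           null = 0.700),
                       effect_size = 2,
                       interaction = 0,
                       dispersion = 0.1,
                       base_mean_log_range = c(3, 10),
                       depth_log_sd = 0.15,
                       peak_gf_bias = 0.8,
                       background_peak_rate = 0.05,
                       peak_width_range = c(200, 400),
                       peak_height = 15,
                       ortholog_dropout = 0.1,
                       paralog_rate = 0.05,
                       disease_true_slope = 0.8,
                       disease_noise_sd_x = 0.3,
                       disease_noise_sd_y = 0.3,
                       seed = 1) {
  classes <- c("suppressed_activated", "suppressed_repressed",
               "induced_activated", "induced_repressed",
               "colonization_only", "genotype_only", "null")
  if (!setequal(names(class_fractions), classes)) {
    stop("class_fractions must be named over: ", paste(classes, collapse = ", "),
         call. = FALSE)
  }
  class_fractions <- class_fractions[classes]
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1", call. = FALSE)
  }
  probs <- c(class_fractions, peak_gf_bias = peak_gf_bias,
             background_peak_rate = background_peak_rate,
             ortholog_dropout = ortholog_dropout, paralog_rate = paralog_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  need <- c("WTGF", "WTCV", "MutGF", "MutCV")
  if (!setequal(names(n_reps), need)) stop("n_reps must be named WTGF, WTCV, MutGF, MutCV", call. = FALSE)
  n_reps <- n_reps[need]
  if (any(n_reps < 2)) stop("each design cell needs >= 2 replicates", call. = FALSE)
  if (is.null(names(chrom_sizes)) || !length(chrom_sizes)) {
    stop("chrom_sizes must be a named non-empty vector", call. = FALSE)
  }
  if (dispersion <= 0 || disease_noise_sd_x <= 0 || disease_noise_sd_y <= 0) {
    stop("dispersion and disease noise SDs must be positive", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), chrom_sizes = chrom_sizes,
                 n_reps = n_reps, class_fractions = class_fractions,
                 effect_size = effect_size, interaction = interaction,
                 dispersion = dispersion,
                 base_mean_log_range = base_mean_log_range,
                 depth_log_sd = depth_log_sd, peak_gf_bias = peak_gf_bias,
                 background_peak_rate = background_peak_rate,
                 peak_width_range = peak_width_range,
                 peak_height = peak_height,
                 ortholog_dropout = ortholog_dropout,
                 paralog_rate = paralog_rate,
                 disease_true_slope = disease_true_slope,
                 disease_noise_sd_x = disease_noise_sd_x,
                 disease_noise_sd_y = disease_noise_sd_y,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Derived substream seeds keep each generator deterministic on its own and
## the whole dataset deterministic end to end (all < 2^31).
stage_seed <- function(config, offset) {
  (config$seed %% 100000L) * 16384L + offset
}

MIN_TSS_SPACING <- 2000L

#' Simulate a gene annotation
#'
#' Places `n_genes` TSSs uniformly across the configured chromosomes
#' (allocated proportionally to length) with a minimum spacing of 2 kb and a
#' random strand. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return A [gene_annotation()] with ids `g0001`, `g0002`, ...
#' @export
simulate_annotation <- function(config) {
  set.seed(stage_seed(config, 1L))
  sizes <- config$chrom_sizes
  n <- config$n_genes
  alloc <- floor(n * sizes / sum(sizes))
  rem <- n - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  s <- MIN_TSS_SPACING
  over <- names(sizes)[sizes < alloc * s]
  if (length(over)) {
    stop(sprintf("genome too small: %s needs %d genes at %d bp spacing",
                 over[1], alloc[over[1]], s), call. = FALSE)
  }
  rows <- lapply(names(sizes), function(chr) {
    k <- alloc[[chr]]
    if (k == 0) return(NULL)
    slack <- sizes[[chr]] - k * s
    pos <- sort(stats::runif(k, 0, slack)) + (seq_len(k) - 1) * s
    data.frame(chrom = chr, tss = as.integer(floor(pos)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  width <- max(4L, nchar(as.character(n)))
  gene_annotation(sprintf(paste0("g%0", width, "d"), seq_len(n)),
                  tab$chrom,
                  sample(c("+", "-"), n, replace = TRUE),
                  tab$tss)
}

#' Simulate a 2x2 count matrix with planted class effects
#'
#' Counts are NB(mu, dispersion) with
#' `log2 mu = baseline + col_effect*[GF] + geno_effect*[WT] + interaction*[WT&GF]`
#' scaled by per-sample depth factors. Class-determined effects:
#' suppressed classes have `col_effect = +effect_size` (higher germ-free),
#' induced classes `-effect_size`; activated classes have
#' `geno_effect = +effect_size` (higher wild-type), repressed `-effect_size`;
#' single-axis classes draw a random sign on their one axis; null genes have
#' no effect.
#'
#' @param annotation a [gene_annotation()].
#' @param config a [sim_config()].
#' @return A list with `counts` (a [count_matrix()]) and `truth` (class
#'   `ground_truth`: per-gene `class`, `col_effect` (true GF-vs-CV log2FC
#'   within WT), `geno_effect` (true WT-vs-Mut log2FC within CV),
#'   `base_log2_mean`, `depth` per sample).
#' @export
simulate_counts <- function(annotation, config) {
  if (!nrow(annotation)) stop("empty annotation", call. = FALSE)
  set.seed(stage_seed(config, 2L))
  n <- nrow(annotation)
  cls <- sample(names(config$class_fractions), n, replace = TRUE,
                prob = config$class_fractions)
  e <- config$effect_size
  col_effect <- numeric(n)
  geno_effect <- numeric(n)
  col_effect[cls %in% c("suppressed_activated", "suppressed_repressed")] <- e
  col_effect[cls %in% c("induced_activated", "induced_repressed")] <- -e
  geno_effect[cls %in% c("suppressed_activated", "induced_activated")] <- e
  geno_effect[cls %in% c("suppressed_repressed", "induced_repressed")] <- -e
  only_c <- cls == "colonization_only"
  col_effect[only_c] <- e * sample(c(-1, 1), sum(only_c), replace = TRUE)
  only_g <- cls == "genotype_only"
  geno_effect[only_g] <- e * sample(c(-1, 1), sum(only_g), replace = TRUE)

  cells <- names(config$n_reps)
  design <- do.call(rbind, lapply(cells, function(cell) {
    k <- config$n_reps[[cell]]
    data.frame(sample = sprintf("%s_%d", cell, seq_len(k)),
               genotype = if (startsWith(cell, "WT")) "WT" else "Mut",
               colonization = if (endsWith(cell, "GF")) "GF" else "CV",
               replicate = seq_len(k), stringsAsFactors = FALSE)
  }))
  base <- stats::runif(n, config$base_mean_log_range[1], config$base_mean_log_range[2])
  depth <- exp(stats::rnorm(nrow(design), 0, config$depth_log_sd))
  names(depth) <- design$sample
  log2mu <- outer(col_effect, as.numeric(design$colonization == "GF")) +
    outer(geno_effect, as.numeric(design$genotype == "WT")) +
    config$interaction * outer(rep(1, n), as.numeric(
      design$genotype == "WT" & design$colonization == "GF")) +
    base
  mu <- sweep(2^log2mu, 2, depth, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                   n, nrow(design),
                   dimnames = list(annotation$gene_id, design$sample))
  truth <- structure(list(gene_id = annotation$gene_id,
                          class = stats::setNames(cls, annotation$gene_id),
                          col_effect = stats::setNames(col_effect, annotation$gene_id),
                          geno_effect = stats::setNames(geno_effect, annotation$gene_id),
                          base_log2_mean = stats::setNames(base, annotation$gene_id),
                          depth = depth,
                          disease_true_slope = config$disease_true_slope),
                     class = "ground_truth")
  list(counts = count_matrix(counts, design), truth = truth)
}

## Piecewise-constant track from triangular bumps over a flat background.
## Bumps are discretized in 25 bp steps; overlapping bumps add.
build_track <- function(chrom_sizes, bump_chrom, bump_summit, bump_halfwidth,
                        bump_height, background = 1, step = 25) {
  rows <- list()
  for (chr in names(chrom_sizes)) {
    L <- chrom_sizes[[chr]]
    sel <- which(bump_chrom == chr)
    ## event list: value changes at segment starts (+v) and ends (-v)
    pos <- c(0, L); delta <- c(background, -background)
    for (i in sel) {
      w <- bump_halfwidth[i]
      edges <- seq(max(0, bump_summit[i] - w), min(L, bump_summit[i] + w), by = step)
      if (length(edges) < 2) next
      mids <- (edges[-1] + edges[-length(edges)]) / 2
      v <- bump_height[i] * pmax(0, 1 - abs(mids - bump_summit[i]) / w)
      pos <- c(pos, edges[-length(edges)], edges[-1])
      delta <- c(delta, v, -v)
    }
    ord <- order(pos)
    pos <- pos[ord]; delta <- delta[ord]
    agg <- rowsum(delta, pos)
    bp <- as.numeric(rownames(agg))
    val <- cumsum(agg[, 1])
    k <- length(bp)
    if (k < 2) next
    seg <- data.frame(chrom = chr, start = bp[-k], end = bp[-1],
                      value = pmax(0, round(val[-k], 9)),
                      stringsAsFactors = FALSE)
    seg <- seg[seg$end > seg$start, , drop = FALSE]
    ## merge runs of equal value
    if (nrow(seg) > 1) {
      run <- cumsum(c(TRUE, abs(diff(seg$value)) > 1e-12))
      seg <- data.frame(chrom = chr,
                        start = tapply(seg$start, run, min),
                        end = tapply(seg$end, run, max),
                        value = tapply(seg$value, run, `[`, 1),
                        stringsAsFactors = FALSE)
    }
    rows[[chr]] <- seg
  }
  all <- do.call(rbind, rows)
  signal_track(all$chrom, all$start, all$end, all$value,
               library_size = sum(all$value * (all$end - all$start)))
}

#' Simulate binding peaks and coverage tracks for two conditions
#'
#' Every planted-effect gene receives one peak (width in
#' `peak_width_range`, summit recorded) close to its TSS. The peak is
#' specific to the gene's expression-concordant condition with probability
#' `peak_gf_bias` (GF-specific for genes higher in GF, CV-specific for genes
#' higher in CV; genotype-only genes get shared peaks), otherwise shared.
#' Null genes contribute background peaks at random positions (in both
#' conditions) at rate `background_peak_rate`. Coverage tracks carry a
#' triangular signal bump at each present peak's summit over a flat
#' background of 1.
#'
#' @param annotation a [gene_annotation()].
#' @param truth ground truth from [simulate_counts()].
#' @param config a [sim_config()].
#' @return A list: `peaks_gf`, `peaks_cv` ([genomic_regions()] with summits
#'   and condition labels), `track_gf`, `track_cv` ([signal_track()]s), and
#'   `peak_truth` (data.frame with `name`, `gene_id`, `specificity` in
#'   GF/CV/shared/background).
#' @export
simulate_peaks <- function(annotation, truth, config) {
  set.seed(stage_seed(config, 3L))
  planted <- which(truth$class[annotation$gene_id] != "null")
  nulls <- which(truth$class[annotation$gene_id] == "null")
  wr <- config$peak_width_range
  n_p <- length(planted)
  width <- sample(wr[1]:wr[2], n_p, replace = TRUE)
  ## summit near the TSS (well inside the assignment radius and closer to the
  ## target gene than to any neighbour at the 2 kb spacing floor)
  offset <- sample(-900:900, n_p, replace = TRUE)
  summit <- annotation$tss[planted] + offset
  chrom <- annotation$chrom[planted]
  summit <- pmax(summit, 1L)
  start <- pmax(0L, summit - width %/% 2L)
  end <- start + width
  col_eff <- truth$col_effect[annotation$gene_id[planted]]
  u <- stats::runif(n_p)
  specificity <- rep("shared", n_p)
  specificity[col_eff > 0 & u < config$peak_gf_bias] <- "GF"
  specificity[col_eff < 0 & u < config$peak_gf_bias] <- "CV"
  name <- paste0("pk_", annotation$gene_id[planted])

  n_bg <- stats::rbinom(1, length(nulls), config$background_peak_rate)
  if (n_bg > 0) {
    bg_chr <- sample(names(config$chrom_sizes), n_bg, replace = TRUE,
                     prob = config$chrom_sizes / sum(config$chrom_sizes))
    bg_w <- sample(wr[1]:wr[2], n_bg, replace = TRUE)
    bg_summit <- floor(stats::runif(n_bg, 1, config$chrom_sizes[bg_chr] - wr[2]))
    chrom <- c(chrom, bg_chr)
    start <- c(start, pmax(0L, as.integer(bg_summit - bg_w %/% 2L)))
    end <- c(end, pmax(0L, as.integer(bg_summit - bg_w %/% 2L)) + bg_w)
    summit <- c(summit, bg_summit)
    specificity <- c(specificity, rep("background", n_bg))
    name <- c(name, sprintf("bg_%04d", seq_len(n_bg)))
  }
  gene_id <- c(annotation$gene_id[planted], rep(NA_character_, n_bg))
  in_gf <- specificity %in% c("GF", "shared", "background")
  in_cv <- specificity %in% c("CV", "shared", "background")
  make_set <- function(sel, cond) {
    genomic_regions(chrom[sel], start[sel], end[sel], name = name[sel],
                    summit_offset = summit[sel] - start[sel],
                    condition = cond)
  }
  peaks_gf <- make_set(in_gf, "GF")
  peaks_cv <- make_set(in_cv, "CV")
  halfw <- (end - start)
  track_gf <- build_track(config$chrom_sizes, chrom[in_gf], summit[in_gf],
                          halfw[in_gf], rep(config$peak_height, sum(in_gf)))
  track_cv <- build_track(config$chrom_sizes, chrom[in_cv], summit[in_cv],
                          halfw[in_cv], rep(config$peak_height, sum(in_cv)))
  list(peaks_gf = peaks_gf, peaks_cv = peaks_cv,
       track_gf = track_gf, track_cv = track_cv,
       peak_truth = data.frame(name = name, gene_id = gene_id,
                               specificity = specificity,
                               stringsAsFactors = FALSE))
}

#' Simulate replicated region counts from condition tracks
#'
#' For each region of the union peak set, the expected count in a condition
#' is the integral of that condition's coverage track over the region;
#' replicate counts are NB draws around depth-scaled means, giving a region
#' count matrix the differential test can consume.
#'
#' @param regions union [genomic_regions()] set (e.g. GF and CV peaks
#'   combined and deduplicated by name).
#' @param track_gf,track_cv condition [signal_track()]s.
#' @param config a [sim_config()].
#' @param n_reps replicates per condition (default 3 and 3).
#' @return A [count_matrix()] of regions x samples (genotype fixed at WT;
#'   colonization GF/CV distinguishes the conditions).
#' @export
simulate_region_counts <- function(regions, track_gf, track_cv, config,
                                   n_reps = c(GF = 3, CV = 3)) {
  set.seed(stage_seed(config, 4L))
  mean_of <- function(track) {
    out <- numeric(nrow(regions))
    for (chr in unique(regions$chrom)) {
      ix <- which(regions$chrom == chr)
      cumf <- track_cumulative(track, chr)
      out[ix] <- cumf(regions$end[ix]) - cumf(regions$start[ix])
    }
    out / 10   # per-10bp read units keep counts in a realistic range
  }
  mu_gf <- mean_of(track_gf)
  mu_cv <- mean_of(track_cv)
  design <- data.frame(
    sample = c(sprintf("GF_%d", seq_len(n_reps[["GF"]])),
               sprintf("CV_%d", seq_len(n_reps[["CV"]]))),
    genotype = "WT",
    colonization = rep(c("GF", "CV"), n_reps[c("GF", "CV")]),
    replicate = c(seq_len(n_reps[["GF"]]), seq_len(n_reps[["CV"]])),
    stringsAsFactors = FALSE)
  depth <- exp(stats::rnorm(nrow(design), 0, config$depth_log_sd))
  mu <- cbind(matrix(mu_gf, nrow(regions), n_reps[["GF"]]),
              matrix(mu_cv, nrow(regions), n_reps[["CV"]]))
  mu <- sweep(mu, 2, depth, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                   nrow(regions), nrow(design),
                   dimnames = list(regions$name, design$sample))
  count_matrix(counts, design)
}

#' Simulate pairwise ortholog tables with dropout and paralog noise
#'
#' The annotation's gene ids are treated as the zebrafish namespace; mouse
#' and human orthologs are named `m_<id>` and `h_<id>`. Each gene enters a
#' pairwise table with probability `1 - ortholog_dropout`; with probability
#' `paralog_rate` a conflicting extra partner is injected (a second gene
#' mapping to the same partner), which the one-to-one filter later removes.
#'
#' @param annotation a [gene_annotation()].
#' @param config a [sim_config()].
#' @return A list: `human_mouse` and `mouse_zebrafish` ([ortholog_map()]s,
#'   unfiltered), and `true_pairs` (data.frame `human`, `mouse`, `zebrafish`
#'   of the planted true bijection rows present in both tables).
#' @export
simulate_ortholog_tables <- function(annotation, config) {
  if (!nrow(annotation)) stop("empty annotation", call. = FALSE)
  set.seed(stage_seed(config, 5L))
  ids <- annotation$gene_id
  n <- length(ids)
  keep_hm <- stats::runif(n) >= config$ortholog_dropout
  keep_mz <- stats::runif(n) >= config$ortholog_dropout
  par_hm <- stats::runif(n) < config$paralog_rate
  par_mz <- stats::runif(n) < config$paralog_rate
  p0 <- function(prefix, x) paste0(prefix, x, recycle0 = TRUE)
  hm_a <- c(p0("h_", ids[keep_hm]), p0("hpar_", ids[keep_hm & par_hm]))
  hm_b <- c(p0("m_", ids[keep_hm]), p0("m_", ids[keep_hm & par_hm]))
  mz_a <- c(p0("m_", ids[keep_mz]), p0("mpar_", ids[keep_mz & par_mz]))
  mz_b <- c(ids[keep_mz], ids[keep_mz & par_mz])
  true_ok <- keep_hm & keep_mz & !par_hm & !par_mz
  list(human_mouse = ortholog_map(hm_a, hm_b, "human", "mouse"),
       mouse_zebrafish = ortholog_map(mz_a, mz_b, "mouse", "zebrafish"),
       true_pairs = data.frame(human = p0("h_", ids[true_ok]),
                               mouse = p0("m_", ids[true_ok]),
                               zebrafish = ids[true_ok],
                               stringsAsFactors = FALSE))
}

#' Simulate a disease differential-gene list tied to the planted effects
#'
#' For every gene with a human ortholog, the disease log2FC is
#' `y = disease_true_slope * x_star + eps_y` where `x_star` is the planted
#' MutCV/WTCV log2 fold change (`-geno_effect`). Genes with a nonzero
#' planted genotype effect form the list's significant subset and receive a
#' direction label `sign(y)`; others have direction `NA`. The attribute
#' `x_observed` carries the noisy observed comparison axis
#' `x_star + eps_x` for desk-scale slope-recovery checks.
#'
#' @param truth ground truth from [simulate_counts()].
#' @param orthologs result of [simulate_ortholog_tables()].
#' @param config a [sim_config()].
#' @param disease_label label for the list.
#' @return A [disease_gene_set()] in the human namespace with attributes
#'   `x_observed` and `x_star` (named by human gene id).
#' @export
simulate_disease_list <- function(truth, orthologs, config,
                                  disease_label = "synthetic-IBD") {
  set.seed(stage_seed(config, 6L))
  hm <- orthologs$human_mouse
  mz <- orthologs$mouse_zebrafish
  ## human genes with a (possibly ambiguous) path to an annotated gene
  z_of <- stats::setNames(mz$gene_b, mz$gene_a)
  zid <- z_of[hm$gene_b]
  ok <- !is.na(zid) & zid %in% names(truth$geno_effect) &
    !duplicated(hm$gene_a)
  human <- hm$gene_a[ok]
  x_star <- -truth$geno_effect[zid[ok]]
  y <- config$disease_true_slope * x_star +
    stats::rnorm(length(x_star), 0, config$disease_noise_sd_y)
  x_obs <- x_star + stats::rnorm(length(x_star), 0, config$disease_noise_sd_x)
  direction <- ifelse(x_star != 0, ifelse(y > 0, "up", "down"), NA_character_)
  ## guard the sign-consistency invariant for the rare y == 0 draw
  direction[y == 0] <- NA_character_
  ds <- disease_gene_set(human, direction, y, disease_label)
  attr(ds, "x_observed") <- stats::setNames(x_obs, human)
  attr(ds, "x_star") <- stats::setNames(as.numeric(x_star), human)
  ds
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits exactly the files the readers consume: `annotation.tsv`,
#' `counts.tsv`, `peaks_gf.bed`/`peaks_cv.bed` (with summit offsets in a
#' side TSV), `track_gf.bedgraph`/`track_cv.bedgraph`, ortholog TSVs, the
#' disease list, and `ground_truth.json`.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(config)
  sim <- simulate_counts(ann, config)
  pk <- simulate_peaks(ann, sim$truth, config)
  orth <- simulate_ortholog_tables(ann, config)
  ds <- simulate_disease_list(sim$truth, orth, config)
  write_gene_annotation(ann, file.path(dir, "annotation.tsv"))
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  utils::write.table(sim$counts$design, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(pk$peaks_gf, file.path(dir, "peaks_gf.bed"))
  write_bed(pk$peaks_cv, file.path(dir, "peaks_cv.bed"))
  for (cond in c("gf", "cv")) {
    set <- if (cond == "gf") pk$peaks_gf else pk$peaks_cv
    utils::write.table(
      data.frame(name = set$name, summit_offset = set$summit_offset),
      file.path(dir, sprintf("summits_%s.tsv", cond)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_bedgraph(pk$track_gf, file.path(dir, "track_gf.bedgraph"))
  write_bedgraph(pk$track_cv, file.path(dir, "track_cv.bedgraph"))
  write_ortholog_table(orth$human_mouse, file.path(dir, "orthologs_human_mouse.tsv"))
  write_ortholog_table(orth$mouse_zebrafish, file.path(dir, "orthologs_mouse_zebrafish.tsv"))
  write_disease_list(ds, file.path(dir, "disease.tsv"))
  truth_json <- list(
    class = as.list(sim$truth$class),
    col_effect = as.list(sim$truth$col_effect),
    geno_effect = as.list(sim$truth$geno_effect),
    disease_true_slope = config$disease_true_slope,
    library_size_gf = pk$track_gf$library_size,
    library_size_cv = pk$track_cv$library_size)
  jsonlite::write_json(truth_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(annotation = ann, counts = sim$counts, truth = sim$truth,
                 peaks = pk, orthologs = orth, disease = ds))
}
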