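#' Pipeline configuration
#'
#' Bundles the simulation block and the analysis thresholds: gene-level
#' q cut 0.05, region-level q cut 0.01, 10 kb assignment radius, 1000 bp
#' profile flank with 50 bp bins, and Deming error-variance ratio 1.
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param q_gene gene-level significance threshold on BH-adjusted values.
#' @param q_region region-level significance threshold.
#' @param max_distance peak-to-gene assignment radius in bp.
#' @param flank,bin_width profile window parameters in bp.
#' @param delta Deming error-variance ratio.
#' @param input_dir optional dataset directory in the [simulate_dataset()]
#'   layout; when given, inputs are loaded from files instead of simulated
#'   (exactly one of the two sources is used; `sim` then only supplies the
#'   stochastic-stage parameters such as the region-count dispersion).
#' @param outdir output directory for intermediate files and the report;
#'   `NULL` keeps everything in memory.
#' @param seed run seed; overrides `sim$seed` so one integer controls the
#'   whole run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), q_gene = 0.05,
                            q_region = 0.01, max_distance = 10000,
                            flank = 1000, bin_width = 50, delta = 1,
                            input_dir = NULL, outdir = NULL,
                            seed = sim$seed) {
  if (q_gene <= 0 || q_region <= 0 || max_distance <= 0 || flank <= 0 ||
      bin_width <= 0 || delta <= 0) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, q_gene = q_gene, q_region = q_region,
                 max_distance = max_distance, flank = flank,
                 bin_width = bin_width, delta = delta,
                 input_dir = input_dir, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the `sim` block
#' mirrors [sim_config()] (`chrom_sizes`, `n_reps` and `class_fractions` as
#' named maps).
#'
#' @param path path to the YAML file.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  for (field in c("chrom_sizes", "n_reps", "class_fractions")) {
    if (!is.null(sim_args[[field]])) {
      v <- unlist(sim_args[[field]])
      ## YAML scientific notation like "2.0e6" lacks the sign and parses as
      ## character; coerce explicitly
      sim_args[[field]] <- stats::setNames(as.numeric(v), names(v))
    }
  }
  sim <- do.call(sim_config, sim_args)
  args <- y[setdiff(names(y), "sim")]
  do.call(pipeline_config, c(list(sim = sim), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a dataset directory in the layout written by [simulate_dataset()]
#'
#' Expects `annotation.tsv`, `counts.tsv`, `design.tsv`, `peaks_gf.bed` /
#' `peaks_cv.bed` with `summits_gf.tsv` / `summits_cv.tsv`,
#' `track_gf.bedgraph` / `track_cv.bedgraph` (library sizes from
#' `ground_truth.json` when present, else the tracks' own integrals),
#' `orthologs_human_mouse.tsv`, `orthologs_mouse_zebrafish.tsv` and
#' `disease.tsv`. A missing file raises an error naming the path.
#'
#' @param dir dataset directory.
#' @return A list with `annotation`, `counts`, `peaks` (list with
#'   `peaks_gf`, `peaks_cv`, `track_gf`, `track_cv`), `orthologs` (list with
#'   `human_mouse`, `mouse_zebrafish`) and `disease`.
#' @export
load_dataset <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop(sprintf("dataset file missing: %s", p), call. = FALSE)
    p
  }
  ann <- read_gene_annotation(need("annotation.tsv"))
  design <- utils::read.delim(need("design.tsv"), stringsAsFactors = FALSE)
  cm <- read_counts(need("counts.tsv"), design)
  lib <- list(library_size_gf = NULL, library_size_cv = NULL)
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path)
    lib$library_size_gf <- gt$library_size_gf
    lib$library_size_cv <- gt$library_size_cv
  }
  read_peaks <- function(cond) {
    pk <- read_bed(need(sprintf("peaks_%s.bed", cond)),
                   condition = toupper(cond))
    sm <- utils::read.delim(need(sprintf("summits_%s.tsv", cond)),
                            stringsAsFactors = FALSE)
    pk$summit_offset <- as.integer(sm$summit_offset[match(pk$name, sm$name)])
    pk
  }
  read_track <- function(cond, lib_size) {
    p <- need(sprintf("track_%s.bedgraph", cond))
    if (is.null(lib_size)) {
      tr <- read_bedgraph(p, 1)
      tr$library_size <- sum(tr$intervals$value *
                               (tr$intervals$end - tr$intervals$start))
      tr
    } else {
      read_bedgraph(p, lib_size)
    }
  }
  list(annotation = ann, counts = cm,
       peaks = list(peaks_gf = read_peaks("gf"), peaks_cv = read_peaks("cv"),
                    track_gf = read_track("gf", lib$library_size_gf),
                    track_cv = read_track("cv", lib$library_size_cv)),
       orthologs = list(
         human_mouse = read_ortholog_table(need("orthologs_human_mouse.tsv"),
                                           "human", "mouse"),
         mouse_zebrafish = read_ortholog_table(
           need("orthologs_mouse_zebrafish.tsv"), "mouse", "zebrafish")),
       disease = read_disease_list(need("disease.tsv")))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), "outdir")], f)
  unname(tools::md5sum(f))
}

#' Deduplicated union of two peak sets
#'
#' Regions are keyed by name; regions present in both sets contribute once.
#' @param a,b [genomic_regions()] peak sets with names.
#' @return A [genomic_regions()] set.
#' @export
union_peak_sets <- function(a, b) {
  extra <- b[!(b$name %in% a$name), , drop = FALSE]
  out <- rbind(as.data.frame(a), as.data.frame(extra))
  genomic_regions(out$chrom, out$start, out$end, out$name, out$score,
                  out$summit_offset)
}

#' Differential region sets from a region count matrix
#'
#' Runs the shared-dispersion NB test with the GF samples as numerator and
#' splits the significant regions by fold-change direction.
#'
#' @param region_counts a [count_matrix()] of regions x samples whose
#'   `colonization` column distinguishes the conditions.
#' @param regions the [genomic_regions()] the rows refer to (matched by
#'   name).
#' @param q_threshold region-level FDR cut (default 0.01).
#' @return A list: `table` (the `expression_comparison` over regions),
#'   `gf_enriched` and `cv_enriched` ([genomic_regions()] subsets).
#' @export
differential_regions <- function(region_counts, regions, q_threshold = 0.01) {
  gf <- region_counts$design$sample[region_counts$design$colonization == "GF"]
  cv <- region_counts$design$sample[region_counts$design$colonization == "CV"]
  tab <- differential_table(region_counts, gf, cv, contrast_label = "GF/CV",
                            q_threshold = q_threshold)
  sig <- tab$gene_id[tab$significant]
  dir_up <- tab$gene_id[tab$significant & tab$log2fc > 0]
  dir_dn <- tab$gene_id[tab$significant & tab$log2fc < 0]
  list(table = tab,
       gf_enriched = regions[regions$name %in% dir_up, , drop = FALSE],
       cv_enriched = regions[regions$name %in% dir_dn, , drop = FALSE],
       n_significant = length(sig))
}

#' Run the full integrative analysis on synthetic data
#'
#' Executes, in order: input simulation; the four gene-level differential
#' contrasts (WTCV/WTGF, MutCV/MutGF, WTCV/MutCV, WTGF/MutGF); four-way
#' membership and fold-change quadrant classification; region-level
#' differential testing and nearest-TSS assignment; the
#' enhancer-state/expression KS concordance test; GF/CV peak-set comparison;
#' flanking-signal profiles; ortholog filtering, chaining, hypergeometric
#' enrichment and association proportions; and the Deming concordance grid
#' against the disease list. Identical config and seed give identical
#' reports.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_report` with per-stage summaries and
#'   provenance (`seed`, `config_md5`, `package_version`). When
#'   `config$outdir` is set, intermediate files and `report.json` are
#'   written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  emit <- function(fun, ...) if (!is.null(outdir)) fun(...)
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scfg <- config$sim

  ## --- obtain inputs (simulate or load) -----------------------------------
  if (is.null(config$input_dir)) {
    ann <- simulate_annotation(scfg)
    sim <- simulate_counts(ann, scfg)
    pk <- simulate_peaks(ann, sim$truth, scfg)
    orth <- simulate_ortholog_tables(ann, scfg)
    disease <- simulate_disease_list(sim$truth, orth, scfg)
    cm <- sim$counts
  } else {
    ds <- load_dataset(config$input_dir)
    ann <- ds$annotation; cm <- ds$counts; pk <- ds$peaks
    orth <- ds$orthologs; disease <- ds$disease
  }
  emit(write_gene_annotation, ann, file.path(outdir %||% ".", "annotation.tsv"))
  emit(write_counts, cm, file.path(outdir %||% ".", "counts.tsv"))

  ## --- gene-level differential tables ------------------------------------
  sf <- size_factors(cm)
  pick <- function(g, c) condition_samples(cm, g, c)
  contrasts <- list(
    "WTCV/WTGF" = list(pick("WT", "CV"), pick("WT", "GF")),
    "MutCV/MutGF" = list(pick("Mut", "CV"), pick("Mut", "GF")),
    "WTCV/MutCV" = list(pick("WT", "CV"), pick("Mut", "CV")),
    "WTGF/MutGF" = list(pick("WT", "GF"), pick("Mut", "GF")))
  tables <- lapply(names(contrasts), function(lab) {
    differential_table(cm, contrasts[[lab]][[1]], contrasts[[lab]][[2]],
                       contrast_label = lab, q_threshold = config$q_gene,
                       sf = sf)
  })
  names(tables) <- names(contrasts)
  if (!is.null(outdir)) {
    for (lab in names(tables)) {
      write_differential_table(tables[[lab]], file.path(
        outdir, sprintf("diffexp_%s.tsv", gsub("/", "_vs_", lab))))
    }
  }
  diff_counts <- vapply(tables, function(t) sum(t$significant), integer(1))

  ## --- four-way membership and quadrant classes ---------------------------
  fw <- classify_four_way(tables, config$q_gene)
  x_tab <- swap_contrast(tables[["WTCV/WTGF"]])       # -> WTGF/WTCV
  y_tab <- tables[["WTCV/MutCV"]]
  ord <- match(x_tab$gene_id, y_tab$gene_id)
  labels <- quadrant_classify(x_tab$log2fc, x_tab$q,
                              y_tab$log2fc[ord], y_tab$q[ord],
                              config$q_gene)
  coreg <- coregulation_summary(labels, x_tab$gene_id)
  if (!is.null(outdir)) {
    utils::write.table(data.frame(gene_id = x_tab$gene_id, class = labels),
                       file.path(outdir, "quadrant_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## --- region differential + assignment + KS concordance ------------------
  union_pk <- union_peak_sets(pk$peaks_gf, pk$peaks_cv)
  region_counts <- simulate_region_counts(union_pk, pk$track_gf, pk$track_cv,
                                          scfg)
  dr <- differential_regions(region_counts, union_pk, config$q_region)
  assign_gf_enr <- assign_peaks_to_genes(dr$gf_enriched, ann, config$max_distance)
  assign_cv_enr <- assign_peaks_to_genes(dr$cv_enriched, ann, config$max_distance)
  ks <- ks_region_expression(assign_gf_enr, assign_cv_enr,
                             tables[["WTCV/WTGF"]])

  ## --- peak-set comparison and signal profiles ----------------------------
  sharing <- compare_peak_sets(pk$peaks_gf, pk$peaks_cv)
  prof_gf <- flanking_signal_matrix(pk$peaks_gf, pk$track_gf,
                                    config$flank, config$bin_width)
  prof_cv <- flanking_signal_matrix(pk$peaks_gf, pk$track_cv,
                                    config$flank, config$bin_width)
  mp_gf <- mean_profile(prof_gf)
  mp_cv <- mean_profile(prof_cv)
  if (!is.null(outdir)) {
    write_profile_matrix(prof_gf, file.path(outdir, "profile_gf_sites_gf_signal.tsv"))
    write_profile_matrix(prof_cv, file.path(outdir, "profile_gf_sites_cv_signal.tsv"))
  }

  ## --- ortholog enrichment -------------------------------------------------
  hm <- one_to_one_filter(orth$human_mouse)
  mz <- one_to_one_filter(orth$mouse_zebrafish)
  chain <- chain_orthologs(hm, mz)
  assign_gf_all <- assign_peaks_to_genes(pk$peaks_gf, ann, config$max_distance)
  assign_cv_all <- assign_peaks_to_genes(pk$peaks_cv, ann, config$max_distance)
  assoc_gf_z <- unique(stats::na.omit(assign_gf_all$gene_id))
  assoc_cv_z <- unique(stats::na.omit(assign_cv_all$gene_id))
  universe <- chain$gene_a
  assoc_sets <- list(GF = chain$gene_a[chain$gene_c %in% assoc_gf_z],
                     CV = chain$gene_a[chain$gene_c %in% assoc_cv_z])
  queries <- list(
    down = disease$gene[!is.na(disease$direction) & disease$direction == "down"],
    up = disease$gene[!is.na(disease$direction) & disease$direction == "up"])
  enrich <- enrichment_table(queries, assoc_sets, universe)
  mouse_assoc <- mz$gene_a[mz$gene_b %in% assoc_gf_z]
  props <- association_proportions(disease, mouse_assoc, hm)
  if (!is.null(outdir)) {
    utils::write.table(enrich, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(props, file.path(outdir, "association_proportions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## --- Deming concordance grid --------------------------------------------
  pair_of <- function(lab, restrict = NULL, complement = FALSE) {
    build_pairs(tables[[lab]], disease, map = chain,
                map_col_a = "gene_c", map_col_b = "gene_a",
                restrict = restrict, restrict_col = "gene_c",
                complement = complement,
                labels = c(lab, attr(disease, "disease_label")))
  }
  pairs_sets <- list(
    "WTCV/WTGF" = pair_of("WTCV/WTGF"),
    "MutCV/MutGF" = pair_of("MutCV/MutGF"),
    "MutCV/WTCV" = {
      t <- swap_contrast(tables[["WTCV/MutCV"]])
      build_pairs(t, disease, map = chain, map_col_a = "gene_c",
                  map_col_b = "gene_a",
                  labels = c("MutCV/WTCV", attr(disease, "disease_label")))
    },
    "MutGF/WTGF" = {
      t <- swap_contrast(tables[["WTGF/MutGF"]])
      build_pairs(t, disease, map = chain, map_col_a = "gene_c",
                  map_col_b = "gene_a",
                  labels = c("MutGF/WTGF", attr(disease, "disease_label")))
    },
    "MutCV/WTCV (assoc)" = {
      t <- swap_contrast(tables[["WTCV/MutCV"]])
      build_pairs(t, disease, map = chain, map_col_a = "gene_c",
                  map_col_b = "gene_a", restrict = assoc_gf_z,
                  restrict_col = "gene_c",
                  labels = c("MutCV/WTCV (assoc)", attr(disease, "disease_label")))
    })
  grid <- concordance_grid(pairs_sets, reference = "WTCV/WTGF",
                           delta = config$delta)

  report <- structure(list(
    provenance = list(seed = config$seed, config_md5 = config_hash(config),
                      package_version = as.character(utils::packageVersion("gnotoreg")),
                      n_genes = nrow(ann)),
    differential = list(counts = as.list(diff_counts),
                        union_size = fw$union_size,
                        venn = as.list(fw$venn)),
    coregulation = list(n_shared = coreg$n_shared,
                        counts = as.list(coreg$counts),
                        suppressed_activated_fraction = coreg$suppressed_activated_fraction),
    regions = list(n_regions = nrow(union_pk),
                   n_differential = dr$n_significant,
                   n_gf_enriched = nrow(dr$gf_enriched),
                   n_cv_enriched = nrow(dr$cv_enriched)),
    ks = list(D = ks$D, p = ks$p, shift_sign = ks$shift_sign,
              n_cv = ks$n1, n_gf = ks$n2, n_both = ks$n_both),
    peak_sharing = list(gf_total = nrow(pk$peaks_gf),
                        cv_total = nrow(pk$peaks_cv),
                        shared_gf = sharing$shared_a,
                        gf_specific = sharing$unique_a,
                        cv_specific = sharing$unique_b),
    profiles = list(gf_mean_at_summit = mp_gf$mean[which.min(abs(mp_gf$bin_center))],
                    cv_mean_at_summit = mp_cv$mean[which.min(abs(mp_cv$bin_center))]),
    enrichment = lapply(seq_len(nrow(enrich)), function(i) as.list(enrich[i, ])),
    association_proportions = lapply(seq_len(nrow(props)), function(i) as.list(props[i, ])),
    deming = list(slopes = as.list(grid$slopes),
                  se = lapply(grid$fits, `[[`, "se_slope"),
                  tests = lapply(seq_len(nrow(grid$tests)), function(i) as.list(grid$tests[i, ])))),
    class = "pipeline_report")
  if (!is.null(outdir)) {
    jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Integrative pipeline report (seed", x$provenance$seed, ")\n")
  cat("  differential genes per contrast:",
      paste(sprintf("%s=%d", names(x$differential$counts),
                    unlist(x$differential$counts)), collapse = ", "), "\n")
  cat(sprintf("  union of differential genes: %d\n", x$differential$union_size))
  cat(sprintf("  coregulated (both axes): %d; suppressed & activated fraction: %.3f\n",
              x$coregulation$n_shared,
              x$coregulation$suppressed_activated_fraction))
  cat(sprintf("  KS concordance: D = %.3f, p = %.3g, shift %+d\n",
              x$ks$D, x$ks$p, x$ks$shift_sign))
  cat(sprintf("  peaks: %d GF (%d GF-specific), %d CV (%d CV-specific)\n",
              x$peak_sharing$gf_total, x$peak_sharing$gf_specific,
              x$peak_sharing$cv_total, x$peak_sharing$cv_specific))
  cat("  Deming slopes:",
      paste(sprintf("%s=%.3f", names(x$deming$slopes),
                    unlist(x$deming$slopes)), collapse = ", "), "\n")
  invisible(x)
}
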