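#' Four-way differential membership and Venn regions
#'
#' Flags each gene as significant (q below threshold) in each of four labeled
#' contrasts, and tabulates the union and all 15 disjoint Venn regions. The
#' region counts sum to the union size by construction, which is asserted.
#'
#' @param comparisons named list of exactly four `expression_comparison`
#'   tables covering the same gene universe (same ids, any order).
#' @param q_threshold significance cut applied to each contrast's `q`.
#' @return A list of class `four_way_membership`: `flags` (genes x 4 logical
#'   matrix), `union_genes`, `union_size`, `venn` (named counts of the 15
#'   disjoint regions, names like `"WTCV/WTGF+WTCV/MutCV"`),
#'   `pairwise` (4 x 4 matrix of pairwise intersection sizes).
#' @export
classify_four_way <- function(comparisons, q_threshold = 0.05) {
  if (length(comparisons) != 4) stop("exactly four comparisons required", call. = FALSE)
  labels <- names(comparisons)
  if (is.null(labels)) {
    labels <- vapply(comparisons, function(x) attr(x, "contrast_label"), "")
  }
  universe <- sort(comparisons[[1]]$gene_id)
  for (cmp in comparisons[-1]) {
    if (!identical(sort(cmp$gene_id), universe)) {
      stop("comparisons cover different gene universes", call. = FALSE)
    }
  }
  flags <- vapply(comparisons, function(cmp) {
    q <- cmp$q[match(universe, cmp$gene_id)]
    !is.na(q) & q < q_threshold
  }, logical(length(universe)))
  dimnames(flags) <- list(universe, labels)
  in_union <- rowSums(flags) > 0
  sig <- flags[in_union, , drop = FALSE]
  key <- apply(sig, 1, function(f) paste(labels[f], collapse = "+"))
  combos <- unlist(lapply(1:4, function(k) {
    utils::combn(labels, k, paste, collapse = "+", simplify = FALSE)
  }))
  venn <- table(factor(key, levels = combos))
  venn <- stats::setNames(as.integer(venn), combos)
  stopifnot(sum(venn) == sum(in_union))
  pairwise <- crossprod(flags)
  structure(list(flags = flags,
                 union_genes = universe[in_union],
                 union_size = sum(in_union),
                 venn = venn, pairwise = pairwise,
                 q_threshold = q_threshold),
            class = "four_way_membership")
}

#' Quadrant classification of genes over two fold-change axes
#'
#' Genes significant on both axes are labeled by their fold-change sign pair;
#' all other genes are `not_coregulated`. With the microbiota axis as x
#' (GF over CV: positive means higher germ-free, i.e. suppressed by the
#' microbiota) and the genotype axis as y (WT over mutant: positive means
#' activated by the factor), the four labels are:
#' `(+,+)` suppressed_activated, `(+,-)` suppressed_repressed,
#' `(-,+)` induced_activated, `(-,-)` induced_repressed.
#'
#' @param fc_x,q_x fold change and q-value on the x axis (e.g. WTGF/WTCV).
#' @param fc_y,q_y fold change and q-value on the y axis (e.g. WTCV/MutCV).
#' @param q_threshold significance cut applied to both axes.
#' @return Character vector of class labels. A fold change of exactly 0 with
#'   a significant q is contradictory input and raises an error. `NA` q
#'   (untested gene) yields `not_coregulated`.
#' @export
quadrant_classify <- function(fc_x, q_x, fc_y, q_y, q_threshold = 0.05) {
  n <- length(fc_x)
  stopifnot(length(q_x) == n, length(fc_y) == n, length(q_y) == n)
  sig <- !is.na(q_x) & !is.na(q_y) & q_x < q_threshold & q_y < q_threshold
  if (any(sig & (!is.finite(fc_x) | !is.finite(fc_y)))) {
    stop("non-finite fold change for a significant gene", call. = FALSE)
  }
  if (any(sig & (fc_x == 0 | fc_y == 0))) {
    stop("zero fold change with significant q: contradictory input", call. = FALSE)
  }
  out <- rep("not_coregulated", n)
  out[sig & fc_x > 0 & fc_y > 0] <- "suppressed_activated"
  out[sig & fc_x > 0 & fc_y < 0] <- "suppressed_repressed"
  out[sig & fc_x < 0 & fc_y > 0] <- "induced_activated"
  out[sig & fc_x < 0 & fc_y < 0] <- "induced_repressed"
  out
}

#' Summary of coregulated gene classes
#'
#' Counts quadrant labels over the shared-significant set and reports the
#' fraction of microbiota-suppressed genes that are also activated by the
#' genotype axis, i.e.
#' `suppressed_activated / (suppressed_activated + suppressed_repressed)`.
#'
#' @param labels character vector from [quadrant_classify()].
#' @param gene_ids optional gene ids parallel to `labels`.
#' @return A list: `n_shared` (genes significant on both axes), `counts`
#'   (named per-class counts over the four quadrant classes),
#'   `suppressed_activated_fraction` (`NA` when no suppressed genes), and
#'   `genes` (per-class gene id lists when `gene_ids` given).
#' @export
coregulation_summary <- function(labels, gene_ids = NULL) {
  classes <- c("suppressed_activated", "suppressed_repressed",
               "induced_activated", "induced_repressed")
  counts <- vapply(classes, function(k) sum(labels == k), integer(1))
  n_shared <- sum(counts)
  denom <- counts[["suppressed_activated"]] + counts[["suppressed_repressed"]]
  frac <- if (denom > 0) counts[["suppressed_activated"]] / denom else NA_real_
  genes <- NULL
  if (!is.null(gene_ids)) {
    genes <- lapply(classes, function(k) gene_ids[labels == k])
    names(genes) <- classes
  }
  list(n_shared = n_shared, counts = counts,
       suppressed_activated_fraction = frac, genes = genes)
}

## Survival function of the asymptotic Kolmogorov distribution:
## P(sqrt(n) D > t) = 2 sum_{k>=1} (-1)^{k-1} exp(-2 k^2 t^2)
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(p, .Machine$double.xmin))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the maximum absolute difference of the two empirical
#' CDFs over the pooled sample points. The default p-value uses the
#' asymptotic Kolmogorov distribution at effective sample size
#' `n1*n2/(n1+n2)`; for small problems (`n1*n2 <= 10^4`, no ties) an exact
#' p-value via [stats::psmirnov()] is available.
#'
#' @param x,y numeric samples, each non-empty.
#' @param exact `NULL` (exact when `n1*n2 <= 1e4` and tie-free), or logical.
#' @return A list of class `ks_result`: `D`, `p`, `n1`, `n2`, `shift_sign`
#'   (sign of `mean(x) - mean(y)`), `method`.
#' @export
ks_two_sample <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA in sample", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  pooled <- sort(unique(c(x, y)))
  Fx <- vapply(pooled, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pooled, function(t) mean(y <= t), numeric(1))
  D <- max(abs(Fx - Fy))
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (n1 * n2 <= 1e4) && !ties
  if (exact && ties) {
    warning("ties present; falling back to the asymptotic p-value")
    exact <- FALSE
  }
  if (exact) {
    p <- 1 - stats::psmirnov(D, sizes = c(n1, n2), two.sided = TRUE)
    p <- min(1, max(p, .Machine$double.xmin))
    method <- "exact"
  } else {
    neff <- n1 * n2 / (n1 + n2)
    p <- kolmogorov_sf(sqrt(neff) * D)
    method <- "asymptotic"
  }
  structure(list(D = D, p = p, n1 = n1, n2 = n2,
                 shift_sign = sign(mean(x) - mean(y)), method = method),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, p = %.3g (%s), n1 = %d, n2 = %d, shift %+d\n",
              x$D, x$p, x$method, x$n1, x$n2, x$shift_sign))
  invisible(x)
}

#' Concordance of differential-region state with expression direction
#'
#' Tests whether genes near regions enriched in one colonization state are
#' shifted in expression toward that state. Sample A collects the CV/GF log2
#' fold changes of genes assigned to CV-enriched regions; sample B those of
#' genes assigned to GF-enriched regions; the two samples are compared with
#' [ks_two_sample()]. A positive `shift_sign` means CV-region genes sit
#' higher in CV, i.e. enhancer state and expression agree in direction.
#' Genes assigned to both kinds of region contribute to both samples (the
#' count is reported). A `"background"` mode instead compares each group
#' against the full fold-change distribution.
#'
#' @param assignment_gf,assignment_cv [assign_peaks_to_genes()] results for
#'   the GF-enriched and CV-enriched region sets.
#' @param expression an `expression_comparison` whose `log2fc` is CV over GF
#'   (e.g. contrast `"WTCV/WTGF"`).
#' @param mode `"pairwise"` (default) or `"background"`.
#' @return For `"pairwise"`, a `ks_result` with extra fields `n_both`
#'   (genes in both samples) and `mode`. For `"background"`, a list of two
#'   `ks_result`s (`cv_vs_all`, `gf_vs_all`).
#' @export
ks_region_expression <- function(assignment_gf, assignment_cv, expression,
                                 mode = c("pairwise", "background")) {
  mode <- match.arg(mode)
  fc <- stats::setNames(expression$log2fc, expression$gene_id)
  genes_gf <- unique(stats::na.omit(assignment_gf$gene_id))
  genes_cv <- unique(stats::na.omit(assignment_cv$gene_id))
  a <- fc[intersect(genes_cv, names(fc))]
  b <- fc[intersect(genes_gf, names(fc))]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a)) stop("no genes assigned to CV-enriched regions with finite fold change", call. = FALSE)
  if (!length(b)) stop("no genes assigned to GF-enriched regions with finite fold change", call. = FALSE)
  if (mode == "background") {
    all_fc <- fc[is.finite(fc)]
    return(list(cv_vs_all = ks_two_sample(a, all_fc),
                gf_vs_all = ks_two_sample(b, all_fc)))
  }
  res <- ks_two_sample(a, b)
  res$n_both <- length(intersect(names(a), names(b)))
  res$mode <- "pairwise"
  res
}
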