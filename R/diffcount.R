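#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes whose count is positive in every sample, so the per-gene geometric
#' mean is positive) of the ratio count/geometric-mean. Factors are then
#' rescaled to have geometric mean 1, so a contrast of two samples with
#' identical composition but a 2-fold depth difference yields factors
#' (1/sqrt(2), sqrt(2)).
#'
#' @param x a [count_matrix()] or a genes x samples count matrix.
#' @return Named numeric vector of positive per-sample scale factors.
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    stop("size_factors: no gene has positive counts in all samples", call. = FALSE)
  }
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  f <- apply(exp(logc - loggeo), 2, stats::median)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Method-of-moments negative-binomial dispersion
#'
#' Estimates the NB dispersion alpha (variance = mu + alpha * mu^2) from
#' within-group sample variances: each group with mean m and variance s2
#' contributes `(s2 - m) / m^2`, and the per-group estimates are pooled by a
#' degrees-of-freedom-weighted mean, then floored:
#' `alpha = max(floor, pooled (s2 - m) / m^2)`, floor 1e-8. Pooling on the
#' dispersion scale (not the variance scale) keeps the estimate unbiased when
#' group means differ, since alpha is mean-free under the NB
#' mean-variance relation. Operates on normalized counts.
#'
#' @param counts numeric vector (single group) or genes x samples matrix.
#' @param groups factor of group membership per sample (matrix input); every
#'   group needs >= 2 replicates.
#' @param floor lower bound for alpha.
#' @param poisson_scale per-sample scale of the shot-noise term: for counts
#'   normalized by size factors `s`, the variance of a normalized count is
#'   `m/s + alpha*m^2`, so pass `1/s`. Default 1 (unnormalized counts).
#'   Makes the estimate invariant to a global rescaling of library sizes.
#' @return Dispersion estimate(s): a scalar for vector input, a per-gene
#'   vector for matrix input.
#' @export
estimate_dispersion <- function(counts, groups = NULL, floor = 1e-8,
                                poisson_scale = NULL) {
  if (is.null(dim(counts))) {
    counts <- matrix(as.numeric(counts), nrow = 1)
    if (is.null(groups)) groups <- rep("g1", ncol(counts))
  }
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("estimate_dispersion: every group needs >= 2 replicates; ",
         "pool samples into one group for a pooled estimate", call. = FALSE)
  }
  if (is.null(poisson_scale)) poisson_scale <- rep(1, ncol(counts))
  num <- 0; wsum <- 0
  for (g in levels(groups)) {
    sel <- groups == g
    sub <- counts[, sel, drop = FALSE]
    n <- ncol(sub)
    m <- rowMeans(sub)
    v <- rowSums((sub - m)^2) / (n - 1)
    shot <- mean(poisson_scale[sel])
    a_g <- ifelse(m > 0, (v - shot * m) / m^2, 0)
    w <- (n - 1) * (m > 0)
    num <- num + w * a_g
    wsum <- wsum + w
  }
  alpha <- ifelse(wsum > 0, num / wsum, floor)
  alpha <- pmax(floor, alpha)
  if (nrow(counts) == 1) alpha[[1]] else alpha
}

## Vectorized NB mean MLE with fixed dispersion: maximizes
## sum_j y_j log(m s_j) - (y_j + r) log(r + m s_j) over m, per gene.
## Newton iterations on m with positivity clamping; exact (= sum(y)/sum(s))
## in the Poisson limit r -> Inf and whenever size factors are equal.
solve_nb_mean <- function(Y, sf, r, iter = 40L) {
  m <- pmax(rowSums(Y) / sum(sf), 0)
  zero <- m == 0
  sfm <- matrix(sf, nrow(Y), ncol(Y), byrow = TRUE)
  for (i in seq_len(iter)) {
    mu <- m * sfm
    denom <- r + mu
    U <- rowSums(Y) / m - rowSums((Y + r) * sfm / denom)
    H <- -rowSums(Y) / m^2 + rowSums((Y + r) * sfm^2 / denom^2)
    step <- ifelse(H < 0, -U / H, 0)
    step[!is.finite(step)] <- 0
    m_new <- m + step
    m <- ifelse(m_new > 0, m_new, m / 2)
    m[zero] <- 0
  }
  m
}

nb_loglik <- function(Y, sf, r, m) {
  mu <- m %o% sf
  sum(stats::dnbinom(Y, size = matrix(r, nrow(Y), ncol(Y)), mu = mu, log = TRUE))
}

nb_loglik_rows <- function(Y, sf, r, m) {
  mu <- m * matrix(sf, nrow(Y), ncol(Y), byrow = TRUE)
  rowSums(stats::dnbinom(Y, size = matrix(r, nrow(Y), ncol(Y)), mu = mu,
                         log = TRUE))
}

#' Negative-binomial two-group likelihood-ratio test
#'
#' A fully specified shared-dispersion NB test: the dispersion is estimated by
#' pooled method of moments on normalized counts ([estimate_dispersion()]),
#' group means are maximum-likelihood under means scaled by size factors, and
#' the null (common mean) is compared to the alternative (per-group means) by
#' a likelihood-ratio statistic. Because the per-gene dispersion is a plug-in
#' estimate with only `N - 2` residual degrees of freedom at typical replicate
#' numbers, the statistic is referred to an F(1, N - 2) distribution rather
#' than chi-square(1): treating the noisy dispersion as known makes the
#' chi-square reference strongly anti-conservative at 2-3 replicates per
#' group, while the F reference keeps null p-values uniform (the chi-square
#' p is the `N -> Inf` limit). The reported fold change is
#' `log2((m1 + 0.5) / (m2 + 0.5))` on the normalized scale, group 1 being the
#' numerator.
#'
#' When a design has more cells than the two being contrasted (e.g. a full
#' 2x2 with four cells), the dispersion can be estimated once from every
#' cell's within-group variance and passed in via `alpha`/`df2`; the extra
#' residual degrees of freedom sharpen the F reference without any sharing
#' of information across genes.
#'
#' @param counts genes x samples matrix (or vector for one gene) of raw counts
#'   for the two groups only.
#' @param groups factor with two levels; the FIRST level is the numerator.
#'   Each group needs >= 2 samples.
#' @param sf per-sample size factors (default all 1).
#' @param alpha optional per-gene dispersion estimated externally (e.g. from
#'   all design cells); default: estimated from the two groups.
#' @param df2 denominator degrees of freedom of the F reference; defaults to
#'   the residual df of the dispersion estimate (`N - 2` when estimated
#'   internally).
#' @return A data.frame with columns `base_mean`, `log2fc`, `p`, `lrt`.
#' @export
nb_two_group_test <- function(counts, groups, sf = NULL, alpha = NULL,
                              df2 = NULL) {
  if (is.null(dim(counts))) counts <- matrix(as.numeric(counts), nrow = 1)
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples", call. = FALSE)
  if (length(groups) != ncol(counts)) stop("groups length != number of samples", call. = FALSE)
  if (is.null(sf)) sf <- rep(1, ncol(counts))
  if (is.null(alpha)) {
    norm <- sweep(counts, 2, sf, "/")
    alpha <- estimate_dispersion(norm, groups, poisson_scale = 1 / sf)
    if (is.null(df2)) df2 <- ncol(counts) - 2L
  } else if (is.null(df2)) {
    df2 <- ncol(counts) - 2L
  }
  if (nrow(counts) == 1) alpha <- alpha[[1]]
  r <- 1 / alpha
  g1 <- groups == levels(groups)[1]
  m0 <- solve_nb_mean(counts, sf, r)
  m1 <- solve_nb_mean(counts[, g1, drop = FALSE], sf[g1], r)
  m2 <- solve_nb_mean(counts[, !g1, drop = FALSE], sf[!g1], r)
  ll0 <- nb_loglik_rows(counts, sf, r, m0)
  ll1 <- nb_loglik_rows(counts[, g1, drop = FALSE], sf[g1], r, m1) +
    nb_loglik_rows(counts[, !g1, drop = FALSE], sf[!g1], r, m2)
  lrt <- pmax(0, 2 * (ll1 - ll0))
  p <- stats::pf(lrt, df1 = 1, df2 = df2, lower.tail = FALSE)
  data.frame(base_mean = m0, log2fc = log2((m1 + 0.5) / (m2 + 0.5)),
             p = p, lrt = lrt)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values in input order (delegates to [stats::p.adjust()]).
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Select samples of a count matrix by design cell
#'
#' @param cm a [count_matrix()].
#' @param genotype,colonization optional filters (`"WT"`/`"Mut"`,
#'   `"GF"`/`"CV"`).
#' @return Character vector of matching sample names.
#' @export
condition_samples <- function(cm, genotype = NULL, colonization = NULL) {
  d <- cm$design
  keep <- rep(TRUE, nrow(d))
  if (!is.null(genotype)) keep <- keep & d$genotype == genotype
  if (!is.null(colonization)) keep <- keep & d$colonization == colonization
  d$sample[keep]
}

#' Per-gene differential table for one labeled contrast
#'
#' Runs the shared-dispersion NB LRT on the samples of one contrast and
#' BH-adjusts the p-values. Genes with zero counts in all samples of the
#' contrast are excluded from testing and reported with `tested = FALSE`
#' (their fold change is undefined). Size factors are computed on the full
#' matrix so contrasts share a normalization, and each gene's dispersion is
#' pooled over the within-cell variances of ALL design cells (not only the
#' two being contrasted), which raises the residual df of the F reference —
#' within-gene pooling only, never across genes.
#'
#' @param cm a [count_matrix()].
#' @param numerator,denominator disjoint character vectors of sample names
#'   (>= 2 each), e.g. from [condition_samples()].
#' @param contrast_label label recording direction, conventionally
#'   `"NUM/DEN"` such as `"WTCV/WTGF"`.
#' @param q_threshold significance cut on the BH-adjusted value.
#' @param sf optional precomputed size factors for all samples of `cm`.
#' @return A data.frame of class `expression_comparison` with columns
#'   `gene_id`, `base_mean`, `log2fc`, `p`, `q`, `significant`, `tested` and
#'   attributes `contrast_label` and `q_threshold`. Swapping numerator and
#'   denominator negates `log2fc` gene-wise and leaves `p` unchanged.
#' @export
differential_table <- function(cm, numerator, denominator,
                               contrast_label = "A/B", q_threshold = 0.05,
                               sf = NULL) {
  if (length(intersect(numerator, denominator))) {
    stop("numerator and denominator sample sets overlap", call. = FALSE)
  }
  miss <- setdiff(c(numerator, denominator), colnames(cm$counts))
  if (length(miss)) stop("unknown sample: ", miss[1], call. = FALSE)
  if (length(numerator) < 2 || length(denominator) < 2) {
    stop("each side of the contrast needs >= 2 samples", call. = FALSE)
  }
  if (is.null(sf)) sf <- size_factors(cm)
  samples <- c(numerator, denominator)
  sub <- cm$counts[, samples, drop = FALSE]
  groups <- factor(rep(c("num", "den"), c(length(numerator), length(denominator))),
                   levels = c("num", "den"))
  tested <- rowSums(sub) > 0
  ## gene-level dispersion from every design cell with >= 2 replicates
  cell <- interaction(cm$design$genotype, cm$design$colonization, drop = TRUE)
  keep_cells <- names(which(table(cell) >= 2))
  disp_samples <- cm$design$sample[cell %in% keep_cells]
  norm_all <- sweep(cm$counts[, disp_samples, drop = FALSE], 2,
                    sf[disp_samples], "/")
  disp_groups <- droplevels(cell[cell %in% keep_cells])
  alpha_all <- estimate_dispersion(norm_all, disp_groups,
                                   poisson_scale = 1 / sf[disp_samples])
  df_disp <- length(disp_samples) - nlevels(disp_groups)
  res <- data.frame(gene_id = rownames(cm$counts),
                    base_mean = NA_real_, log2fc = NA_real_,
                    p = NA_real_, q = NA_real_,
                    significant = FALSE, tested = tested,
                    stringsAsFactors = FALSE)
  if (any(tested)) {
    fit <- nb_two_group_test(sub[tested, , drop = FALSE], groups, sf[samples],
                             alpha = alpha_all[tested], df2 = df_disp)
    res$base_mean[tested] <- fit$base_mean
    res$log2fc[tested] <- fit$log2fc
    res$p[tested] <- fit$p
    res$q[tested] <- bh_adjust(fit$p)
    res$significant[tested] <- res$q[tested] < q_threshold
  }
  class(res) <- c("expression_comparison", "data.frame")
  attr(res, "contrast_label") <- contrast_label
  attr(res, "q_threshold") <- q_threshold
  res
}

#' Reverse the direction of a differential table
#'
#' @param ec an `expression_comparison`.
#' @return The same table with `log2fc` negated and the contrast label
#'   flipped (`"A/B"` becomes `"B/A"`).
#' @export
swap_contrast <- function(ec) {
  ec$log2fc <- -ec$log2fc
  parts <- strsplit(attr(ec, "contrast_label"), "/", fixed = TRUE)[[1]]
  attr(ec, "contrast_label") <- paste(rev(parts), collapse = "/")
  ec
}

#' Write a differential table as TSV
#'
#' The contrast label and threshold are written as a `#` header comment.
#' @param ec an `expression_comparison`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential_table <- function(ec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# contrast=%s q_threshold=%g",
                     attr(ec, "contrast_label"), attr(ec, "q_threshold")), con)
  utils::write.table(as.data.frame(ec), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
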