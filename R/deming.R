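#' Pair orthologous fold changes from two comparisons
#'
#' Builds one (x, y) point per gene linked by a one-to-one ortholog map (or
#' chain) and present with a finite fold change in both inputs. `x` comes
#' from `comparison_a`, `y` from `comparison_b`. An optional restriction set
#' implements with/without-association splits: restricting to a set and to
#' its complement yields disjoint point sets whose union is the unrestricted
#' set.
#'
#' @param comparison_a an `expression_comparison` or [disease_gene_set()];
#'   its gene ids live in the namespace of `map_col_a`.
#' @param comparison_b an `expression_comparison`; ids in the namespace of
#'   `map_col_b`.
#' @param map a one-to-one [ortholog_map()] or [chain_orthologs()] result;
#'   `NULL` pairs ids directly (shared namespace).
#' @param map_col_a,map_col_b columns of `map` holding the namespaces of the
#'   two comparisons (defaults: first and last gene column).
#' @param restrict optional gene set to restrict to; `restrict_col` names the
#'   map column in whose namespace `restrict` lives.
#' @param complement if `TRUE`, restrict to genes NOT in `restrict`.
#' @param labels length-2 character vector naming the two comparisons.
#' @return A data.frame of class `paired_fold_changes` with columns
#'   `gene_a`, `gene_b`, `x`, `y`; at least 3 pairs are required.
#' @export
build_pairs <- function(comparison_a, comparison_b, map = NULL,
                        map_col_a = NULL, map_col_b = NULL,
                        restrict = NULL, restrict_col = NULL,
                        complement = FALSE, labels = c("A", "B")) {
  fc_of <- function(cmp) {
    if (inherits(cmp, "disease_gene_set")) {
      stats::setNames(cmp$log2fc, cmp$gene)
    } else {
      stats::setNames(cmp$log2fc, cmp$gene_id)
    }
  }
  xa <- fc_of(comparison_a)
  yb <- fc_of(comparison_b)
  if (is.null(map)) {
    shared <- intersect(names(xa), names(yb))
    pairs <- data.frame(gene_a = shared, gene_b = shared,
                        stringsAsFactors = FALSE)
  } else {
    if (!isTRUE(attr(map, "one_to_one")) && !inherits(map, "ortholog_chain")) {
      stop("ortholog map must be one-to-one filtered", call. = FALSE)
    }
    gene_cols <- grep("^gene_", names(map), value = TRUE)
    if (is.null(map_col_a)) map_col_a <- gene_cols[1]
    if (is.null(map_col_b)) map_col_b <- gene_cols[length(gene_cols)]
    pairs <- data.frame(gene_a = as.character(map[[map_col_a]]),
                        gene_b = as.character(map[[map_col_b]]),
                        stringsAsFactors = FALSE)
    if (!is.null(restrict)) {
      rc <- if (is.null(restrict_col)) map_col_a else restrict_col
      inset <- as.character(map[[rc]]) %in% restrict
      pairs <- pairs[if (complement) !inset else inset, , drop = FALSE]
    }
  }
  x <- xa[pairs$gene_a]
  y <- yb[pairs$gene_b]
  ok <- !is.na(x) & !is.na(y) & is.finite(x) & is.finite(y)
  out <- data.frame(gene_a = pairs$gene_a[ok], gene_b = pairs$gene_b[ok],
                    x = as.numeric(x[ok]), y = as.numeric(y[ok]),
                    stringsAsFactors = FALSE)
  if (nrow(out) < 3) {
    stop(sprintf("only %d ortholog-linked pairs with finite fold changes (need >= 3)",
                 nrow(out)), call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("paired_fold_changes", "data.frame")
  attr(out, "labels") <- labels
  out
}

deming_slope_closed_form <- function(sxx, syy, sxy, delta) {
  d <- syy - delta * sxx
  (d + sqrt(d^2 + 4 * delta * sxy^2)) / (2 * sxy)
}

#' Deming (errors-in-variables) regression with jackknife standard error
#'
#' Fits `y = intercept + slope * x` when both axes carry measurement error
#' with error-variance ratio `delta = var(err_y)/var(err_x)`. The slope has
#' the closed form
#' `(s_yy - delta*s_xx + sqrt((s_yy - delta*s_xx)^2 + 4*delta*s_xy^2)) / (2*s_xy)`
#' and minimizes the weighted orthogonal residual sum
#' `sum (y - a - b*x)^2 / (delta + b^2)` (perpendicular distances when
#' `delta = 1`). The slope standard error is the leave-one-out jackknife; the
#' 95% CI is `slope +/- 1.96*se`. At `delta = 1`, fitting y on x and x on y
#' gives reciprocal slopes.
#'
#' @param points a [build_pairs()] result, or any data frame with `x`, `y`.
#' @param delta error-variance ratio (default 1).
#' @return A list of class `deming_fit`: `slope`, `intercept`, `delta`,
#'   `se_slope`, `ci95`, `n`, `labels`.
#' @export
deming_fit <- function(points, delta = 1) {
  x <- points$x; y <- points$y
  n <- length(x)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  xb <- mean(x); yb <- mean(y)
  dx <- x - xb; dy <- y - yb
  sxx <- sum(dx^2) / (n - 1)
  syy <- sum(dy^2) / (n - 1)
  sxy <- sum(dx * dy) / (n - 1)
  if (sxy == 0 && syy == delta * sxx) {
    stop("degenerate orientation: s_xy = 0 with s_yy = delta*s_xx", call. = FALSE)
  }
  if (sxy == 0) {
    ## limit of the closed form as s_xy -> 0: vertical or horizontal
    slope <- if (syy > delta * sxx) Inf else 0
    if (!is.finite(slope)) stop("degenerate fit: infinite slope", call. = FALSE)
  } else {
    slope <- deming_slope_closed_form(sxx, syy, sxy, delta)
  }
  intercept <- yb - slope * xb
  ## leave-one-out jackknife, via downdated first and second moments
  xb_i <- (n * xb - x) / (n - 1)
  yb_i <- (n * yb - y) / (n - 1)
  sxx_i <- (sum(dx^2) - (x - xb)^2 * n / (n - 1)) / (n - 2)
  syy_i <- (sum(dy^2) - (y - yb)^2 * n / (n - 1)) / (n - 2)
  sxy_i <- (sum(dx * dy) - (x - xb) * (y - yb) * n / (n - 1)) / (n - 2)
  slope_i <- deming_slope_closed_form(sxx_i, syy_i, sxy_i, delta)
  bad <- !is.finite(slope_i) | sxy_i == 0
  slope_i[bad] <- slope
  se <- sqrt((n - 1) / n * sum((slope_i - mean(slope_i))^2))
  structure(list(slope = slope, intercept = intercept, delta = delta,
                 se_slope = se, ci95 = c(slope - 1.96 * se, slope + 1.96 * se),
                 n = n, labels = attr(points, "labels")),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming fit (delta = %g): slope = %.4f (se %.4f, 95%% CI %.4f..%.4f), intercept = %.4f, n = %d\n",
              x$delta, x$slope, x$se_slope, x$ci95[1], x$ci95[2],
              x$intercept, x$n))
  invisible(x)
}

#' Compare two Deming slopes
#'
#' Normal-theory z test on the slope difference using the jackknife standard
#' errors: `z = (m1 - m2) / sqrt(se1^2 + se2^2)`; one-sided "greater" tests
#' whether fit1's slope exceeds fit2's.
#'
#' @param fit1,fit2 [deming_fit()] results.
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @return A list: `z`, `p`, `alternative`, `degenerate` (TRUE when both SEs
#'   are zero; then `p` is 0.5/1 for equal slopes and 0 otherwise, by
#'   direction).
#' @export
slope_difference_test <- function(fit1, fit2,
                                  alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  d <- fit1$slope - fit2$slope
  se <- sqrt(fit1$se_slope^2 + fit2$se_slope^2)
  if (se == 0) {
    if (d == 0) {
      z <- 0
      p <- if (alternative == "greater") 0.5 else 1
    } else {
      z <- sign(d) * Inf
      p <- if (alternative == "greater" && d < 0) 1 else 0
    }
    return(list(z = z, p = p, alternative = alternative, degenerate = TRUE))
  }
  z <- d / se
  p <- if (alternative == "greater") {
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  list(z = z, p = min(1, p), alternative = alternative, degenerate = FALSE)
}

#' Deming slope grid with reference comparisons
#'
#' Fits a Deming regression to each labeled set of paired fold changes and
#' tests every fit against one or more designated reference fits with the
#' one-sided "greater" alternative, mirroring slope heat maps annotated with
#' significance marks against reference comparisons. Raw and BH-adjusted
#' p-values are both reported.
#'
#' @param pairs_sets named list of [build_pairs()] results.
#' @param reference character vector of names in `pairs_sets` to test
#'   against (default: none, slopes only).
#' @param delta error-variance ratio passed to [deming_fit()].
#' @return A list of class `deming_grid`: `fits` (named list), `slopes`
#'   (named numeric), and `tests` (data.frame with `comparison`, `reference`,
#'   `z`, `p`, `q`) or `NULL` when no reference is given.
#' @export
concordance_grid <- function(pairs_sets, reference = character(), delta = 1) {
  if (!length(pairs_sets)) stop("need at least one pair set", call. = FALSE)
  fits <- lapply(pairs_sets, deming_fit, delta = delta)
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  tests <- NULL
  if (length(reference)) {
    miss <- setdiff(reference, names(fits))
    if (length(miss)) stop("unknown reference: ", miss[1], call. = FALSE)
    rows <- list()
    for (ref in reference) {
      for (cmp in setdiff(names(fits), ref)) {
        t <- slope_difference_test(fits[[cmp]], fits[[ref]], "greater")
        rows[[length(rows) + 1]] <- data.frame(
          comparison = cmp, reference = ref, z = t$z, p = t$p,
          stringsAsFactors = FALSE)
      }
    }
    tests <- do.call(rbind, rows)
    tests$q <- bh_adjust(tests$p)
  }
  structure(list(fits = fits, slopes = slopes, tests = tests, delta = delta),
            class = "deming_grid")
}
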