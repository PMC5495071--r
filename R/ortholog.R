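#' One-to-one ortholog filter
#'
#' Removes every pair whose `gene_a` or `gene_b` participates in more than
#' one pair, leaving a bijection on the surviving genes. The filter is
#' idempotent.
#'
#' @param map an [ortholog_map()] (or data frame with `gene_a`, `gene_b`).
#' @return The filtered [ortholog_map()] with attribute `one_to_one = TRUE`.
#' @export
one_to_one_filter <- function(map) {
  dup_a <- map$gene_a %in% map$gene_a[duplicated(map$gene_a)]
  dup_b <- map$gene_b %in% map$gene_b[duplicated(map$gene_b)]
  keep <- !(dup_a | dup_b)
  sp <- attr(map, "species")
  if (is.null(sp)) sp <- c("a", "b")
  out <- ortholog_map(map$gene_a[keep], map$gene_b[keep], sp[1], sp[2],
                      one_to_one = TRUE)
  rownames(out) <- NULL
  out
}

#' Chain two one-to-one ortholog maps through a shared middle species
#'
#' Builds triples `(a, b, c)` where `(a, b)` is in `ab` and `(b, c)` in `bc`;
#' genes lacking either link are dropped. Both maps must already be
#' one-to-one filtered, so the result is one-to-one-to-one.
#'
#' @param ab,bc one-to-one [ortholog_map()]s; `ab`'s second species is the
#'   middle species and must equal `bc`'s first species (when both are
#'   labeled).
#' @return A data.frame of class `ortholog_chain` with columns `gene_a`,
#'   `gene_b`, `gene_c` and a `species` attribute of length 3.
#' @export
chain_orthologs <- function(ab, bc) {
  if (!isTRUE(attr(ab, "one_to_one")) || !isTRUE(attr(bc, "one_to_one"))) {
    stop("both maps must be one-to-one filtered before chaining", call. = FALSE)
  }
  sp_ab <- attr(ab, "species"); sp_bc <- attr(bc, "species")
  if (!is.null(sp_ab) && !is.null(sp_bc) &&
      !identical(sp_ab[2], sp_bc[1])) {
    stop(sprintf("middle species mismatch: '%s' vs '%s'", sp_ab[2], sp_bc[1]),
         call. = FALSE)
  }
  i <- match(ab$gene_b, bc$gene_a)
  keep <- !is.na(i)
  out <- data.frame(gene_a = ab$gene_a[keep], gene_b = ab$gene_b[keep],
                    gene_c = bc$gene_b[i[keep]], stringsAsFactors = FALSE)
  class(out) <- c("ortholog_chain", "data.frame")
  attr(out, "species") <- c(sp_ab[1], sp_ab[2], sp_bc[2])
  out
}

#' Upper-tail hypergeometric gene-set enrichment
#'
#' Tests whether a query gene list overlaps an annotated set more than
#' expected by chance within a fixed universe:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`, where
#' `k = |query  annotated|`, `K = |annotated|`, `n = |query|` (both
#' intersected with the universe first) and `N = |universe|`.
#'
#' @param query character vector of query genes.
#' @param annotated character vector of annotated genes; must be a subset of
#'   the universe.
#' @param universe character vector defining the background.
#' @return A list of class `enrichment_result`: `k`, `K`, `n`, `N`, `p`,
#'   `expected` (`n*K/N`), `fold` (`k/expected`, `NA` when expected is 0).
#' @export
hypergeometric_enrichment <- function(query, annotated, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  annotated <- unique(as.character(annotated))
  if (length(setdiff(annotated, universe))) {
    stop("annotated set must be a subset of the universe", call. = FALSE)
  }
  query <- intersect(unique(as.character(query)), universe)
  k <- length(intersect(query, annotated))
  K <- length(annotated); n <- length(query); N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  expected <- n * K / N
  structure(list(k = k, K = K, n = n, N = N, p = p, expected = expected,
                 fold = if (expected > 0) k / expected else NA_real_),
            class = "enrichment_result")
}

#' Enrichment of annotated genes across a grid of query lists
#'
#' Applies [hypergeometric_enrichment()] to every combination of query list
#' and annotated set, then BH-adjusts the p-values across the whole grid.
#'
#' @param queries named list of query gene vectors (e.g. disease lists split
#'   by direction).
#' @param annotated_sets named list of annotated gene vectors (e.g. genes
#'   with a binding association in GF and in CV).
#' @param universe background gene set shared by all tests.
#' @return A data.frame with one row per (query, annotated set) pair:
#'   `query`, `set`, `k`, `K`, `n`, `N`, `p`, `q`, `neg_log10_p`.
#' @export
enrichment_table <- function(queries, annotated_sets, universe) {
  rows <- list()
  for (qn in names(queries)) {
    for (an in names(annotated_sets)) {
      e <- hypergeometric_enrichment(queries[[qn]], annotated_sets[[an]], universe)
      rows[[length(rows) + 1]] <- data.frame(
        query = qn, set = an, k = e$k, K = e$K, n = e$n, N = e$N, p = e$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$neg_log10_p <- -log10(pmax(out$p, .Machine$double.xmin))
  out
}

#' Proportion of disease genes with a binding association, by direction
#'
#' Maps a disease gene list through a one-to-one ortholog map into the
#' species namespace of the associated genes, then reports, for each
#' direction (up/down), the fraction of mapped disease genes that carry an
#' association.
#'
#' @param disease a [disease_gene_set()]; its `gene` ids live in the map's
#'   `gene_a` namespace.
#' @param associated_genes character vector of genes with an association,
#'   in the map's `gene_b` namespace.
#' @param map a one-to-one [ortholog_map()] from the disease species to the
#'   associated-gene species.
#' @return A data.frame with one row per direction: `direction`, `n_mapped`,
#'   `n_associated`, `proportion`.
#' @export
association_proportions <- function(disease, associated_genes, map) {
  if (!isTRUE(attr(map, "one_to_one"))) {
    stop("ortholog map must be one-to-one filtered", call. = FALSE)
  }
  i <- match(disease$gene, map$gene_a)
  mapped <- !is.na(i)
  if (!any(mapped)) stop("no disease gene maps through the ortholog table", call. = FALSE)
  partner <- map$gene_b[i]
  out <- lapply(c("up", "down"), function(dir) {
    sel <- mapped & !is.na(disease$direction) & disease$direction == dir
    n <- sum(sel)
    k <- sum(partner[sel] %in% associated_genes)
    data.frame(direction = dir, n_mapped = n, n_associated = k,
               proportion = if (n > 0) k / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
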