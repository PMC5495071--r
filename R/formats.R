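#' @keywords internal
stop_parse <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

#' Construct a set of genomic regions
#'
#' Regions use 0-based half-open coordinates throughout the package: a region
#' covers bases `start, start+1, ..., end-1` and its length is `end - start`.
#' An optional `summit_offset` locates a peak summit relative to `start`.
#'
#' @param chrom character vector of chromosome names (compared exact-string,
#'   no "chr" aliasing).
#' @param start,end integer coordinates, `0 <= start < end`.
#' @param name optional region identifiers.
#' @param score optional numeric scores.
#' @param summit_offset optional integer offsets from `start`, each in
#'   `[0, end - start)`; `NA` where no summit is known.
#' @param condition optional condition label (e.g. `"GF"` or `"CV"`) attached
#'   as the `condition` attribute, making the object a peak set.
#' @return A `data.frame` of class `genomic_regions` with columns
#'   `chrom`, `start`, `end`, `name`, `score`, `summit_offset`.
#' @export
genomic_regions <- function(chrom, start, end, name = NULL, score = NULL,
                            summit_offset = NULL, condition = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  n <- length(start)
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n) {
    stop("chrom, start and end must have equal length", call. = FALSE)
  }
  if (is.null(name)) name <- rep(NA_character_, n)
  if (is.null(score)) score <- rep(NA_real_, n)
  if (is.null(summit_offset)) summit_offset <- rep(NA_integer_, n)
  bad <- which(!(start >= 0L & start < end))
  if (length(bad)) {
    stop(sprintf("invalid region at index %d: start=%d end=%d (need 0 <= start < end)",
                 bad[1], start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  so <- as.integer(summit_offset)
  bad <- which(!is.na(so) & !(so >= 0L & so < end - start))
  if (length(bad)) {
    stop(sprintf("summit_offset out of range at index %d", bad[1]), call. = FALSE)
  }
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    name = as.character(name), score = as.numeric(score),
                    summit_offset = so, stringsAsFactors = FALSE)
  class(out) <- c("genomic_regions", "data.frame")
  attr(out, "condition") <- condition
  out
}

#' Read a BED file
#'
#' Coordinates are taken verbatim as 0-based half-open; there is no 1-based
#' dialect auto-detection. Fields beyond the third are optional: the 4th maps
#' to `name`, the 5th to `score`.
#'
#' @param path path to a tab-separated BED3/BED4/BED5/BED6 file.
#' @param condition optional condition label for the resulting peak set.
#' @return A [genomic_regions()] data frame, in file order. An empty file
#'   yields an empty set.
#' @export
read_bed <- function(path, condition = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(genomic_regions(character(), integer(), integer(), condition = condition))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_parse(path, idx[which(nf < 3L)[1]], "fewer than 3 tab-separated fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop_parse(path, idx[bad[1]], "non-integer coordinate")
  bad <- which(!(start >= 0L & start < end))
  if (length(bad)) {
    stop_parse(path, idx[bad[1]],
               sprintf("invalid interval [%d, %d)", start[bad[1]], end[bad[1]]))
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, ""), NA_character_)
  score <- rep(NA_real_, length(idx))
  has5 <- nf >= 5L
  if (any(has5)) {
    raw <- vapply(fields[has5], `[[`, "", 5L)
    val <- suppressWarnings(as.numeric(ifelse(raw == ".", NA, raw)))
    score[has5] <- val
  }
  genomic_regions(chrom, start, end, name = name, score = score,
                  condition = condition)
}

#' Write regions as BED
#'
#' @param regions a [genomic_regions()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  has_name <- any(!is.na(regions$name))
  has_score <- any(!is.na(regions$score))
  cols <- list(regions$chrom, regions$start, regions$end)
  if (has_name || has_score) cols <- c(cols, list(ifelse(is.na(regions$name), ".", regions$name)))
  if (has_score) cols <- c(cols, list(ifelse(is.na(regions$score), ".", format(regions$score, trim = TRUE, scientific = FALSE))))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' The annotation is a flat TSV with header columns `gene_id`, `chrom`,
#' `strand` and `tss` (0-based). TSS is treated as input data rather than
#' derived from a gene model.
#'
#' @param path path to the TSV.
#' @return A `data.frame` of class `gene_annotation` with those four columns.
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("%s: missing annotation column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  gene_annotation(tab$gene_id, tab$chrom, tab$strand, tab$tss)
}

#' Construct a gene annotation
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"` per gene.
#' @param tss 0-based transcription start site coordinates, `>= 0`.
#' @return A `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, strand, tss) {
  gene_id <- as.character(gene_id)
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) {
    stop(sprintf("duplicate gene_id: %s", dup[1]), call. = FALSE)
  }
  strand <- as.character(strand)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("invalid strand '%s' for gene %s (must be + or -)",
                 strand[bad[1]], gene_id[bad[1]]), call. = FALSE)
  }
  tss <- as.integer(tss)
  if (anyNA(tss) || any(tss < 0L)) stop("tss must be a non-negative integer", call. = FALSE)
  out <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                    strand = strand, tss = tss, stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Write a gene annotation table
#' @param annotation a [gene_annotation()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Import an annotation from GTF/GFF, deriving the TSS by strand
#'
#' Computes the 0-based TSS as the 5' end of each gene feature: `start - 1`
#' on `+` (GTF is 1-based inclusive) and `end - 1` on `-`.
#'
#' @param path path to a GTF/GFF file (gene features are rows with
#'   `type == "gene"`, or all rows if none are typed "gene").
#' @param id_attr attribute holding the gene identifier (default `gene_id`).
#' @return A [gene_annotation()].
#' @export
annotation_from_gtf <- function(path, id_attr = "gene_id") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("annotation_from_gtf requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  meta <- GenomicRanges::mcols(gr)
  if ("type" %in% names(meta) && any(meta$type == "gene")) {
    gr <- gr[meta$type == "gene"]
    meta <- GenomicRanges::mcols(gr)
  }
  ids <- meta[[id_attr]]
  if (is.null(ids)) stop(sprintf("GTF lacks attribute '%s'", id_attr), call. = FALSE)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("gene feature without strand", call. = FALSE)
  tss <- ifelse(strand == "+", GenomicRanges::start(gr) - 1L,
                GenomicRanges::end(gr) - 1L)
  gene_annotation(ids, as.character(GenomicRanges::seqnames(gr)), strand, tss)
}

#' Construct a signal track
#'
#' A piecewise-constant coverage track with bedGraph semantics: sorted,
#' non-overlapping 0-based half-open intervals per chromosome with a
#' non-negative value each, plus the library size used for normalization.
#'
#' @param chrom,start,end interval coordinates.
#' @param value per-base coverage values, `>= 0`.
#' @param library_size total read count for RPKM-style normalization, `> 0`.
#' @return A list of class `signal_track` with elements `intervals`
#'   (data.frame) and `library_size`.
#' @export
signal_track <- function(chrom, start, end, value, library_size) {
  if (!is.numeric(library_size) || length(library_size) != 1 ||
      is.na(library_size) || library_size <= 0) {
    stop("library_size must be a single positive number", call. = FALSE)
  }
  start <- as.numeric(start); end <- as.numeric(end)
  value <- as.numeric(value)
  if (any(start < 0) || any(start >= end)) stop("invalid track interval", call. = FALSE)
  if (any(value < 0)) stop("negative coverage value", call. = FALSE)
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   value = value, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  by_chr <- split(seq_len(nrow(df)), df$chrom)
  for (ix in by_chr) {
    if (length(ix) > 1 && any(df$start[ix][-1] < df$end[ix][-length(ix)])) {
      stop("overlapping track intervals on chromosome ",
           df$chrom[ix[1]], call. = FALSE)
    }
  }
  structure(list(intervals = df, library_size = library_size),
            class = "signal_track")
}

#' Read a bedGraph coverage track
#'
#' @param path path to a 4-column bedGraph file.
#' @param library_size total read count for normalization, `> 0`.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, library_size) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) {
    return(signal_track(character(), numeric(), numeric(), numeric(), library_size))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) stop_parse(path, idx[which(nf < 4L)[1]], "fewer than 4 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad)) stop_parse(path, idx[bad[1]], "malformed bedGraph line")
  bad <- which(value < 0)
  if (length(bad)) stop_parse(path, idx[bad[1]], "negative coverage value")
  bad <- which(start < 0 | start >= end)
  if (length(bad)) stop_parse(path, idx[bad[1]], "invalid interval")
  signal_track(chrom, start, end, value, library_size)
}

#' Write a signal track as bedGraph
#' @param track a [signal_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  iv <- track$intervals
  writeLines(paste(iv$chrom, format(iv$start, trim = TRUE, scientific = FALSE),
                   format(iv$end, trim = TRUE, scientific = FALSE),
                   format(iv$value, trim = TRUE, scientific = FALSE),
                   sep = "\t"), path)
  invisible(path)
}

#' Construct a count matrix with 2x2 design metadata
#'
#' @param counts genes x samples matrix of non-negative integer counts with
#'   gene ids as rownames and sample names as colnames.
#' @param design data frame with columns `sample`, `genotype` (`"WT"`/`"Mut"`),
#'   `colonization` (`"GF"`/`"CV"`) and `replicate`; one row per sample.
#' @return A list of class `count_matrix` with elements `counts` and `design`.
#' @export
count_matrix <- function(counts, design) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  need <- c("sample", "genotype", "colonization", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!setequal(colnames(counts), design$sample) ||
      ncol(counts) != nrow(design)) {
    stop("design samples do not match count matrix columns", call. = FALSE)
  }
  if (!all(design$genotype %in% c("WT", "Mut"))) stop("genotype must be WT or Mut", call. = FALSE)
  if (!all(design$colonization %in% c("GF", "CV"))) stop("colonization must be GF or CV", call. = FALSE)
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, design = design), class = "count_matrix")
}

#' Read a gene-by-sample count table
#'
#' @param path TSV whose first column holds gene ids and remaining columns
#'   hold integer counts for samples named in `design`.
#' @param design sample design data frame (see [count_matrix()]); every sample
#'   named in `design` must be a column of the file and vice versa.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, design) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  gene_ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  extra <- setdiff(colnames(mat), design$sample)
  miss <- setdiff(design$sample, colnames(mat))
  if (length(extra)) stop(sprintf("%s: sample '%s' absent from design", path, extra[1]), call. = FALSE)
  if (length(miss)) stop(sprintf("%s: design sample '%s' absent from file", path, miss[1]), call. = FALSE)
  if (any(is.na(mat)) || any(mat != round(mat))) {
    stop(sprintf("%s: non-integer count value", path), call. = FALSE)
  }
  rownames(mat) <- gene_ids
  count_matrix(mat, design)
}

#' Write a count matrix as TSV
#' @param cm a [count_matrix()].
#' @param path output TSV path (first column `gene_id`).
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairwise ortholog table
#'
#' @param path TSV with header columns `gene_a` and `gene_b`.
#' @param species_a,species_b species labels attached as attributes.
#' @return A `data.frame` of class `ortholog_map` with attribute
#'   `one_to_one = FALSE` (apply [one_to_one_filter()] before chaining).
#' @export
read_ortholog_table <- function(path, species_a = "a", species_b = "b") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("gene_a", "gene_b"), names(tab))
  if (length(miss)) stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")), call. = FALSE)
  ortholog_map(tab$gene_a, tab$gene_b, species_a, species_b)
}

#' Construct a pairwise ortholog map
#' @param gene_a,gene_b paired gene identifiers.
#' @param species_a,species_b species labels.
#' @param one_to_one has the one-to-one filter been applied?
#' @return A `data.frame` of class `ortholog_map`.
#' @export
ortholog_map <- function(gene_a, gene_b, species_a = "a", species_b = "b",
                         one_to_one = FALSE) {
  out <- data.frame(gene_a = as.character(gene_a),
                    gene_b = as.character(gene_b), stringsAsFactors = FALSE)
  class(out) <- c("ortholog_map", "data.frame")
  attr(out, "species") <- c(species_a, species_b)
  attr(out, "one_to_one") <- one_to_one
  out
}

#' Write an ortholog map as TSV
#' @param map an [ortholog_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("gene_a", "gene_b")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a disease differential-gene list
#'
#' @param path TSV with header columns `gene`, `direction` (`up`/`down`) and
#'   `log2fc`; `direction` may be `NA` for genes below the list's own
#'   significance cut.
#' @param disease_label label attached as attribute (e.g. `"iCD-1"`).
#' @return A `data.frame` of class `disease_gene_set`.
#' @export
read_disease_list <- function(path, disease_label = "disease") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  miss <- setdiff(c("gene", "direction", "log2fc"), names(tab))
  if (length(miss)) stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")), call. = FALSE)
  disease_gene_set(tab$gene, tab$direction, tab$log2fc, disease_label)
}

#' Construct a disease differential-gene set
#' @param gene gene identifiers (in the disease list's own species namespace).
#' @param direction `"up"`, `"down"` or `NA` per gene; when both direction and
#'   log2fc are present they must agree in sign.
#' @param log2fc log2 fold changes (disease vs healthy).
#' @param disease_label set label.
#' @return A `data.frame` of class `disease_gene_set`.
#' @export
disease_gene_set <- function(gene, direction, log2fc, disease_label = "disease") {
  direction <- as.character(direction)
  log2fc <- as.numeric(log2fc)
  ok <- is.na(direction) | direction %in% c("up", "down")
  if (!all(ok)) stop("direction must be 'up', 'down' or NA", call. = FALSE)
  bad <- !is.na(direction) & !is.na(log2fc) &
    ((direction == "up" & log2fc <= 0) | (direction == "down" & log2fc >= 0))
  if (any(bad)) {
    stop(sprintf("direction inconsistent with log2fc sign for gene %s",
                 gene[which(bad)[1]]), call. = FALSE)
  }
  out <- data.frame(gene = as.character(gene), direction = direction,
                    log2fc = log2fc, stringsAsFactors = FALSE)
  class(out) <- c("disease_gene_set", "data.frame")
  attr(out, "disease_label") <- disease_label
  out
}

#' Write a disease gene list as TSV
#' @param ds a [disease_gene_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disease_list <- function(ds, path) {
  utils::write.table(as.data.frame(ds)[, c("gene", "direction", "log2fc")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
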