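## Reference point of a region: summit if recorded, else midpoint (floor).
region_reference_point <- function(regions) {
  mid <- regions$start + (regions$end - regions$start) %/% 2L
  ifelse(is.na(regions$summit_offset), mid,
         regions$start + regions$summit_offset)
}

#' Assign peaks to their single nearest TSS within a distance cut
#'
#' Each peak is represented by one reference point (its summit when recorded,
#' otherwise the floored midpoint) and assigned to the gene with the minimal
#' `|reference - TSS|` on the same chromosome, provided that distance does not
#' exceed `max_distance`. Exact distance ties are broken toward the
#' lexicographically smaller `gene_id`. Peaks on chromosomes absent from the
#' annotation are unassigned.
#'
#' @param peaks a [genomic_regions()] peak set.
#' @param annotation a [gene_annotation()].
#' @param max_distance maximum assignment distance in bp (default 10000).
#' @return A data.frame of class `peak_gene_assignment` with one row per peak:
#'   `peak_name`, `chrom`, `reference`, `gene_id` (`NA` if unassigned) and
#'   `distance` (`NA` if unassigned).
#' @export
assign_peaks_to_genes <- function(peaks, annotation, max_distance = 10000) {
  if (nrow(annotation) == 0) stop("empty annotation", call. = FALSE)
  if (max_distance <= 0) stop("max_distance must be positive", call. = FALSE)
  ref <- region_reference_point(peaks)
  n <- nrow(peaks)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  for (chr in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == chr)
    ann <- annotation[annotation$chrom == chr, , drop = FALSE]
    if (nrow(ann) == 0) next
    ## collapse genes sharing a TSS to the lexicographically smallest id,
    ## then compare the nearest TSS on each side of the reference point
    ord <- order(ann$tss, ann$gene_id)
    ann <- ann[ord, , drop = FALSE]
    first <- !duplicated(ann$tss)
    tss <- ann$tss[first]
    gid <- ann$gene_id[first]
    x <- ref[pk]
    i <- findInterval(x, tss)          # index of nearest TSS <= x (0 if none)
    left_d <- ifelse(i >= 1, x - tss[pmax(i, 1)], Inf)
    right_ok <- i < length(tss)
    right_d <- ifelse(right_ok, tss[pmin(i + 1, length(tss))] - x, Inf)
    left_g <- ifelse(i >= 1, gid[pmax(i, 1)], NA_character_)
    right_g <- ifelse(right_ok, gid[pmin(i + 1, length(tss))], NA_character_)
    take_left <- left_d < right_d |
      (left_d == right_d & !is.na(left_g) & !is.na(right_g) & left_g <= right_g)
    d <- ifelse(take_left, left_d, right_d)
    g <- ifelse(take_left, left_g, right_g)
    ok <- is.finite(d) & d <= max_distance
    gene[pk[ok]] <- g[ok]
    dist[pk[ok]] <- d[ok]
  }
  name <- peaks$name
  if (all(is.na(name))) name <- sprintf("peak_%d", seq_len(n))
  out <- data.frame(peak_name = name, chrom = peaks$chrom, reference = ref,
                    gene_id = gene, distance = dist, stringsAsFactors = FALSE)
  class(out) <- c("peak_gene_assignment", "data.frame")
  attr(out, "max_distance") <- max_distance
  out
}

#' Write a peak-to-gene assignment as TSV
#' @param assignment a `peak_gene_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end))
}

#' Compare two peak sets by overlap
#'
#' A region of set A is "shared" iff it overlaps at least `min_overlap` bp
#' (half-open overlap) with at least one region of set B, and symmetrically.
#' The shared/unique counts partition each set.
#'
#' @param a,b [genomic_regions()] peak sets.
#' @param min_overlap minimum overlap in bp (>= 1).
#' @return A list with counts `shared_a`, `unique_a`, `shared_b`, `unique_b`
#'   and logical membership vectors `a_shared`, `b_shared`.
#' @export
compare_peak_sets <- function(a, b, min_overlap = 1) {
  if (min_overlap < 1) stop("min_overlap must be >= 1", call. = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) {
    a_shared <- rep(FALSE, nrow(a))
    b_shared <- rep(FALSE, nrow(b))
  } else {
    gra <- regions_to_granges(a)
    grb <- regions_to_granges(b)
    a_shared <- IRanges::overlapsAny(gra, grb, minoverlap = min_overlap)
    b_shared <- IRanges::overlapsAny(grb, gra, minoverlap = min_overlap)
  }
  list(shared_a = sum(a_shared), unique_a = sum(!a_shared),
       shared_b = sum(b_shared), unique_b = sum(!b_shared),
       a_shared = a_shared, b_shared = b_shared)
}

## Cumulative coverage integral of a piecewise-constant track on one
## chromosome: C(x) = integral_0^x value. Returns a function of position.
track_cumulative <- function(track, chrom) {
  iv <- track$intervals[track$intervals$chrom == chrom, , drop = FALSE]
  if (nrow(iv) == 0) {
    return(function(x) rep(0, length(x)))
  }
  bp <- c(iv$start, iv$end[nrow(iv)])
  cum <- c(0, cumsum(iv$value * (iv$end - iv$start)))
  function(x) {
    x <- pmax(x, 0)
    i <- findInterval(x, iv$start)
    out <- numeric(length(x))
    pos <- i >= 1
    ii <- i[pos]
    out[pos] <- cum[ii] +
      iv$value[ii] * pmax(0, pmin(x[pos], iv$end[ii]) - iv$start[ii])
    out
  }
}

#' Binned, normalized signal around peak summits
#'
#' For each site, signal is summed per bin over `2*flank/bin_width` bins
#' spanning `[-flank, +flank)` around the site's reference point (summit else
#' midpoint), then normalized RPKM-style:
#' `value = bin_sum / ((bin_width/1000) * (library_size/1e6))`.
#' Track values are treated as per-base read depth; any read-length factor is
#' absorbed into the recorded `normalization_constant`
#' (`(bin_width/1000) * (library_size/1e6)`), so profiles computed with the
#' same parameters are comparable across conditions. Bins truncated at the
#' chromosome start (negative coordinates) are zero-filled and flagged.
#'
#' @param sites a [genomic_regions()] peak set.
#' @param track a [signal_track()].
#' @param flank half-window in bp (default 1000).
#' @param bin_width bin size in bp; must divide `2*flank`.
#' @return A list of class `profile_matrix`: `values` (sites x bins),
#'   `truncated` (logical, same shape), `bin_centers` (bp relative to the
#'   summit), `flank`, `bin_width`, `normalization_constant`.
#' @export
flanking_signal_matrix <- function(sites, track, flank = 1000, bin_width = 50) {
  if (flank <= 0) stop("flank must be positive", call. = FALSE)
  if ((2 * flank) %% bin_width != 0) {
    stop("bin_width must divide 2*flank", call. = FALSE)
  }
  nbins <- as.integer(2 * flank / bin_width)
  ref <- region_reference_point(sites)
  offsets <- seq(-flank, flank - bin_width, by = bin_width)
  norm_const <- (bin_width / 1000) * (track$library_size / 1e6)
  values <- matrix(0, nrow(sites), nbins)
  truncated <- matrix(FALSE, nrow(sites), nbins)
  for (chr in unique(sites$chrom)) {
    ix <- which(sites$chrom == chr)
    cumf <- track_cumulative(track, chr)
    starts <- outer(ref[ix], offsets, "+")        # sites x bins
    ends <- starts + bin_width
    sums <- cumf(as.numeric(ends)) - cumf(as.numeric(starts))
    sums <- matrix(sums, length(ix), nbins)
    trunc <- starts < 0
    sums[trunc] <- 0
    values[ix, ] <- sums / norm_const
    truncated[ix, ] <- trunc
  }
  site_ids <- sites$name
  if (all(is.na(site_ids))) site_ids <- sprintf("site_%d", seq_len(nrow(sites)))
  rownames(values) <- site_ids
  structure(list(values = values, truncated = truncated,
                 bin_centers = offsets + bin_width / 2,
                 flank = flank, bin_width = bin_width,
                 normalization_constant = norm_const),
            class = "profile_matrix")
}

#' Average signal profile across sites
#'
#' Arithmetic mean per bin over sites; entries from bins truncated at the
#' chromosome start are excluded from their bin's mean.
#'
#' @param pm a [flanking_signal_matrix()] result.
#' @return A data.frame with `bin_center`, `mean` and `n_sites` (number of
#'   contributing sites per bin).
#' @export
mean_profile <- function(pm) {
  if (!nrow(pm$values)) stop("empty profile matrix", call. = FALSE)
  v <- pm$values
  v[pm$truncated] <- NA
  n <- colSums(!pm$truncated)
  data.frame(bin_center = pm$bin_centers,
             mean = colMeans(v, na.rm = TRUE),
             n_sites = n)
}

#' Write a profile matrix as TSV with bin headers
#' @param pm a `profile_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(pm, path) {
  tab <- data.frame(site_id = rownames(pm$values), pm$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab)[-1] <- sprintf("bin_%+d", as.integer(pm$bin_centers - pm$bin_width / 2))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
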