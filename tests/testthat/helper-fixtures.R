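# Shared in-code fixtures and independent oracles for the test suite.

tiny_annotation <- function() {
  gene_annotation(c("g1", "g2", "g3"),
                  c("chr1", "chr1", "chr2"),
                  c("+", "-", "+"),
                  c(4000L, 20000L, 1000L))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal expression_comparison for tests that only need fc/q columns.
fake_comparison <- function(gene_id, log2fc, q, label = "A/B",
                            q_threshold = 0.05) {
  out <- data.frame(gene_id = gene_id, base_mean = 100, log2fc = log2fc,
                    p = q, q = q, significant = q < q_threshold,
                    tested = TRUE, stringsAsFactors = FALSE)
  class(out) <- c("expression_comparison", "data.frame")
  attr(out, "contrast_label") <- label
  attr(out, "q_threshold") <- q_threshold
  out
}

# Brute-force oracle: two-sample KS statistic by evaluating both ECDFs at
# every pooled point with a double loop.
ks_oracle_D <- function(x, y) {
  pts <- c(x, y)
  best <- 0
  for (t in pts) {
    fx <- sum(x <= t) / length(x)
    fy <- sum(y <= t) / length(y)
    best <- max(best, abs(fx - fy))
  }
  best
}

# Brute-force oracle: nearest-TSS assignment by exhaustive all-pairs search.
assign_oracle <- function(peaks, annotation, max_distance = 10000) {
  ref <- ifelse(is.na(peaks$summit_offset),
                peaks$start + (peaks$end - peaks$start) %/% 2L,
                peaks$start + peaks$summit_offset)
  n <- nrow(peaks)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cand <- annotation[annotation$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(cand)) next
    d <- abs(ref[i] - cand$tss)
    best <- min(d)
    if (best > max_distance) next
    ids <- sort(cand$gene_id[d == best])
    gene[i] <- ids[1]
    dist[i] <- best
  }
  list(gene_id = gene, distance = dist)
}

# Brute-force oracle: upper-tail hypergeometric p by exhaustive enumeration
# of all overlap outcomes via binomial coefficients.
hyper_oracle <- function(k, K, n, N) {
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  total <- choose(N, n)
  sum(vapply(max(k, lo):hi, function(j) choose(K, j) * choose(N - K, n - j),
             numeric(1))) / total
}

# Numerical oracle: Deming slope by 1-D minimization of the weighted
# orthogonal objective sum (y - a - b x)^2 / (delta + b^2), profiling out a.
deming_oracle_slope <- function(x, y, delta = 1) {
  obj <- function(b) {
    a <- mean(y) - b * mean(x)
    sum((y - a - b * x)^2) / (delta + b^2)
  }
  stats::optimize(obj, interval = c(-1e3, 1e3), tol = 1e-10)$minimum
}

# Hand-written BH step-up oracle (independent of stats::p.adjust).
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, p[ord] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
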