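test_that("nearest-TSS assignment follows the 10 kb single-nearest rule", {
  ann <- tiny_annotation()  # g1@chr1:4000, g2@chr1:20000, g3@chr2:1000
  pk <- genomic_regions(c("chr1", "chr1", "chr3"),
                        c(4900, 49900, 100),
                        c(5100, 50100, 300),
                        name = c("p1", "p2", "p3"),
                        summit_offset = c(100L, 100L, NA))
  a <- assign_peaks_to_genes(pk, ann, 10000)
  expect_equal(a$gene_id, c("g1", NA, NA))   # p2: nearest TSS 30000 bp away
  expect_equal(a$distance, c(1000, NA, NA))  # p3: chromosome not annotated
})

test_that("exact distance ties break to the lexicographically smaller gene", {
  ann <- gene_annotation(c("gB", "gA"), c("chr1", "chr1"), c("+", "+"),
                         c(6000L, 4000L))
  pk <- genomic_regions("chr1", 4900, 5100, name = "p",
                        summit_offset = 100L)   # summit 5000, both at 1000 bp
  a <- assign_peaks_to_genes(pk, ann)
  expect_equal(a$gene_id, "gA")
  expect_equal(a$distance, 1000)
})

test_that("midpoint is the reference when no summit is recorded", {
  ann <- gene_annotation("g1", "chr1", "+", 500L)
  pk <- genomic_regions("chr1", 400, 501, name = "p")  # midpoint floor = 450
  a <- assign_peaks_to_genes(pk, ann)
  expect_equal(a$reference, 450L)
  expect_equal(a$distance, 50)
})

test_that("assignment agrees with the all-pairs brute force on random layouts", {
  set.seed(301)
  for (rep in 1:200) {
    n_genes <- sample(2:20, 1)
    n_peaks <- sample(1:15, 1)
    chroms <- c("chr1", "chr2")
    ann <- gene_annotation(paste0("g", sample(100, n_genes)),
                           sample(chroms, n_genes, TRUE),
                           sample(c("+", "-"), n_genes, TRUE),
                           sample(0:60000, n_genes))
    start <- sample(0:60000, n_peaks)
    width <- sample(50:400, n_peaks, TRUE)
    pk <- genomic_regions(sample(chroms, n_peaks, TRUE), start, start + width,
                          name = paste0("p", seq_len(n_peaks)),
                          summit_offset = ifelse(runif(n_peaks) < 0.5,
                                                 sample(0:49, n_peaks, TRUE),
                                                 NA))
    got <- assign_peaks_to_genes(pk, ann, 10000)
    want <- assign_oracle(pk, ann, 10000)
    expect_identical(got$gene_id, want$gene_id)
    expect_identical(got$distance, want$distance)
  }
})

test_that("peak-set comparison partitions each set and is symmetric on identity", {
  a <- genomic_regions("chr1", c(100, 300), c(200, 400), name = c("a1", "a2"))
  b <- genomic_regions("chr1", 150, 250, name = "b1")
  cmp <- compare_peak_sets(a, b)
  expect_equal(cmp$shared_a, 1); expect_equal(cmp$unique_a, 1)
  expect_equal(cmp$shared_b, 1); expect_equal(cmp$unique_b, 0)
  expect_equal(cmp$shared_a + cmp$unique_a, nrow(a))

  far <- genomic_regions("chr1", 1000, 1100, name = "f")
  cmp2 <- compare_peak_sets(a, far)
  expect_equal(cmp2$shared_a, 0); expect_equal(cmp2$unique_a, 2)
  expect_equal(cmp2$unique_b, 1)

  self <- compare_peak_sets(a, a)
  expect_equal(self$shared_a, nrow(a))
  expect_equal(self$unique_b, 0)
  expect_error(compare_peak_sets(a, b, min_overlap = 0), "min_overlap")
})

test_that("half-open overlap semantics: adjacent regions do not overlap", {
  a <- genomic_regions("chr1", 100, 200)
  b <- genomic_regions("chr1", 200, 300)   # touches at 200, zero overlap
  cmp <- compare_peak_sets(a, b)
  expect_equal(cmp$shared_a, 0)
  c30 <- compare_peak_sets(genomic_regions("chr1", 100, 200),
                           genomic_regions("chr1", 180, 300),
                           min_overlap = 21)  # only 20 bp overlap
  expect_equal(c30$shared_a, 0)
})

test_that("shared counts agree with a brute-force pair count in both directions", {
  set.seed(302)
  for (rep in 1:50) {
    na <- sample(1:12, 1); nb <- sample(1:12, 1)
    sa <- sample(0:2000, na); sb <- sample(0:2000, nb)
    a <- genomic_regions("chr1", sa, sa + sample(20:200, na, TRUE))
    b <- genomic_regions("chr1", sb, sb + sample(20:200, nb, TRUE))
    ov <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))
    mat <- outer(seq_len(na), seq_len(nb), function(i, j)
      ov(a$start[i], a$end[i], b$start[j], b$end[j]) >= 1)
    cmp <- compare_peak_sets(a, b)
    expect_equal(cmp$shared_a, sum(rowSums(mat) > 0))
    expect_equal(cmp$shared_b, sum(colSums(mat) > 0))
  }
})

test_that("profile matrices obey the RPKM scaling contract", {
  tr <- signal_track("chr1", 0, 1e5, 2.0, library_size = 1e6)
  sites <- genomic_regions("chr1", c(4900, 9900), c(5100, 10100),
                           name = c("s1", "s2"),
                           summit_offset = c(100L, 100L))
  pm <- flanking_signal_matrix(sites, tr, flank = 1000, bin_width = 50)
  expect_equal(dim(pm$values), c(2, 40))
  # uniform coverage 2/bp: bin sum = 100; / (0.05 kb * 1 M reads) = 2000
  expect_true(all(abs(pm$values - 2000) < 1e-9))

  tr2 <- signal_track("chr1", 0, 1e5, 2.0, library_size = 2e6)
  pm2 <- flanking_signal_matrix(sites, tr2, flank = 1000, bin_width = 50)
  expect_equal(pm2$values, pm$values / 2)

  tr0 <- signal_track("chr1", 0, 1e5, 0, library_size = 1e6)
  pm0 <- flanking_signal_matrix(sites, tr0, flank = 1000, bin_width = 50)
  expect_true(all(pm0$values == 0))
  expect_error(flanking_signal_matrix(sites, tr, flank = 0), "flank")
  expect_error(flanking_signal_matrix(sites, tr, flank = 1000, bin_width = 300),
               "divide")
})

test_that("profiles are equivariant under a joint coordinate shift", {
  set.seed(303)
  vals <- runif(20, 0, 5)
  bounds <- seq(0, 20000, by = 1000)
  tr <- signal_track(rep("chr1", 20), bounds[-21], bounds[-1], vals, 1e6)
  site <- genomic_regions("chr1", 9000, 9200, name = "s",
                          summit_offset = 100L)
  pm <- flanking_signal_matrix(site, tr, 1000, 50)

  shift <- 3000
  tr_s <- signal_track(rep("chr1", 20), bounds[-21] + shift,
                       bounds[-1] + shift, vals, 1e6)
  site_s <- genomic_regions("chr1", 9000 + shift, 9200 + shift, name = "s",
                            summit_offset = 100L)
  pm_s <- flanking_signal_matrix(site_s, tr_s, 1000, 50)
  expect_equal(pm_s$values, pm$values, tolerance = 1e-9)
})

test_that("mean profiles average rows and exclude truncated bins", {
  tr <- signal_track("chr1", 0, 1e5, 1.0, library_size = 1e6)
  one <- genomic_regions("chr1", 4900, 5100, name = "s1",
                         summit_offset = 100L)
  pm1 <- flanking_signal_matrix(one, tr, 1000, 50)
  mp1 <- mean_profile(pm1)
  expect_equal(mp1$mean, as.numeric(pm1$values[1, ]))
  expect_equal(mp1$n_sites, rep(1L, 40))

  # site whose left flank crosses the chromosome start: bins flagged,
  # excluded from the mean but zero-filled in the matrix
  edge <- genomic_regions("chr1", c(100, 9900), c(300, 10100),
                          name = c("edge", "mid"),
                          summit_offset = c(100L, 100L))
  pme <- flanking_signal_matrix(edge, tr, 1000, 50)
  expect_true(any(pme$truncated[1, ]))
  expect_true(all(pme$values[1, pme$truncated[1, ]] == 0))
  mpe <- mean_profile(pme)
  left_bins <- which(pme$truncated[1, ])
  expect_equal(mpe$n_sites[left_bins], rep(1L, length(left_bins)))
  expect_equal(mpe$mean, rep(1000, 40))  # untruncated entries all equal
  expect_error(mean_profile(flanking_signal_matrix(
    genomic_regions(character(), integer(), integer()), tr, 1000, 50)),
    "empty")
})
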