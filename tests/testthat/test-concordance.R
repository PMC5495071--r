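four_fake <- function(qmat, genes = paste0("g", seq_len(nrow(qmat))),
                      fc = 1) {
  labs <- c("WTCV/WTGF", "MutCV/MutGF", "WTCV/MutCV", "WTGF/MutGF")
  out <- lapply(seq_along(labs), function(j) {
    fake_comparison(genes, rep_len(fc, length(genes)), qmat[, j], labs[j])
  })
  names(out) <- labs
  out
}

test_that("four-way membership counts genes once and partitions the union", {
  q <- matrix(1, 3, 4)
  q[1, 1] <- 0.001                     # gene 1 significant only in contrast 1
  q[2, c(1, 3)] <- 0.001               # gene 2 in contrasts 1 and 3
  fw <- classify_four_way(four_fake(q), 0.05)
  expect_equal(fw$union_size, 2)
  expect_equal(unname(fw$venn[["WTCV/WTGF"]]), 1)
  expect_equal(unname(fw$venn[["WTCV/WTGF+WTCV/MutCV"]]), 1)
  expect_equal(sum(fw$venn), fw$union_size)
  expect_equal(unname(fw$pairwise["WTCV/WTGF", "WTCV/MutCV"]), 1)

  fw0 <- classify_four_way(four_fake(matrix(1, 5, 4)), 0.05)
  expect_equal(fw0$union_size, 0)
  expect_equal(sum(fw0$venn), 0)
})

test_that("four-way Venn regions satisfy inclusion-exclusion on random flag sets", {
  set.seed(401)
  for (rep in 1:20) {
    n <- 60
    q <- matrix(ifelse(runif(4 * n) < 0.3, 0.001, 0.5), n, 4)
    fw <- classify_four_way(four_fake(q), 0.05)
    expect_equal(sum(fw$venn), fw$union_size)
    # pairwise intersections from disjoint venn regions must match flags
    labs <- colnames(fw$flags)
    for (i in 1:3) for (j in (i + 1):4) {
      from_venn <- sum(fw$venn[vapply(names(fw$venn), function(k) {
        parts <- strsplit(k, "+", fixed = TRUE)[[1]]
        all(labs[c(i, j)] %in% parts)
      }, logical(1))])
      expect_equal(from_venn, sum(fw$flags[, i] & fw$flags[, j]))
    }
  }
  bad <- four_fake(matrix(1, 3, 4))
  bad[[2]]$gene_id <- c("x", "y", "z")
  expect_error(classify_four_way(bad), "universe")
})

test_that("quadrant classification maps sign pairs to the four classes", {
  expect_equal(quadrant_classify(2, 0.01, 1.5, 0.001), "suppressed_activated")
  expect_equal(quadrant_classify(-2, 0.01, 1, 0.01), "induced_activated")
  expect_equal(quadrant_classify(2, 0.01, -1, 0.01), "suppressed_repressed")
  expect_equal(quadrant_classify(-2, 0.01, -1, 0.01), "induced_repressed")
  expect_equal(quadrant_classify(2, 0.5, 1.5, 0.001), "not_coregulated")
  expect_equal(quadrant_classify(2, 0.01, 1.5, NA), "not_coregulated")
  expect_error(quadrant_classify(0, 0.01, 1, 0.01), "contradictory")
})

test_that("quadrant labels partition the shared-significant set", {
  set.seed(402)
  n <- 500
  fc_x <- rnorm(n); fc_y <- rnorm(n)
  q_x <- runif(n); q_y <- runif(n)
  labels <- quadrant_classify(fc_x, q_x, fc_y, q_y, 0.2)
  shared <- q_x < 0.2 & q_y < 0.2
  expect_equal(sum(labels != "not_coregulated"), sum(shared))
  expect_true(all(labels[!shared] == "not_coregulated"))
  cs <- coregulation_summary(labels)
  expect_equal(cs$n_shared, sum(shared))
})

test_that("coregulation summary reproduces the 88-of-98 arithmetic", {
  labels <- c(rep("suppressed_activated", 88), rep("suppressed_repressed", 10),
              rep("induced_repressed", 197), rep("not_coregulated", 5))
  cs <- coregulation_summary(labels)
  expect_equal(cs$n_shared, 295)
  expect_equal(cs$counts[["suppressed_activated"]], 88L)
  expect_equal(cs$suppressed_activated_fraction, 88 / 98, tolerance = 1e-12)

  none <- coregulation_summary(rep("not_coregulated", 10))
  expect_equal(none$n_shared, 0)
  expect_true(is.na(none$suppressed_activated_fraction))
})

test_that("KS statistic matches hand-worked and degenerate cases", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  disjoint <- ks_two_sample(c(1, 2), c(3, 4))
  expect_equal(disjoint$D, 1)

  inter <- ks_two_sample(c(1, 3), c(2, 4))
  expect_equal(inter$D, 0.5)
  expect_error(ks_two_sample(numeric(), 1:3), "empty")
})

test_that("KS statistic equals the brute-force pooled-ECDF oracle", {
  set.seed(403)
  for (rep in 1:200) {
    n1 <- sample(1:12, 1); n2 <- sample(1:12, 1)
    x <- round(rnorm(n1), 1)   # rounding forces frequent ties
    y <- round(rnorm(n2, sample(c(0, 1), 1)), 1)
    expect_equal(ks_two_sample(x, y)$D, ks_oracle_D(x, y))
  }
})

test_that("asymptotic and exact KS p-values agree with stats::ks.test", {
  set.seed(404)
  x <- rnorm(60); y <- rnorm(80, 0.3)
  got <- ks_two_sample(x, y, exact = FALSE)
  want <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(got$D, unname(want$statistic))
  expect_equal(got$p, want$p.value, tolerance = 1e-8)

  xs <- rnorm(8); ys <- rnorm(9, 1)
  got_e <- ks_two_sample(xs, ys)        # exact by default at this size
  want_e <- stats::ks.test(xs, ys, exact = TRUE)
  expect_equal(got_e$method, "exact")
  expect_equal(got_e$p, want_e$p.value, tolerance = 1e-10)
})

fake_assignment <- function(genes) {
  data.frame(peak_name = if (length(genes)) paste0("p", seq_along(genes)) else character(),
             chrom = rep("chr1", length(genes)),
             reference = integer(length(genes)), gene_id = genes,
             distance = numeric(length(genes)), stringsAsFactors = FALSE)
}

test_that("region-expression concordance detects a planted shift", {
  set.seed(405)
  hits <- 0
  runs <- 50
  for (r in 1:runs) {
    genes <- paste0("g", 1:200)
    fc <- c(rnorm(60, 2, 0.5), rnorm(60, -2, 0.5), rnorm(80, 0, 0.5))
    expr <- fake_comparison(genes, fc, rep(0.01, 200), "WTCV/WTGF")
    a_cv <- fake_assignment(genes[1:60])     # CV-enriched near CV-high genes
    a_gf <- fake_assignment(genes[61:120])   # GF-enriched near GF-high genes
    ks <- ks_region_expression(a_gf, a_cv, expr)
    if (ks$shift_sign == 1 && ks$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.95)
})

test_that("region-expression concordance is null-calibrated", {
  # the two-sample KS statistic is discrete at these group sizes, so null
  # p-values are valid but conservative between atoms; calibration is
  # asserted through rejection rates rather than strict uniformity
  set.seed(406)
  pvals <- replicate(300, {
    genes <- paste0("g", 1:150)
    expr <- fake_comparison(genes, rnorm(150), runif(150), "WTCV/WTGF")
    picks <- sample(genes, 100)
    ks_region_expression(fake_assignment(picks[1:50]),
                         fake_assignment(picks[51:100]), expr)$p
  })
  expect_gt(mean(pvals < 0.05), 0.01)
  expect_lt(mean(pvals < 0.05), 0.09)
  expect_lte(mean(pvals < 0.01), 0.03)
  expect_gt(mean(pvals), 0.45)
})

test_that("empty region sets raise informative errors", {
  expr <- fake_comparison(c("g1", "g2"), c(1, -1), c(0.01, 0.01))
  expect_error(ks_region_expression(fake_assignment(character()),
                                    fake_assignment("g1"), expr),
               "GF-enriched")
  expect_error(ks_region_expression(fake_assignment("g1"),
                                    fake_assignment(character()), expr),
               "CV-enriched")
})

test_that("background mode compares each group against all genes", {
  genes <- paste0("g", 1:100)
  expr <- fake_comparison(genes, c(rnorm(50, 1), rnorm(50, -1)),
                          rep(0.01, 100))
  res <- ks_region_expression(fake_assignment(genes[51:100]),
                              fake_assignment(genes[1:50]), expr,
                              mode = "background")
  expect_named(res, c("cv_vs_all", "gf_vs_all"))
  expect_s3_class(res$cv_vs_all, "ks_result")
  expect_equal(res$cv_vs_all$n2, 100)
})
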