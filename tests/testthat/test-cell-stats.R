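test_that("low-expression filter keeps exactly the cells at or above the cutoff", {
  df <- data.frame(label = 1:4, mrna_count = c(0L, 9L, 10L, 11L))
  expect_equal(filter_low_expression(df)$mrna_count, c(10L, 11L))
  expect_identical(filter_low_expression(df, 0), df)
  expect_warning(filter_low_expression(data.frame(mrna_count = c(0L, 0L))),
                 "all cells removed")
})

test_that("TS subgrouping partitions into 0 / 1 / 2+ classes", {
  df <- data.frame(label = 1:5, ts_count = c(0L, 1L, 2L, 3L, 4L))
  g <- group_by_ts(df)
  expect_equal(unname(attr(g, "sizes")), c(1L, 1L, 3L))
  g0 <- group_by_ts(df[0, ])
  expect_equal(unname(attr(g0, "sizes")), c(0L, 0L, 0L))
  expect_error(group_by_ts(data.frame(ts_count = -1L)), "negative")
})

test_that("TS class proportions follow the binomial ON-probability law", {
  cfg <- counts_config(seed = 21)
  cm <- build_cell_lattice(cfg)
  fl <- assign_domains(cm, cfg)
  gt <- simulate_transcription(cm, fl, cfg, "WT")
  sizes <- attr(group_by_ts(data.frame(ts_count = gt$cells$true_ts)), "sizes")
  n <- sum(sizes)
  p_on <- cfg$k_on / (cfg$k_on + cfg$k_off)
  expected <- n * stats::dbinom(0:2, size = 2, prob = p_on)
  for (k in 1:3) {
    se <- sqrt(n * (expected[k] / n) * (1 - expected[k] / n))
    expect_lt(abs(sizes[k] - expected[k]), 3.5 * se)
  }
})

test_that("neighbor graph: grid geometry, symmetry, definition agreement", {
  # 3x3 regular square lattice by construction
  lab <- matrix(0L, 30, 30)
  for (r in 1:3) for (c in 1:3)
    lab[(r - 1) * 10 + 1:10, (c - 1) * 10 + 1:10] <- (r - 1L) * 3L + c
  g <- build_neighbor_graph(lab)
  deg <- vapply(g$adj, length, integer(1))
  expect_equal(unname(deg[c("1", "2", "5")]), c(2L, 3L, 4L))
  # symmetry
  for (nd in g$nodes)
    for (nb in g$adj[[as.character(nd)]])
      expect_true(nd %in% g$adj[[as.character(nb)]])

  # label-adjacency and centroid-Voronoi adjacency agree on a regular
  # lattice interior
  cfg <- sim_config(n_cols = 7, n_rows = 6, cell_pitch_px = 20, jitter = 0)
  cm <- build_cell_lattice(cfg)
  g_lab <- build_neighbor_graph(cm$label_image)
  g_cen <- build_neighbor_graph(centroids = cm$cells[, c("label", "cx", "cy")])
  interior <- cm$cells$label[!cm$cells$border]
  for (nd in interior)
    expect_equal(g_cen$adj[[as.character(nd)]], g_lab$adj[[as.character(nd)]])
})

test_that("local dispersion matches hand computation and brute force", {
  # focal cell 5 of the 3x3 grid with counts {2,4,6} in a 3-cluster
  lab <- matrix(0L, 30, 30)
  for (r in 1:3) for (c in 1:3)
    lab[(r - 1) * 10 + 1:10, (c - 1) * 10 + 1:10] <- (r - 1L) * 3L + c
  g <- build_neighbor_graph(lab)
  cells <- data.frame(label = 1:9, mrna_count = c(0, 2, 0, 4, 6, 0, 0, 0, 0))
  # focal 5, exclude focal: cluster = {2,4,6,8} -> counts {2,4,0,0}; include
  # focal: {6,2,4,0,0}. Use a custom cluster to pin the hand case: cells
  # 2,4,6 around a synthetic star graph.
  star <- structure(list(nodes = 1:4,
                         adj = list(`1` = 2:4, `2` = 1L, `3` = 1L, `4` = 1L),
                         edges = cbind(1L, 2:4),
                         border = c(`1` = FALSE, `2` = TRUE, `3` = TRUE,
                                    `4` = TRUE)),
                    class = "neighbor_graph")
  cc <- data.frame(label = 1:4, mrna_count = c(2, 4, 6, 5))
  d_excl <- local_dispersion(cc, star, include_focal = FALSE)
  # cluster {4,6,5}: mean 5, var 1, fano 0.2, cv 0.2
  expect_equal(d_excl$cluster_mean, 5)
  expect_equal(d_excl$fano, 0.2)
  cc2 <- data.frame(label = 1:4, mrna_count = c(4, 2, 4, 6))
  d2 <- local_dispersion(cc2, star, include_focal = TRUE)
  # cluster {4,2,4,6}: mean 4, sample var 8/3
  expect_equal(d2$cluster_mean, 4)
  expect_equal(d2$cluster_var, 8 / 3)
  # the documented hand case: counts {2,4,6} -> mean 4, var 4, FF 1, CV 0.5
  star3 <- structure(list(nodes = 1:3,
                          adj = list(`1` = 2:3, `2` = 1L, `3` = 1L),
                          edges = cbind(1L, 2:3),
                          border = c(`1` = FALSE, `2` = TRUE, `3` = TRUE)),
                     class = "neighbor_graph")
  d3 <- local_dispersion(data.frame(label = 1:3, mrna_count = c(2, 4, 6)),
                         star3, include_focal = TRUE)
  expect_equal(d3$cluster_mean, 4)
  expect_equal(d3$cluster_var, 4)
  expect_equal(d3$fano, 1)
  expect_equal(d3$cv, 0.5)

  # equal counts: zero dispersion
  d_eq <- local_dispersion(data.frame(label = 1:4, mrna_count = rep(5, 4)),
                           star, include_focal = TRUE)
  expect_equal(d_eq$fano, 0)
  expect_equal(d_eq$cv, 0)

  # brute-force recomputation matches on a jittered lattice
  cfg <- sim_config(n_cols = 12, n_rows = 10, cell_pitch_px = 10, seed = 8)
  cm <- build_cell_lattice(cfg)
  gr <- build_neighbor_graph(cm$label_image)
  cells_r <- data.frame(label = cm$cells$label,
                        mrna_count = with_seed(31, rpois(nrow(cm$cells), 15)))
  mod <- local_dispersion(cells_r, gr)
  ora <- brute_dispersion(cells_r, gr)
  expect_equal(mod$fano, ora$fano)
  expect_equal(mod$cv, ora$cv)
  expect_equal(mod$cluster_var, ora$cluster_var)

  # zero-mean clusters are missing, never zero
  d0 <- local_dispersion(data.frame(label = 1:4, mrna_count = rep(0, 4)), star)
  expect_true(is.na(d0$fano))
})

test_that("Poisson counts calibrate FF to 1 and CV to 1/sqrt(lambda)", {
  cfg <- sim_config(n_cols = 40, n_rows = 36, cell_pitch_px = 8, seed = 14)
  cm <- build_cell_lattice(cfg)
  gr <- build_neighbor_graph(cm$label_image)
  lambda <- 20
  cells <- data.frame(label = cm$cells$label,
                      mrna_count = with_seed(15, rpois(nrow(cm$cells), lambda)))
  d <- local_dispersion(cells, gr)
  expect_gte(sum(!is.na(d$fano)), 500)
  expect_gt(mean(d$fano, na.rm = TRUE), 0.9)
  expect_lt(mean(d$fano, na.rm = TRUE), 1.1)
  cv_mean <- mean(d$cv, na.rm = TRUE)
  expect_lt(abs(cv_mean - 1 / sqrt(lambda)) / (1 / sqrt(lambda)), 0.15)
})

test_that("FF scales linearly with counts while CV is scale-free", {
  star <- structure(list(nodes = 1:4,
                         adj = list(`1` = 2:4, `2` = 1L, `3` = 1L, `4` = 1L),
                         edges = cbind(1L, 2:4),
                         border = c(`1` = FALSE, `2` = TRUE, `3` = TRUE,
                                    `4` = TRUE)),
                    class = "neighbor_graph")
  cells <- data.frame(label = 1:4, mrna_count = c(3, 7, 11, 6))
  a <- 3.7
  d1 <- local_dispersion(cells, star)
  d2 <- local_dispersion(transform(cells, mrna_count = mrna_count * a), star)
  expect_equal(d2$fano, a * d1$fano)
  expect_equal(d2$cv, d1$cv)
})

test_that("genotype comparison: exact oracle, identity, and approximation", {
  r <- compare_genotypes(1:8, 101:108)
  expect_true(r$exact)
  expect_equal(r$p.value, 2 / 12870)
  expect_equal(r$median_ko - r$median_wt, 100)
  expect_equal(r$hl_shift, 100)

  same <- compare_genotypes(1:20 * 1.5, 1:20 * 1.5)
  expect_gte(same$p.value, 0.95)

  expect_error(compare_genotypes(numeric(0), 1:3), "non-empty")

  # normal approximation tracks exact enumeration for moderate p at n <= 8
  with_seed(77, {
    checked <- 0
    while (checked < 25) {
      x <- sample(1:200, 8); y <- sample(1:200, 8) + sample(0:40, 1)
      if (anyDuplicated(c(x, y))) next
      pe <- wilcox.test(y, x, exact = TRUE)$p.value
      if (pe < 0.05) next
      pn <- suppressWarnings(
        wilcox.test(y, x, exact = FALSE, correct = TRUE)$p.value)
      expect_lt(abs(pn - pe) / pe, 0.10)
      checked <- checked + 1
    }
  })
})

test_that("measurement ROIs: 15 areas, 5 per region, disjoint, reproducible", {
  mask <- matrix(TRUE, 60, 180)
  rois <- sample_measurement_areas(mask, seed = 4)
  expect_equal(nrow(rois), 15L)
  expect_equal(unname(table(rois$region)[c("anterior", "central", "posterior")]),
               rep(5L, 3), ignore_attr = TRUE)
  # pairwise disjoint
  for (i in 1:14) for (j in (i + 1):15) {
    sep <- rois$x0[i] + rois$box_px[i] <= rois$x0[j] ||
           rois$x0[j] + rois$box_px[j] <= rois$x0[i] ||
           rois$y0[i] + rois$box_px[i] <= rois$y0[j] ||
           rois$y0[j] + rois$box_px[j] <= rois$y0[i]
    expect_true(sep)
  }
  expect_identical(rois, sample_measurement_areas(mask, seed = 4))
  expect_error(sample_measurement_areas(matrix(TRUE, 12, 12), box_px = 10),
               "region too small")
})

test_that("adjusted fluorescence implements the background formula exactly", {
  expect_equal(as.numeric(adjusted_fluorescence(1000, 50, 4)), 800)
  expect_equal(as.numeric(adjusted_fluorescence(123.4, 0, 99)), 123.4)
  neg <- adjusted_fluorescence(100, 50, 4)
  expect_equal(as.numeric(neg), -100)
  expect_true(attr(neg, "flagged"))
  expect_error(adjusted_fluorescence(Inf, 1, 1), "non-finite")
  expect_error(adjusted_fluorescence(1, -2, 1), "area")
})
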