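# shared control profile for power tests: modest size keeps the suite quick
ctrl_norm <- lognormalize(make_control_matrix(
  sim_config(n_cells = 500, n_genes = 300, seed = 77)))

test_that("quantile bucketing splits genes into equal-count contiguous intervals", {
  b <- bucket_genes(ctrl_norm, 10)
  sizes <- lengths(b$buckets)
  expect_equal(sum(sizes), sum(Matrix::colMeans(ctrl_norm) > 0))
  expect_true(max(sizes) - min(sizes) <= 1)
  # boundaries reproduce a brute-force sort-and-split of gene means
  means <- Matrix::colMeans(ctrl_norm)
  means <- sort(means[means > 0])
  for (i in seq_along(b$buckets)) {
    lo <- floor((i - 1) * length(means) / 10) + 1
    hi <- floor(i * length(means) / 10)
    expect_equal(sort(unname(Matrix::colMeans(ctrl_norm)[b$buckets[[i]]])),
                 unname(means[lo:hi]))
  }
  # buckets ordered by increasing expression
  expect_true(!is.unsorted(b$min_mean))
})

test_that("equal-mean genes collapse to a single bucket with a warning", {
  m <- Matrix::Matrix(matrix(1, 20, 15), sparse = TRUE,
                      dimnames = list(sprintf("c%02d", 1:20),
                                      sprintf("g%02d", 1:15)))
  expect_warning(b <- bucket_genes(m, 10), "single effective bucket")
  expect_equal(length(b$buckets), 1)
})

test_that("filtered test counts match brute-force enumeration over gene means", {
  b <- bucket_genes(ctrl_norm, 10)
  means <- Matrix::colMeans(ctrl_norm)
  for (i in c(1, 4, 10)) {
    expect_equal(filtered_test_count(b, i), sum(means >= b$min_mean[i]))
  }
  # bottom bucket tests every expressed gene plus any higher zero-mean... none
  expect_equal(filtered_test_count(b, 1), sum(means >= b$min_mean[1]))
  # top bucket of an equal-count split over 1000 genes has ~100 genes
  big <- Matrix::Matrix(matrix(rep(seq(0.1, 10, length.out = 1000),
                                   each = 10), 10), sparse = TRUE,
                        dimnames = list(sprintf("c%02d", 1:10),
                                        sprintf("g%04d", 1:1000)))
  bb <- bucket_genes(big, 10)
  expect_equal(filtered_test_count(bb, 10), 100)
  expect_equal(filtered_test_count(bb, 1), 1000)
})

test_that("loss injection halves or zeroes the sampled expression", {
  vals <- rlnorm(200, 1, 0.5)
  withr::with_seed(1, {
    out <- simulate_loss(vals, 50, f_mono = 0, f_full = 0)
    expect_true(all(out %in% vals))  # unmodified resample
    expect_true(all(simulate_loss(vals, 50, 0, 1) == 0))
  })
  expect_error(simulate_loss(vals, 10, 0.6, 0.6), "<= 1")
  expect_error(simulate_loss(vals, 0, 0.1, 0.1), ">= 1")
  # expectation: mean converges to (1 - f_full - f_mono/2) * control mean
  withr::with_seed(2, {
    draws <- replicate(200, mean(simulate_loss(vals, 50, 0.3, 0.1)))
  })
  expect_equal(mean(draws), (1 - 0.1 - 0.15) * mean(vals), tolerance = 0.02)
})

test_that("power grids satisfy their adjustment and dominance invariants", {
  pg <- power_curve(ctrl_norm, f_mono = 0.25, f_full = 0.25,
                    n_treat_grid = c(50, 150), n_buckets = 5, reps = 20,
                    seed = 4)
  g <- pg$grid
  expect_true(all(g$p_adj_all >= g$p_raw))
  expect_true(all(g$p_adj_filtered >= g$p_raw))
  expect_true(all(g$p_adj_filtered <= g$p_adj_all + 1e-12))
  expect_true(all(g$m_b <= g$m_all))
  mc_f <- min_cells_required(pg, 0.05, "filtered")$min_cells
  mc_a <- min_cells_required(pg, 0.05, "all")$min_cells
  both <- !is.na(mc_f) & !is.na(mc_a)
  expect_true(all(mc_f[both] <= mc_a[both]))
  # a bucket detected under all-genes adjustment is detected under filtering
  expect_true(all(!is.na(mc_f[!is.na(mc_a)])))
})

test_that("power grids are bit-reproducible for a fixed seed", {
  a <- power_curve(ctrl_norm, 0.2, 0.1, c(30, 60), n_buckets = 4, reps = 10,
                   seed = 99)
  b <- power_curve(ctrl_norm, 0.2, 0.1, c(30, 60), n_buckets = 4, reps = 10,
                   seed = 99)
  expect_identical(a$grid, b$grid)
  expect_identical(a$reps, b$reps)
})

test_that("summarized p decreases with treatment size and loss severity (common random numbers)", {
  grid <- c(50, 100, 200)
  pg_full <- power_curve(ctrl_norm, 0, 1, grid, n_buckets = 5, reps = 40,
                         seed = 12)
  # per-bucket medians non-increasing in n_treat, within a paired noise band
  for (b in unique(pg_full$grid$bucket)) {
    sub <- pg_full$grid[pg_full$grid$bucket == b, ]
    reps_b <- pg_full$reps[pg_full$reps$bucket == b, ]
    for (i in seq_len(nrow(sub) - 1)) {
      d <- reps_b$p[reps_b$n_treat == sub$n_treat[i + 1]] -
        reps_b$p[reps_b$n_treat == sub$n_treat[i]]
      band <- 2 * sd(d) / sqrt(length(d)) + 1e-12
      expect_lte(sub$p_raw[i + 1], sub$p_raw[i] + band)
    }
  }
  # heavier biallelic loss cannot weaken the median signal (same substreams)
  pg_half <- power_curve(ctrl_norm, 0, 0.5, grid, n_buckets = 5, reps = 40,
                         seed = 12)
  m_full <- pg_full$grid$p_raw
  m_half <- pg_half$grid$p_raw
  d <- pg_full$reps$p - pg_half$reps$p
  band <- 2 * sd(d) / sqrt(40) + 1e-12
  expect_true(all(m_full <= m_half + band))
  # higher-expression buckets need no more cells than lower ones on median p
  top <- pg_full$grid[pg_full$grid$bucket == 5 & pg_full$grid$n_treat == 200, ]
  bottom <- pg_full$grid[pg_full$grid$bucket == 1 & pg_full$grid$n_treat == 200, ]
  expect_lte(top$p_raw, bottom$p_raw + band)
})

test_that("minimum-cells extraction reads the grid correctly", {
  fake <- list(grid = data.frame(
    bucket = rep(1:2, each = 3), n_treat = rep(c(100, 200, 300), 2),
    p_raw = c(0.2, 0.04, 0.01, 0.3, 0.2, 0.1),
    p_adj_all = c(0.9, 0.4, 0.1, 1, 1, 1),
    p_adj_filtered = c(0.6, 0.04, 0.02, 1, 0.9, 0.8)))
  class(fake) <- "power_grid"
  expect_equal(min_cells_required(fake, 0.05, "raw")$min_cells, c(200, NA))
  expect_equal(min_cells_required(fake, 0.05, "all")$min_cells,
               as.numeric(c(NA, NA)))
  expect_equal(min_cells_required(fake, 0.05, "filtered")$min_cells,
               c(200, NA))
})
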