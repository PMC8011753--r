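test_that("EM recovers generating mixture parameters on simulated counts", {
  s <- sim_mixture_counts(2000, 150, 0.005, 0.95, 0.3, seed = 11)
  fit <- fit_binomial_mixture(s$k, s$n)
  expect_true(fit$converged)
  expect_lt(abs(fit$p_noise - 0.005) / 0.005, 0.10)
  expect_lt(abs(fit$p_signal - 0.95) / 0.95, 0.10)
  expect_lt(abs(fit$pi_signal - 0.3), 0.05)
  expect_false(is.unsorted(fit$loglik_trace))
  pres <- call_presence(fit, s$k, s$n)
  expect_gte(mean(pres == s$z), 0.99)
})

test_that("all-zero counts give a degenerate fit with no presence calls", {
  fit <- fit_binomial_mixture(rep(0, 50), rep(100, 50))
  expect_true(fit$degenerate)
  expect_false(any(call_presence(fit, rep(0, 50), rep(100, 50))))
  expect_true(all(noise_probability(fit, c(0, 50), c(100, 100)) == 1))
})

test_that("well-separated point masses recover the closed-form rates", {
  # when responsibilities saturate, the M step gives the per-cluster
  # weighted means: p = sum(k)/sum(n) within each cluster
  n <- rep(1000, 300)
  k <- c(rep(1, 200), rep(900, 100))
  fit <- fit_binomial_mixture(k, n)
  expect_equal(fit$p_noise, 0.001, tolerance = 1e-6)
  expect_equal(fit$p_signal, 0.9, tolerance = 1e-6)
  expect_equal(fit$pi_signal, 1 / 3, tolerance = 1e-6)
})

test_that("noise probability matches direct evaluation of the posterior", {
  fit <- structure(list(p_noise = 0.005, p_signal = 0.95, pi_signal = 0.3,
                        degenerate = FALSE), class = "mixture_fit")
  k <- 90; n <- 100
  num <- (1 - 0.3) * dbinom(k, n, 0.005)
  den <- num + 0.3 * dbinom(k, n, 0.95)
  expect_equal(noise_probability(fit, k, n), num / den)
  # zero count with a large total overwhelmingly favors noise
  expect_gt(noise_probability(fit, 0, 200), 0.999)
  # n = 0 carries no evidence: defined as pure noise
  expect_equal(noise_probability(fit, 0, 0), 1)
})

test_that("identical components give noise probability 1 - pi everywhere", {
  fit <- structure(list(p_noise = 0.4, p_signal = 0.4, pi_signal = 0.25,
                        degenerate = FALSE), class = "mixture_fit")
  for (kn in list(c(0, 10), c(5, 10), c(10, 10))) {
    expect_equal(noise_probability(fit, kn[1], kn[2]), 0.75)
  }
})

test_that("noise probability is non-increasing in k at fixed n", {
  fit <- structure(list(p_noise = 0.01, p_signal = 0.6, pi_signal = 0.3,
                        degenerate = FALSE), class = "mixture_fit")
  p <- noise_probability(fit, 0:100, rep(100, 101))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("presence threshold is strict: exactly 0.05 is absent", {
  fit <- structure(list(p_noise = 0.01, p_signal = 0.9, pi_signal = 0.3,
                        degenerate = FALSE), class = "mixture_fit")
  # manufacture noise probabilities around the threshold via direct calls
  expect_false(call_presence(fit, 0, 100))       # noise prob ~ 1
  expect_true(call_presence(fit, 90, 100))       # noise prob ~ 0
  # strictness at the boundary, checked on the rule itself
  fit2 <- structure(list(p_noise = 0.5, p_signal = 0.5, pi_signal = 0.95,
                         degenerate = FALSE), class = "mixture_fit")
  expect_equal(noise_probability(fit2, 3, 10), 0.05)
  expect_false(call_presence(fit2, 3, 10))
})

test_that("swapped manual initializations converge to the same ordered fit", {
  s <- sim_mixture_counts(800, 120, 0.01, 0.8, 0.4, seed = 5)
  f1 <- fit_binomial_mixture(s$k, s$n, mixture_opts(
    init = list(p_noise = 0.02, p_signal = 0.7, pi_signal = 0.5)))
  f2 <- fit_binomial_mixture(s$k, s$n, mixture_opts(
    init = list(p_noise = 0.7, p_signal = 0.02, pi_signal = 0.5)))
  expect_equal(f1$p_noise, f2$p_noise, tolerance = 1e-4)
  expect_equal(f1$p_signal, f2$p_signal, tolerance = 1e-4)
  expect_equal(f1$pi_signal, f2$pi_signal, tolerance = 1e-4)
  expect_lt(f1$p_noise, f1$p_signal)
})

test_that("cells are assigned only when exactly one guide is present", {
  presence <- rbind(c(FALSE, TRUE, FALSE),
                    c(TRUE, TRUE, FALSE),
                    c(FALSE, FALSE, FALSE))
  dimnames(presence) <- list(c("c1", "c2", "c3"), c("gA", "gB", "gC"))
  tab <- assign_cells(presence)
  expect_equal(tab$status, c("assigned", "multiple_present", "none_present"))
  expect_equal(tab$assigned_guide, c("gB", NA, NA))
})

test_that("detection rate matches brute-force enumeration and the printed arithmetic", {
  # printed sorted-pool arithmetic: 13016 high-quality cells, 3208 unassigned
  cells <- sprintf("c%05d", 1:13016)
  status <- c(rep("assigned", 13016 - 3208), rep("none_present", 3208))
  tab <- data.frame(cell = cells, status = status,
                    stringsAsFactors = FALSE)
  expect_equal(detection_rate(tab, cells) * 100, 75.3, tolerance = 0.1 / 75.3)

  # synthetic screen: rate equals direct enumeration over cells
  set.seed(31)
  presence <- matrix(runif(600) < 0.3, 200, 3,
                     dimnames = list(sprintf("b%03d", 1:200), c("g1", "g2", "g3")))
  tab2 <- assign_cells(presence)
  hq <- sample(rownames(presence), 150)
  brute <- sum(vapply(hq, function(cc) sum(presence[cc, ]) == 1, logical(1))) /
    length(hq)
  expect_equal(detection_rate(tab2, hq), brute)
  expect_error(detection_rate(tab2, character(0)), "empty")
})

test_that("panel fitting on a simulated pooled screen recovers labels", {
  cfg <- sim_config(n_cells = 600, n_guides = 6, guide_total_mean = 120,
                    p_noise = 0.005, p_signal = 0.95, seed = 9)
  gc <- make_guide_counts(cfg)
  truth <- attr(gc, "truth")
  panel <- fit_guide_panel(gc)
  expect_true(all(vapply(panel$fits, function(f)
    !is.unsorted(f$loglik_trace), logical(1))))
  tab <- assign_cells(panel$presence)
  ok <- tab$status == "assigned" & tab$assigned_guide == truth$true_guide
  expect_gte(mean(ok), 0.99)
})
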