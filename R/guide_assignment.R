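# Guide presence calling: per-guide two-component binomial mixture fit by EM,
# presence at noise posterior < 0.05, single-guide cell assignment, and the
# detection-rate summary.
#
# Model: for cell i with total guide UMI count n_i and count k_i on guide g,
#   k_i | z_i ~ Binomial(n_i, p_{z_i}),   z_i ~ Bernoulli(pi_signal),
# with z_i = 1 the "signal" component (guide truly present) and z_i = 0 the
# "noise" component (mapping artefacts, ambient molecules). Each guide is fit
# independently across all cells with n_i > 0.

#' Options for the binomial mixture fit
#'
#' @param tol EM stops when the log-likelihood gain falls below this.
#' @param max_iter Maximum EM iterations.
#' @param eps Probabilities are clipped to \code{[eps, 1 - eps]} to avoid
#'   degenerate likelihoods.
#' @param min_cells Fewer than this many cells with \code{k > 0} flags the
#'   fit as low-support.
#' @param seed Seed for the Gaussian-mixture initialization (reproducibility).
#' @param init Optional manual initialization, a list with \code{p_noise},
#'   \code{p_signal}, \code{pi_signal}; skips the Gaussian-mixture step.
#' @return A list of options for [fit_binomial_mixture()].
#' @export
mixture_opts <- function(tol = 1e-6, max_iter = 500, eps = 1e-6,
                         min_cells = 5, seed = 1L, init = NULL) {
  list(tol = tol, max_iter = max_iter, eps = eps,
       min_cells = min_cells, seed = seed, init = init)
}

#' @noRd
binom_loglik <- function(k, n, p_noise, p_signal, pi_signal) {
  l0 <- log1p(-pi_signal) + stats::dbinom(k, n, p_noise, log = TRUE)
  l1 <- log(pi_signal) + stats::dbinom(k, n, p_signal, log = TRUE)
  m <- pmax(l0, l1)
  sum(m + log(exp(l0 - m) + exp(l1 - m)))
}

# Initialization: 2-component Gaussian mixture on the raw count fractions
# k/n; initial success probabilities are the cluster means (clipped), the
# initial mixing weight is the upper cluster's weight. Falls back to a
# quantile split if the GMM fails or its clusters coincide.
#' @noRd
init_from_gmm <- function(frac, eps, seed) {
  init <- tryCatch({
    fit <- withr_seed(seed, mclust::Mclust(frac, G = 2, verbose = FALSE))
    if (is.null(fit)) stop("mclust returned NULL")
    mu <- as.numeric(fit$parameters$mean)
    pro <- as.numeric(fit$parameters$pro)
    ord <- order(mu)
    list(p = mu[ord], pi = pro[ord][2])
  }, error = function(e) NULL)
  if (is.null(init)) {
    hi <- frac > stats::median(frac)
    if (!any(hi) || all(hi)) hi <- frac >= max(frac)
    init <- list(p = c(mean(frac[!hi]), mean(frac[hi])), pi = mean(hi))
  }
  p <- pmin(pmax(init$p, eps), 1 - eps)
  if (abs(p[1] - p[2]) < eps) {  # coincident clusters: nudge apart
    p <- pmin(pmax(c(p[1] * 0.9, p[2] * 1.1), eps), 1 - eps)
  }
  pi_signal <- min(max(init$pi, eps), 1 - eps)
  list(p_noise = p[1], p_signal = p[2], pi_signal = pi_signal)
}

#' Run code under a temporary RNG seed, restoring the caller's RNG state
#' @noRd
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit the two-component binomial mixture for one guide
#'
#' Fits \code{k_i | z_i ~ Binomial(n_i, p_{z_i})}, \code{z_i ~
#' Bernoulli(pi_signal)} by expectation-maximization, initialized from a
#' two-component Gaussian mixture on the count fractions \code{k/n}. The E
#' step computes signal responsibilities; the M step uses the closed-form
#' weighted updates \code{p_c = sum(r_c k) / sum(r_c n)} and \code{pi =
#' mean(r_signal)}. Components are relabeled so \code{p_noise < p_signal}.
#'
#' @param k Per-cell UMI counts for this guide.
#' @param n Per-cell total guide UMI counts; cells with \code{n = 0} must be
#'   excluded before fitting.
#' @param opts Options from [mixture_opts()].
#' @return An object of class \code{mixture_fit}: \code{p_noise},
#'   \code{p_signal}, \code{pi_signal}, \code{loglik_trace},
#'   \code{converged}, \code{degenerate} (all-zero counts), \code{low_support},
#'   \code{n_cells_used}.
#' @export
fit_binomial_mixture <- function(k, n, opts = mixture_opts()) {
  if (length(k) != length(n)) stop("k and n must have equal length")
  if (any(n <= 0)) stop("all cells must have total guide count n > 0")
  if (any(k > n)) stop("k must not exceed n")
  fit <- list(n_cells_used = length(k),
              low_support = sum(k > 0) < opts$min_cells)
  if (all(k == 0)) {
    fit <- c(fit, list(p_noise = 0, p_signal = NA_real_, pi_signal = 0,
                       loglik_trace = numeric(), converged = TRUE,
                       degenerate = TRUE))
    class(fit) <- "mixture_fit"
    return(fit)
  }
  init <- if (!is.null(opts$init)) opts$init
  else init_from_gmm(k / n, opts$eps, opts$seed)
  p0 <- init$p_noise; p1 <- init$p_signal; pi1 <- init$pi_signal
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(opts$max_iter)) {
    # E step in log space
    l0 <- log1p(-pi1) + stats::dbinom(k, n, p0, log = TRUE)
    l1 <- log(pi1) + stats::dbinom(k, n, p1, log = TRUE)
    m <- pmax(l0, l1)
    ll <- sum(m + log(exp(l0 - m) + exp(l1 - m)))
    trace <- c(trace, ll)
    if (it > 1 && (ll - trace[it - 1]) < opts$tol) {
      converged <- TRUE
      break
    }
    r1 <- 1 / (1 + exp(l0 - l1))
    # M step: weighted binomial MLEs
    p1 <- sum(r1 * k) / sum(r1 * n)
    p0 <- sum((1 - r1) * k) / sum((1 - r1) * n)
    p0 <- min(max(p0, opts$eps), 1 - opts$eps)
    p1 <- min(max(p1, opts$eps), 1 - opts$eps)
    pi1 <- min(max(mean(r1), opts$eps), 1 - opts$eps)
  }
  # EM guarantees a non-decreasing likelihood; a violation means a defect
  if (length(trace) > 1 && any(diff(trace) < -1e-8)) {
    stop("internal error: EM log-likelihood decreased")
  }
  if (p0 > p1) {  # relabel so the noise component has the lower rate
    tmp <- p0; p0 <- p1; p1 <- tmp
    pi1 <- 1 - pi1
  }
  fit <- c(fit, list(p_noise = p0, p_signal = p1, pi_signal = pi1,
                     loglik_trace = trace, converged = converged,
                     degenerate = FALSE))
  class(fit) <- "mixture_fit"
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Binomial mixture fit (", x$n_cells_used, " cells)\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate: all counts zero, no signal component\n")
  } else {
    cat(sprintf("  p_noise = %.4g, p_signal = %.4g, pi_signal = %.4g\n",
                x$p_noise, x$p_signal, x$pi_signal))
    cat(sprintf("  %d EM iterations, converged = %s\n",
                length(x$loglik_trace), x$converged))
  }
  invisible(x)
}

#' Posterior probability that a count arose from noise
#'
#' For the fitted mixture, returns the posterior responsibility of the noise
#' component at (k, n):
#' \deqn{(1-\pi) B(k; n, p_0) / [(1-\pi) B(k; n, p_0) + \pi B(k; n, p_1)].}
#' Cells with \code{n = 0} carry no evidence of presence and get probability
#' 1; a degenerate (all-zero) fit likewise returns 1 everywhere.
#'
#' @param fit A \code{mixture_fit}.
#' @param k,n Counts and totals (vectorized).
#' @return Numeric vector of noise probabilities in \code{[0, 1]}.
#' @export
noise_probability <- function(fit, k, n) {
  if (any(k > n)) stop("k must not exceed n")
  out <- rep(1, length(k))
  if (fit$degenerate) return(out)
  pos <- n > 0
  l0 <- log1p(-fit$pi_signal) +
    stats::dbinom(k[pos], n[pos], fit$p_noise, log = TRUE)
  l1 <- log(fit$pi_signal) +
    stats::dbinom(k[pos], n[pos], fit$p_signal, log = TRUE)
  out[pos] <- 1 / (1 + exp(l1 - l0))
  out
}

#' Call guide presence in cells
#'
#' A guide is present in a cell when the posterior probability of its count
#' arising from the noise component is strictly below \code{threshold}.
#'
#' @inheritParams noise_probability
#' @param threshold Noise-probability cutoff (default 0.05).
#' @return Logical vector, TRUE where the guide is called present.
#' @export
call_presence <- function(fit, k, n, threshold = 0.05) {
  noise_probability(fit, k, n) < threshold
}

#' Fit all guides of a count matrix
#'
#' Fits the binomial mixture for each guide (column) independently across all
#' cells with total guide count \code{n > 0} and calls presence.
#'
#' @param counts cells x guides matrix of UMI-unique counts.
#' @param threshold Presence threshold on the noise probability.
#' @param opts Options from [mixture_opts()].
#' @return A list with \code{fits} (named list of \code{mixture_fit}),
#'   \code{presence} (cells x guides logical matrix; all-FALSE rows for cells
#'   with \code{n = 0}), and \code{diagnostics} (per-guide data.frame).
#' @export
fit_guide_panel <- function(counts, threshold = 0.05, opts = mixture_opts()) {
  n_tot <- Matrix::rowSums(counts)
  use <- n_tot > 0
  presence <- matrix(FALSE, nrow(counts), ncol(counts),
                     dimnames = dimnames(counts))
  fits <- vector("list", ncol(counts))
  names(fits) <- colnames(counts)
  for (g in seq_len(ncol(counts))) {
    k <- as.numeric(counts[use, g])
    fit <- fit_binomial_mixture(k, n_tot[use], opts)
    fits[[g]] <- fit
    presence[use, g] <- call_presence(fit, k, n_tot[use], threshold)
  }
  diagnostics <- data.frame(
    guide_id = names(fits),
    p_noise = vapply(fits, `[[`, numeric(1), "p_noise"),
    p_signal = vapply(fits, `[[`, numeric(1), "p_signal"),
    pi_signal = vapply(fits, `[[`, numeric(1), "pi_signal"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    degenerate = vapply(fits, `[[`, logical(1), "degenerate"),
    low_support = vapply(fits, `[[`, logical(1), "low_support"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(fits = fits, presence = presence, diagnostics = diagnostics)
}

#' Assign cells carrying exactly one guide
#'
#' @param presence cells x guides logical matrix from [fit_guide_panel()].
#' @return A data.frame with one row per cell: \code{cell}, \code{n_present},
#'   \code{assigned_guide} (NA unless exactly one guide is present), and
#'   \code{status} in \code{assigned}, \code{none_present},
#'   \code{multiple_present}.
#' @export
assign_cells <- function(presence) {
  n_present <- rowSums(presence)
  status <- ifelse(n_present == 1, "assigned",
                   ifelse(n_present == 0, "none_present", "multiple_present"))
  assigned <- rep(NA_character_, nrow(presence))
  one <- n_present == 1
  if (any(one)) {
    assigned[one] <- colnames(presence)[max.col(presence[one, , drop = FALSE],
                                                ties.method = "first")]
  }
  data.frame(cell = rownames(presence), n_present = as.integer(n_present),
             assigned_guide = assigned, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Guide detection rate
#'
#' Fraction of high-quality transcriptomes confidently mapped to exactly one
#' guide.
#'
#' @param assignments Assignment table from [assign_cells()].
#' @param hq_cells Character vector of high-quality cell barcodes. Cells
#'   absent from the assignment table count as unassigned.
#' @return A single fraction in \code{[0, 1]}.
#' @export
detection_rate <- function(assignments, hq_cells) {
  if (length(hq_cells) == 0) stop("hq_cells is empty")
  assigned <- assignments$cell[assignments$status == "assigned"]
  sum(hq_cells %in% assigned) / length(hq_cells)
}
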