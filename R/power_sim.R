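# Simulation-based power analysis: inject monoallelic (halved) and biallelic
# (zeroed) loss of expression into genes bucketed by baseline expression, test
# treatment vs control by Wilcoxon rank-sum with Bonferroni correction (all
# genes, and after independent filtering), and report p-value grids and the
# minimum number of treatment cells required for detection.

#' Bucket genes by baseline expression
#'
#' Genes with nonzero mean log-normalized expression are partitioned into
#' \code{n_buckets} contiguous intervals of mean expression, either with equal
#' gene counts per bucket (quantile mode, the default) or equal-width
#' intervals in mean expression. Zero-mean genes are never bucketed (they are
#' untestable) but still count toward the all-genes test family.
#'
#' @param control cells x genes matrix of log-normalized control expression.
#' @param n_buckets Number of buckets (default 10).
#' @param mode \code{"quantile"} (equal gene counts) or \code{"width"}
#'   (equal-width intervals; empty buckets are merged into their lower
#'   neighbor with a message).
#' @return An object of class \code{gene_buckets}: \code{gene_means} (all
#'   genes), \code{buckets} (list of gene-name vectors, ordered by increasing
#'   expression), \code{ranges} (per-bucket min/max mean), \code{min_mean}
#'   (per-bucket minimum mean, the independent-filtering cutoff),
#'   \code{m_all} (total genes in the matrix).
#' @export
bucket_genes <- function(control, n_buckets = 10,
                         mode = c("quantile", "width")) {
  mode <- match.arg(mode)
  gene_means <- Matrix::colMeans(control)
  expressed <- gene_means[gene_means > 0]
  if (length(expressed) < n_buckets) {
    stop("need at least ", n_buckets, " genes with nonzero mean")
  }
  if (length(unique(expressed)) == 1) {
    warning("all gene means equal; a single effective bucket")
    groups <- rep(1L, length(expressed))
    n_buckets <- 1L
  } else if (mode == "quantile") {
    ord <- rank(expressed, ties.method = "first")
    groups <- ceiling(ord / length(expressed) * n_buckets)
  } else {
    brk <- seq(min(expressed), max(expressed), length.out = n_buckets + 1)
    groups <- findInterval(expressed, brk, rightmost.closed = TRUE)
    # merge empty intervals into the lower neighbor
    present <- sort(unique(groups))
    if (length(present) < n_buckets) {
      message("empty bucket(s) under equal-width mode merged with neighbor")
    }
    groups <- match(groups, present)
    n_buckets <- length(present)
  }
  buckets <- split(names(expressed), groups)
  names(buckets) <- NULL
  out <- list(
    gene_means = gene_means,
    buckets = buckets,
    ranges = t(vapply(buckets, function(g) range(gene_means[g]), numeric(2))),
    min_mean = vapply(buckets, function(g) min(gene_means[g]), numeric(1)),
    m_all = length(gene_means))
  class(out) <- "gene_buckets"
  out
}

#' Number of tests after independent filtering for one bucket
#'
#' Counts the genes whose mean baseline expression is at least the minimum
#' mean within the bucket - the multiple-testing family when testing is
#' restricted to genes detectable at that expression level.
#'
#' @param buckets A \code{gene_buckets} object.
#' @param bucket Bucket index (1 = lowest expression).
#' @return Integer \code{m_b <= m_all}.
#' @export
filtered_test_count <- function(buckets, bucket) {
  sum(buckets$gene_means >= buckets$min_mean[bucket])
}

#' Simulate loss of expression in a treatment population
#'
#' Draws \code{n_treat} cells with replacement from the control values of one
#' gene, then independently marks each cell as biallelic loss with probability
#' \code{f_full} (expression set to zero) or monoallelic loss with probability
#' \code{f_mono} (expression halved), leaving the rest unchanged.
#'
#' @param control_values Per-cell expression of one gene in the control
#'   population.
#' @param n_treat Number of treatment cells to simulate.
#' @param f_mono,f_full Monoallelic and biallelic loss fractions;
#'   \code{f_mono + f_full <= 1}.
#' @return Numeric vector of \code{n_treat} simulated treatment values.
#' @export
simulate_loss <- function(control_values, n_treat, f_mono, f_full) {
  check_loss(f_mono, f_full)
  if (n_treat < 1) stop("n_treat must be >= 1")
  vals <- sample(control_values, n_treat, replace = TRUE)
  u <- stats::runif(n_treat)
  vals[u < f_full] <- 0
  mono <- u >= f_full & u < f_full + f_mono
  vals[mono] <- vals[mono] * 0.5
  vals
}

#' @noRd
check_loss <- function(f_mono, f_full) {
  if (f_mono < 0 || f_full < 0 || f_mono + f_full > 1) {
    stop("loss fractions must be nonnegative with f_mono + f_full <= 1")
  }
}

# Deterministic substream seed per (bucket, rep); the same master seed gives
# the same gene draw, cell resample and loss-label uniforms regardless of the
# loss fractions or treatment grid, so runs share common random numbers.
#' @noRd
derive_seed <- function(seed, bucket, rep) {
  (as.numeric(seed) * 100003 + bucket * 131071 + rep * 257) %% 2147483587 + 1
}

#' Simulation-based power grid
#'
#' For each bucket and replicate, draws one gene uniformly from the bucket,
#' simulates a treatment population of each size in \code{n_treat_grid} under
#' the given loss fractions ([simulate_loss()]), and tests it against the full
#' control population for that gene with a two-sided Wilcoxon rank-sum test.
#' Replicate p-values are summarized (median by default) and adjusted by
#' Bonferroni over all genes (\code{m_all}) and over the independently
#' filtered family (\code{m_b}, genes with mean baseline expression at least
#' the bucket's minimum).
#'
#' Substream seeds are derived per (bucket, replicate), and each replicate's
#' resampled cells and loss labels for a smaller \code{n_treat} are a prefix
#' of those for a larger one, so grids for different treatment sizes or loss
#' fractions share common random numbers.
#'
#' @param control cells x genes log-normalized control matrix.
#' @param f_mono,f_full Loss fractions (see [simulate_loss()]).
#' @param n_treat_grid Increasing vector of treatment-cell counts (each >= 3).
#' @param n_buckets,bucket_mode Passed to [bucket_genes()].
#' @param reps Replicates per (bucket, n_treat) cell (default 100).
#' @param seed Master seed.
#' @param summary Replicate summary: \code{"median"} (default), \code{"mean"},
#'   or \code{"reject"} (fraction of replicates with p < \code{alpha}).
#' @param alpha Rejection level used by the \code{"reject"} summary.
#' @return An object of class \code{power_grid}: \code{grid} (long data.frame
#'   with bucket, bucket_lo, bucket_hi, n_treat, p_raw, p_adj_all,
#'   p_adj_filtered, m_b, m_all), \code{reps} (replicate-level p-values),
#'   \code{buckets}, and the call parameters.
#' @export
power_curve <- function(control, f_mono, f_full, n_treat_grid,
                        n_buckets = 10, reps = 100, seed = 1,
                        bucket_mode = "quantile",
                        summary = c("median", "mean", "reject"),
                        alpha = 0.05) {
  summary <- match.arg(summary)
  check_loss(f_mono, f_full)
  if (any(n_treat_grid < 3)) stop("all treatment sizes must be >= 3")
  n_treat_grid <- sort(unique(n_treat_grid))
  buckets <- bucket_genes(control, n_buckets, bucket_mode)
  nb <- length(buckets$buckets)
  max_n <- max(n_treat_grid)
  n_ctrl <- nrow(control)
  rep_rows <- vector("list", nb * reps)
  idx <- 1L
  for (b in seq_len(nb)) {
    members <- buckets$buckets[[b]]
    for (r in seq_len(reps)) {
      withr_seed(derive_seed(seed, b, r), {
        gene <- members[sample.int(length(members), 1)]
        cells <- sample.int(n_ctrl, max_n, replace = TRUE)
        u <- stats::runif(max_n)
      })
      ctrl_vals <- as.numeric(control[, gene])
      p <- vapply(n_treat_grid, function(nt) {
        vals <- ctrl_vals[cells[seq_len(nt)]]
        ui <- u[seq_len(nt)]
        vals[ui < f_full] <- 0
        mono <- ui >= f_full & ui < f_full + f_mono
        vals[mono] <- vals[mono] * 0.5
        if (all(vals == 0) && all(ctrl_vals == 0)) return(1)  # flagged: no expression
        wilcoxon_p(vals, ctrl_vals)
      }, numeric(1))
      rep_rows[[idx]] <- data.frame(bucket = b, rep = r, gene = gene,
                                    n_treat = n_treat_grid, p = p)
      idx <- idx + 1L
    }
  }
  rep_df <- do.call(rbind, rep_rows)
  summarize <- switch(summary,
    median = function(p) stats::median(p),
    mean = function(p) mean(p),
    reject = function(p) mean(p < alpha))
  agg <- stats::aggregate(p ~ bucket + n_treat, rep_df, summarize)
  m_b <- vapply(seq_len(nb), function(b) filtered_test_count(buckets, b),
                numeric(1))
  grid <- data.frame(
    bucket = agg$bucket,
    bucket_lo = buckets$ranges[agg$bucket, 1],
    bucket_hi = buckets$ranges[agg$bucket, 2],
    n_treat = agg$n_treat,
    p_raw = agg$p,
    p_adj_all = pmin(1, agg$p * buckets$m_all),
    p_adj_filtered = pmin(1, agg$p * m_b[agg$bucket]),
    m_b = m_b[agg$bucket],
    m_all = buckets$m_all)
  grid <- grid[order(grid$bucket, grid$n_treat), ]
  rownames(grid) <- NULL
  out <- list(grid = grid, reps = rep_df, buckets = buckets,
              f_mono = f_mono, f_full = f_full, reps_n = reps,
              summary = summary, seed = seed)
  class(out) <- "power_grid"
  out
}

#' @export
print.power_grid <- function(x, ...) {
  cat("Power grid: ", length(x$buckets$buckets), " buckets x ",
      length(unique(x$grid$n_treat)), " treatment sizes, ",
      x$reps_n, " reps (loss mono = ", x$f_mono, ", full = ", x$f_full,
      ")\n", sep = "")
  print(utils::head(x$grid, 10))
  invisible(x)
}

#' Minimum treatment cells required for detection
#'
#' The smallest treatment-cell count on the grid whose summarized p-value is
#' below \code{alpha}, per bucket; NA when no grid size achieves detection.
#'
#' @param grid A \code{power_grid} from [power_curve()].
#' @param alpha Significance level (default 0.05).
#' @param which Which p-value to threshold: \code{"filtered"},
#'   \code{"all"}, or \code{"raw"}.
#' @return data.frame with \code{bucket} and \code{min_cells} (NA if never
#'   significant).
#' @export
min_cells_required <- function(grid, alpha = 0.05,
                               which = c("filtered", "all", "raw")) {
  which <- match.arg(which)
  col <- switch(which, filtered = "p_adj_filtered", all = "p_adj_all",
                raw = "p_raw")
  df <- grid$grid
  res <- vapply(sort(unique(df$bucket)), function(b) {
    sub <- df[df$bucket == b, ]
    hit <- sub$n_treat[sub[[col]] < alpha]
    if (length(hit) == 0) NA_real_ else min(hit)
  }, numeric(1))
  data.frame(bucket = sort(unique(df$bucket)), min_cells = res)
}
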