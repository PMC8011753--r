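# Differential expression: per-gene two-sided Wilcoxon rank-sum tests of a
# guide-bearing population against control, Bonferroni adjustment, and the
# cross-guide consistency rule.

#' Two-sided Wilcoxon rank-sum test, matching the package's DE policy
#'
#' Exact enumeration when both groups have at most 8 observations and the
#' pooled values are tie-free; otherwise the normal approximation with tie and
#' continuity corrections. The boundary sits at 8 because the worst-case
#' approximation error there (~0.011) still matters at screen-level
#' significance thresholds, while above it the approximation error is
#' negligible relative to Monte-Carlo noise.
#'
#' @param x,y Numeric vectors (treatment, control).
#' @return Two-sided p-value.
#' @export
wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)  # no signal, degenerate variance
  use_exact <- length(x) <= 8 && length(y) <= 8 &&
    !any(duplicated(pooled))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)$p.value)
}

#' Per-gene Wilcoxon differential expression
#'
#' Tests each gene's log-normalized expression in the treatment cells against
#' the control cells with a two-sided Wilcoxon rank-sum test. Genes expressed
#' in neither group are marked untested. Direction is the sign of the
#' treatment-minus-control mean shift.
#'
#' @param treatment,control cells x genes matrices of normalized expression
#'   sharing the same gene columns.
#' @param m Number of tests for Bonferroni adjustment; defaults to the number
#'   of genes in the matrix (untested genes included).
#' @return data.frame with \code{gene}, \code{p_value}, \code{p_adjusted},
#'   \code{direction} (-1, 0, 1), \code{n_treatment}, \code{n_control},
#'   \code{tested}.
#' @export
wilcoxon_de <- function(treatment, control, m = ncol(control)) {
  if (nrow(treatment) == 0 || nrow(control) == 0) stop("empty group")
  if (nrow(treatment) < 3 || nrow(control) < 3) {
    stop("both groups need at least 3 cells")
  }
  if (!identical(colnames(treatment), colnames(control))) {
    stop("treatment and control must share the same gene columns")
  }
  genes <- colnames(control)
  p <- rep(NA_real_, length(genes))
  direction <- rep(0L, length(genes))
  tested <- rep(FALSE, length(genes))
  for (j in seq_along(genes)) {
    x <- as.numeric(treatment[, j])
    y <- as.numeric(control[, j])
    if (all(x == 0) && all(y == 0)) next
    tested[j] <- TRUE
    p[j] <- wilcoxon_p(x, y)
    direction[j] <- sign(mean(x) - mean(y))
  }
  data.frame(gene = genes, p_value = p,
             p_adjusted = ifelse(tested, bonferroni_adjust(p, m), NA_real_),
             direction = direction,
             n_treatment = nrow(treatment), n_control = nrow(control),
             tested = tested, row.names = NULL, stringsAsFactors = FALSE)
}

#' Bonferroni adjustment for m tests
#'
#' @param pvals Raw p-values (NAs pass through).
#' @param m Number of tests in the family.
#' @return \code{pmin(1, pvals * m)}.
#' @export
bonferroni_adjust <- function(pvals, m) {
  if (m <= 0) stop("m must be positive")
  pmin(1, pvals * m)
}

#' Consistently differentially expressed genes across guide populations
#'
#' A gene is consistently differentially expressed when it is significant
#' (adjusted p <= alpha) in every population receiving a guide targeting the
#' same gene's regulatory regions - by default with the same direction of
#' change in each.
#'
#' @param results_per_guide List of DE tables from [wilcoxon_de()], one per
#'   guide population (>= 2).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param require_direction Require the direction of change to agree across
#'   populations (default TRUE).
#' @return Character vector of consistently differentially expressed genes.
#' @export
consistent_de <- function(results_per_guide, alpha = 0.05,
                          require_direction = TRUE) {
  if (length(results_per_guide) < 2) stop("need at least 2 guide populations")
  sig_sets <- lapply(results_per_guide, function(res) {
    res[res$tested & !is.na(res$p_adjusted) & res$p_adjusted <= alpha,
        c("gene", "direction")]
  })
  genes <- Reduce(intersect, lapply(sig_sets, `[[`, "gene"))
  if (require_direction && length(genes) > 0) {
    agree <- vapply(genes, function(g) {
      dirs <- vapply(sig_sets, function(s) s$direction[s$gene == g][1], 0)
      length(unique(dirs)) == 1 && dirs[1] != 0
    }, logical(1))
    genes <- genes[agree]
  }
  genes
}
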