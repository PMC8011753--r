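# Transcriptome quality control: barcode-rank knee filtering, 3-MAD outlier
# removal on per-cell QC metrics, and log-normalization of UMI counts.

#' Barcode-rank knee filter for high-quality transcriptomes
#'
#' Retains all top barcodes with UMI counts within the same order of
#' magnitude: with \code{n = ceiling(0.01 * expected_cells)}, the threshold is
#' 10\% of the n-th ranked barcode's total, and barcodes with totals strictly
#' above it are kept.
#'
#' @param total_counts Named numeric vector of per-barcode total UMI counts.
#' @param expected_cells Expected recovered cell count (>= 100 so n >= 1).
#' @return Character vector of retained barcode names.
#' @export
knee_filter <- function(total_counts, expected_cells) {
  if (is.null(names(total_counts))) stop("total_counts must be named by barcode")
  if (expected_cells < 100) stop("expected_cells must be >= 100")
  n <- ceiling(0.01 * expected_cells)
  if (length(total_counts) < n) {
    stop("fewer barcodes (", length(total_counts), ") than rank n = ", n)
  }
  nth <- sort(total_counts, decreasing = TRUE)[n]
  threshold <- 0.1 * nth
  names(total_counts)[total_counts > threshold]
}

#' Per-cell QC metrics
#'
#' @param counts cells x genes raw UMI matrix.
#' @param mito_prefix Feature-name prefix identifying mitochondrial genes
#'   (default \code{"mt-"}, the mouse convention); matched case-insensitively.
#' @return data.frame with \code{cell}, \code{total_umis}, \code{genes
#'   detected}, \code{mito_fraction}.
#' @export
qc_metrics <- function(counts, mito_prefix = "mt-") {
  total <- Matrix::rowSums(counts)
  genes <- Matrix::rowSums(counts > 0)
  is_mito <- startsWith(tolower(colnames(counts)), tolower(mito_prefix))
  mito <- if (any(is_mito)) {
    Matrix::rowSums(counts[, is_mito, drop = FALSE])
  } else rep(0, nrow(counts))
  data.frame(cell = rownames(counts), total_umis = total,
             genes_detected = as.integer(genes),
             mito_fraction = ifelse(total > 0, mito / total, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove cells that are outliers on QC metrics
#'
#' A cell is an outlier if its mitochondrial fraction exceeds the median by
#' more than \code{n_mads} median absolute deviations (high side), or if its
#' log total UMI count or log genes detected falls more than \code{n_mads}
#' MADs below the median (low side). MADs are scaled by 1.4826 for consistency
#' with the normal distribution. A metric whose MAD is zero filters nothing
#' (with a warning).
#'
#' @param metrics QC metrics from [qc_metrics()].
#' @param n_mads Number of MADs defining an outlier (default 3).
#' @return Character vector of retained cell barcodes.
#' @export
mad_outlier_filter <- function(metrics, n_mads = 3) {
  if (nrow(metrics) < 10) stop("need at least 10 cells for MAD filtering")
  flag <- function(x, side) {
    med <- stats::median(x)
    madv <- stats::mad(x)  # constant = 1.4826
    if (madv == 0) {
      warning("MAD is zero for a QC metric; it filters nothing")
      return(rep(FALSE, length(x)))
    }
    if (side == "high") x > med + n_mads * madv else x < med - n_mads * madv
  }
  out <- flag(metrics$mito_fraction, "high") |
    flag(log(metrics$total_umis), "low") |
    flag(log(metrics$genes_detected), "low")
  metrics$cell[!out]
}

#' Log-normalize a UMI count matrix
#'
#' Per-cell depth normalization followed by a log transform:
#' \code{value = ln(1 + raw * scale_factor / cell_total)} (the default
#' normalization of standard scRNA-seq toolkits).
#'
#' @param raw cells x genes raw UMI matrix; every cell total must be > 0.
#' @param scale_factor Scale applied before log1p (default 1e4).
#' @return Sparse cells x genes matrix of log-normalized values. Attributes
#'   \code{scale_factor} records the scale used.
#' @export
lognormalize <- function(raw, scale_factor = 1e4) {
  totals <- Matrix::rowSums(raw)
  if (any(totals <= 0)) {
    stop("cells with zero total counts present; remove them with QC first")
  }
  norm <- Matrix::Diagonal(x = scale_factor / totals) %*% raw
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(raw)
  attr(norm, "scale_factor") <- scale_factor
  norm
}
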