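# Guide quantification: local alignment of gRNA-library reads against the
# known guide panel, followed by UMI collapse to a cells x guides count matrix.

#' Default alignment parameters
#'
#' Smith-Waterman local alignment with affine gaps: match +1, mismatch -1,
#' gap open -2, gap extend -1. A hit requires score >= \code{min_score} and at
#' least \code{min_spacer_overlap} aligned guide positions inside the spacer,
#' so reads matching only the shared scaffold are rejected.
#'
#' @param match,mismatch,gap_open,gap_extend Alignment scores (gap penalties
#'   given as positive costs).
#' @param min_score Minimum alignment score for a hit.
#' @param min_spacer_overlap Minimum aligned guide bases inside the spacer.
#' @return A list of parameters for [align_reads()].
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = 2,
                         gap_extend = 1, min_score = 15,
                         min_spacer_overlap = 15) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, min_score = min_score,
       min_spacer_overlap = min_spacer_overlap)
}

# Substitution matrix over ACGTN; N mismatches everything, itself included,
# so all-N reads score 0 and produce no hit.
#' @noRd
acgtn_matrix <- function(match, mismatch) {
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- match
  mat["N", ] <- mismatch
  mat[, "N"] <- mismatch
  mat
}

#' Align reads to the guide panel
#'
#' Each read is locally aligned against every guide's full sequence
#' (spacer + scaffold). The hit goes to the unique guide with the best score,
#' provided the score reaches \code{params$min_score} and the alignment covers
#' at least \code{params$min_spacer_overlap} guide positions within the
#' spacer; ties across guides are discarded as ambiguous.
#'
#' @param sequences Character vector of read sequences (ACGTN).
#' @param references Guide reference data.frame from [read_guide_reference()].
#' @param params Alignment parameters from [align_params()].
#' @return A data.frame with one row per read: \code{guide_id} (NA for no
#'   hit), \code{score}, \code{is_ambiguous}.
#' @export
align_reads <- function(sequences, references, params = align_params()) {
  if (nrow(references) == 0) stop("empty guide reference")
  n <- length(sequences)
  if (n == 0) {
    return(data.frame(guide_id = character(), score = numeric(),
                      is_ambiguous = logical(), stringsAsFactors = FALSE))
  }
  submat <- acgtn_matrix(params$match, params$mismatch)
  seqs <- toupper(sequences)
  seqs[!nzchar(seqs)] <- "N"  # placeholder so the aligner accepts it; scores 0
  reads <- Biostrings::DNAStringSet(seqs)
  n_guides <- nrow(references)
  scores <- matrix(-Inf, n, n_guides)
  spacer_cov <- matrix(0L, n, n_guides)
  for (g in seq_len(n_guides)) {
    aln <- Biostrings::pairwiseAlignment(
      reads, Biostrings::DNAString(references$full_sequence[g]),
      type = "local", substitutionMatrix = submat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    scores[, g] <- Biostrings::score(aln)
    sstart <- Biostrings::start(Biostrings::subject(aln))
    send <- Biostrings::end(Biostrings::subject(aln))
    sp_len <- nchar(references$spacer[g])
    spacer_cov[, g] <- pmax(0L, pmin(send, sp_len) - pmax(sstart, 1L) + 1L)
  }
  eligible <- scores >= params$min_score &
    spacer_cov >= params$min_spacer_overlap
  scores[!eligible] <- -Inf
  best <- max.col(scores, ties.method = "first")
  best_score <- scores[cbind(seq_len(n), best)]
  n_best <- rowSums(scores == best_score & is.finite(best_score))
  hit <- is.finite(best_score) & n_best == 1L
  ambiguous <- is.finite(best_score) & n_best > 1L
  data.frame(
    guide_id = ifelse(hit, references$guide_id[best], NA_character_),
    score = ifelse(is.finite(best_score), best_score, 0),
    is_ambiguous = ambiguous,
    stringsAsFactors = FALSE)
}

#' Collapse aligned reads to UMI-unique guide counts
#'
#' One count per distinct (cell barcode, UMI, guide) triple among uniquely
#' mapped reads; unmapped and ambiguous reads are discarded. If the same
#' (barcode, UMI) maps to two different guides in different reads, both
#' triples are kept - the downstream mixture model absorbs such noise.
#'
#' @param hits Alignment table from [align_reads()], row-aligned to
#'   \code{reads}.
#' @param reads Tagged reads from [read_tagged_fastq()].
#' @param guide_ids Full guide panel (columns of the output; defaults to the
#'   guides observed in \code{hits}).
#' @param valid_barcodes Optional barcode whitelist; other barcodes dropped.
#' @return Sparse cells x guides matrix of UMI-unique counts. The attribute
#'   \code{n_per_cell} gives each cell's total guide UMI count (row sums).
#' @export
count_umis <- function(hits, reads, guide_ids = NULL, valid_barcodes = NULL) {
  if (nrow(hits) != nrow(reads)) stop("hits and reads are not row-aligned")
  keep <- !is.na(hits$guide_id)
  bc <- reads$cell_barcode[keep]
  umi <- reads$umi[keep]
  gid <- hits$guide_id[keep]
  if (!is.null(valid_barcodes)) {
    ok <- bc %in% valid_barcodes
    bc <- bc[ok]; umi <- umi[ok]; gid <- gid[ok]
  }
  if (is.null(guide_ids)) guide_ids <- sort(unique(gid))
  triple <- !duplicated(paste(bc, umi, gid, sep = "\r"))
  bc <- bc[triple]; gid <- gid[triple]
  cells <- sort(unique(bc))
  mat <- Matrix::sparseMatrix(
    i = match(bc, cells), j = match(gid, guide_ids),
    x = rep(1, length(bc)), dims = c(length(cells), length(guide_ids)),
    dimnames = list(cells, guide_ids))
  mat <- methods::as(mat, "CsparseMatrix")
  attr(mat, "n_per_cell") <- Matrix::rowSums(mat)
  mat
}

#' Quantify a gRNA-enriched library end to end
#'
#' Convenience wrapper: read tagged FASTQs, align read 2 against the guide
#' panel, and collapse to UMI-unique counts.
#'
#' @inheritParams read_tagged_fastq
#' @inheritParams align_reads
#' @inheritParams count_umis
#' @return As [count_umis()], plus a \code{mapping_summary} attribute
#'   (per-guide mapped read counts and unmapped/ambiguous totals).
#' @export
quantify_guides <- function(r1, r2, references, barcode_len, umi_len,
                            params = align_params(), valid_barcodes = NULL) {
  reads <- read_tagged_fastq(r1, r2, barcode_len, umi_len)
  hits <- align_reads(reads$sequence, references, params)
  counts <- count_umis(hits, reads, guide_ids = references$guide_id,
                       valid_barcodes = valid_barcodes)
  mapped <- table(factor(hits$guide_id, levels = references$guide_id))
  attr(counts, "mapping_summary") <- data.frame(
    guide_id = c(references$guide_id, "<unmapped>", "<ambiguous>"),
    n_reads = c(as.integer(mapped),
                sum(is.na(hits$guide_id) & !hits$is_ambiguous),
                sum(hits$is_ambiguous)),
    stringsAsFactors = FALSE)
  counts
}
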