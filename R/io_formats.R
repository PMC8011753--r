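# Readers/writers for the formats the pipeline touches: guide reference
# tables, 10x-style MatrixMarket triplets, and paired gRNA-library FASTQs.
# All text readers accept gzip-compressed files transparently.

#' Open a text connection, decompressing gzip transparently
#' @noRd
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a guide reference table
#'
#' Parses a delimited table of known gRNAs. The table must have a header with
#' columns \code{guide_id}, \code{spacer} and \code{scaffold}; the scaffold is
#' the invariant hairpin sequence shared by guides (it may be a single value
#' repeated, or vary per guide). The full guide sequence used for alignment is
#' \code{spacer} followed by \code{scaffold}.
#'
#' @param path Path to a TSV/CSV file (gzip accepted). The delimiter is
#'   detected from the extension (".csv" means comma, otherwise tab).
#' @return A data.frame with columns \code{guide_id}, \code{spacer},
#'   \code{scaffold}, \code{full_sequence}.
#' @export
read_guide_reference <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  con <- open_text(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  required <- c("guide_id", "spacer", "scaffold")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("guide reference is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$guide_id)) {
    dup <- unique(df$guide_id[duplicated(df$guide_id)])
    stop("duplicate guide_id in reference: ", paste(dup, collapse = ", "))
  }
  seqs <- paste0(df$spacer, df$scaffold)
  bad <- grepl("[^ACGTN]", toupper(seqs))
  if (any(bad)) {
    stop("non-ACGTN characters in guide sequence at row(s): ",
         paste(which(bad), collapse = ", "))
  }
  df$spacer <- toupper(df$spacer)
  df$scaffold <- toupper(df$scaffold)
  df$full_sequence <- paste0(df$spacer, df$scaffold)
  df[, c("guide_id", "spacer", "scaffold", "full_sequence")]
}

#' Read a 10x-style MatrixMarket triplet directory
#'
#' Reads \code{matrix.mtx}, \code{barcodes.tsv} and \code{features.tsv}
#' (gzipped variants accepted). On disk the matrix follows the droplet
#' convention of features x barcodes; the returned matrix is oriented
#' cells x features.
#'
#' @param dir Directory containing the three files, or a named list/character
#'   vector with elements \code{matrix}, \code{barcodes}, \code{features}.
#' @return A sparse \code{dgCMatrix}, cells in rows (named by barcode),
#'   features in columns (named by feature id).
#' @export
read_mtx_triplet <- function(dir) {
  paths <- resolve_triplet_paths(dir)
  m <- Matrix::readMM(if (grepl("\\.gz$", paths$matrix))
    gzfile(paths$matrix) else paths$matrix)
  if (any(m@x != round(m@x))) stop("matrix contains non-integer entries")
  if (any(m@x < 0)) stop("matrix contains negative entries")
  barcodes <- readLines(bc <- open_text(paths$barcodes)); close(bc)
  feats_con <- open_text(paths$features)
  features <- utils::read.table(feats_con, header = FALSE, sep = "\t",
                                stringsAsFactors = FALSE)[[1]]
  close(feats_con)
  if (nrow(m) != length(features)) {
    stop("features file has ", length(features), " lines but matrix declares ",
         nrow(m), " rows")
  }
  if (ncol(m) != length(barcodes)) {
    stop("barcodes file has ", length(barcodes), " lines but matrix declares ",
         ncol(m), " columns")
  }
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in barcodes file")
  out <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(out) <- list(barcodes, features)
  out
}

#' Write a cells x features matrix as a 10x-style MTX triplet
#'
#' Inverse of [read_mtx_triplet()]: writes \code{matrix.mtx} (features x
#' barcodes, 1-based coordinates), \code{barcodes.tsv} and \code{features.tsv}
#' into \code{dir}.
#'
#' @param mat cells x features matrix with dimnames (barcodes, features).
#' @param dir Output directory, created if absent.
#' @return \code{dir}, invisibly.
#' @export
write_mtx_triplet <- function(mat, dir) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("matrix must have barcode rownames and feature colnames")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::t(Matrix::Matrix(mat, sparse = TRUE)), "TsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(mat), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(mat), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' @noRd
resolve_triplet_paths <- function(dir) {
  if (is.list(dir) || (is.character(dir) && !is.null(names(dir)))) {
    need <- c("matrix", "barcodes", "features")
    if (!all(need %in% names(dir))) {
      stop("named input must give matrix, barcodes and features paths")
    }
    return(as.list(dir)[need])
  }
  find1 <- function(stub) {
    for (cand in c(stub, paste0(stub, ".gz"))) {
      p <- file.path(dir, cand)
      if (file.exists(p)) return(p)
    }
    stop("cannot find ", stub, "[.gz] in ", dir)
  }
  list(matrix = find1("matrix.mtx"),
       barcodes = find1("barcodes.tsv"),
       features = find1("features.tsv"))
}

#' Read paired gRNA-library FASTQs into tagged reads
#'
#' Read 1 carries the cell barcode followed by the UMI; read 2 carries the
#' gRNA-derived sequence. Records are paired positionally. Read-1 records
#' shorter than \code{barcode_len + umi_len} are skipped (with their mates)
#' and counted in the \code{n_skipped} attribute.
#'
#' @param r1,r2 Paths to the paired FASTQ files (gzip accepted).
#' @param barcode_len,umi_len Fixed barcode and UMI lengths in read 1.
#' @return A data.frame with columns \code{read_id}, \code{cell_barcode},
#'   \code{umi}, \code{sequence}; attribute \code{n_skipped} gives the number
#'   of pairs dropped for short read 1.
#' @export
read_tagged_fastq <- function(r1, r2, barcode_len, umi_len) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(s1) != length(s2)) {
    stop("unpaired FASTQ files: read 1 has ", length(s1),
         " records, read 2 has ", length(s2))
  }
  if (length(s1) == 0) {
    out <- data.frame(read_id = character(), cell_barcode = character(),
                      umi = character(), sequence = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  tag_len <- barcode_len + umi_len
  keep <- Biostrings::width(s1) >= tag_len
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " read pair(s) skipped: read 1 shorter than ", tag_len)
  }
  s1 <- s1[keep]; s2 <- s2[keep]
  r1chr <- as.character(s1)
  out <- data.frame(
    read_id = sub("\\s.*$", "", names(s1)),
    cell_barcode = substr(r1chr, 1L, barcode_len),
    umi = substr(r1chr, barcode_len + 1L, tag_len),
    sequence = as.character(s2),
    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a data.frame as a TSV, with an optional comment header
#' @noRd
write_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
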