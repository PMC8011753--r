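# Synthetic-data generators: droplet-like UMI count matrices (overdispersed
# counts, library-size variation, mitochondrial genes), guide count matrices
# with ground-truth labels, perturbed populations with known loss fractions,
# ambient barcode distributions, and paired gRNA-library FASTQ files. Every
# generator is a pure function of its configuration and seed.

#' Simulation configuration
#'
#' Defaults emulate a modest droplet scRNA-seq run: 2000 cells, 1000 genes
#' with mean expression log-spaced over more than three orders of magnitude
#' (so all ten expression buckets populate), negative-binomial counts with
#' log-normal library-size factors scaled to a median of ~4000 UMIs per cell,
#' ten mitochondrial genes at ~5\% of counts, and a ten-guide panel in which
#' a cell's own guide captures ~95\% of its guide UMIs (~150 per cell) while
#' each other guide picks up ~0.5\% noise.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param mean_log10_range log10 range of gene mean expression (before depth
#'   scaling).
#' @param dispersion Negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); 0 gives Poisson counts.
#' @param depth_sdlog Log-normal sd of per-cell library-size factors.
#' @param target_median_umis Median per-cell total UMIs after scaling.
#' @param n_mito,mito_fraction Number of mitochondrial genes (named with the
#'   \code{mt-} prefix) and their expected share of counts.
#' @param n_guides Guide panel size.
#' @param guide_total_mean Mean total guide UMIs per cell.
#' @param p_noise,p_signal,pi_signal Generating mixture truth per guide.
#' @param f_mono,f_full Loss fractions for perturbed populations.
#' @param barcode_len,umi_len Barcode and UMI lengths for read generation.
#' @param seed Mandatory seed.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_cells = 2000, n_genes = 1000,
                       mean_log10_range = c(-2, 1.2), dispersion = 0.3,
                       depth_sdlog = 0.35, target_median_umis = 4000,
                       n_mito = 10, mito_fraction = 0.05,
                       n_guides = 10, guide_total_mean = 150,
                       p_noise = 0.005, p_signal = 0.95, pi_signal = 0.1,
                       f_mono = 0.25, f_full = 0.05,
                       barcode_len = 16, umi_len = 10, seed = 1L) {
  stopifnot(n_cells > 0, n_genes > 0, dispersion >= 0,
            mito_fraction >= 0, mito_fraction < 1,
            p_noise >= 0, p_signal <= 1,
            f_mono >= 0, f_full >= 0, f_mono + f_full <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' @noRd
rnb <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' @noRd
random_barcodes <- function(n, len) {
  bc <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- vapply(dup, function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))
  }
  bc
}

#' Generate a control expression matrix
#'
#' Negative-binomial UMI counts with per-cell log-normal depth factors and
#' log-spaced gene means: \code{counts_ij ~ NB(depth_i * mu_j, dispersion)}.
#' Mitochondrial genes (prefix \code{mt-}) are appended with means set so
#' their expected share of counts is \code{cfg$mito_fraction}.
#'
#' @param cfg A [sim_config()].
#' @return Sparse cells x genes integer matrix with barcode rownames and gene
#'   colnames; attributes \code{true_means} (per-gene mu) and \code{depth}
#'   (per-cell factor).
#' @export
make_control_matrix <- function(cfg) {
  withr_seed(cfg$seed, {
    n_main <- cfg$n_genes - cfg$n_mito
    if (n_main < 1) stop("n_genes must exceed n_mito")
    mu <- 10^seq(cfg$mean_log10_range[1], cfg$mean_log10_range[2],
                 length.out = n_main)
    mu <- mu * cfg$target_median_umis * (1 - cfg$mito_fraction) / sum(mu)
    mu_mito <- if (cfg$n_mito > 0) {
      rep(cfg$target_median_umis * cfg$mito_fraction / cfg$n_mito, cfg$n_mito)
    } else numeric(0)
    mu_all <- c(mu, mu_mito)
    genes <- c(sprintf("gene%04d", seq_len(n_main)),
               if (cfg$n_mito > 0) sprintf("mt-gene%02d", seq_len(cfg$n_mito)))
    depth <- stats::rlnorm(cfg$n_cells, meanlog = 0, sdlog = cfg$depth_sdlog)
    counts <- matrix(0L, cfg$n_cells, cfg$n_genes)
    for (j in seq_len(cfg$n_genes)) {
      counts[, j] <- rnb(cfg$n_cells, depth * mu_all[j], cfg$dispersion)
    }
    barcodes <- random_barcodes(cfg$n_cells, cfg$barcode_len)
    out <- Matrix::Matrix(counts, sparse = TRUE,
                          dimnames = list(barcodes, genes))
    attr(out, "true_means") <- stats::setNames(mu_all, genes)
    attr(out, "depth") <- stats::setNames(depth, barcodes)
    out
  })
}

#' Sample counts from the two-component binomial guide mixture
#'
#' Draws one guide's per-cell counts directly from the generating model:
#' totals \code{n_i} are negative-binomial around \code{total_mean}, signal
#' membership \code{z_i ~ Bernoulli(pi_signal)}, and counts
#' \code{k_i ~ Binomial(n_i, p_signal)} for signal cells or
#' \code{Binomial(n_i, p_noise)} for noise cells.
#'
#' @param n_cells Number of cells.
#' @param total_mean Mean total guide UMI count per cell.
#' @param p_noise,p_signal,pi_signal Generating mixture parameters.
#' @param seed Seed.
#' @return A list with \code{k}, \code{n}, and the true labels \code{z}
#'   (logical, TRUE = signal).
#' @export
sim_mixture_counts <- function(n_cells, total_mean, p_noise, p_signal,
                               pi_signal, seed) {
  if (p_signal <= p_noise) stop("p_signal must exceed p_noise")
  withr_seed(seed, {
    n <- pmax(1L, stats::rnbinom(n_cells, mu = total_mean, size = 20))
    z <- stats::runif(n_cells) < pi_signal
    k <- ifelse(z, stats::rbinom(n_cells, n, p_signal),
                stats::rbinom(n_cells, n, p_noise))
    list(k = k, n = n, z = z)
  })
}

#' Generate a guide count matrix with ground truth
#'
#' Each cell carries one true guide. The true guide's count is
#' \code{Binomial(n_i, p_signal)} on the cell's total budget \code{n_i}; every
#' other guide picks up \code{Binomial(n_i, p_noise)} noise counts, so each
#' guide's marginal across cells follows the two-component binomial mixture.
#'
#' @param cfg A [sim_config()].
#' @param truth_labels Integer vector (one per cell) of true guide indices in
#'   \code{1..cfg$n_guides}, optionally named by barcode; default assigns
#'   cells to guides in balanced round-robin order.
#' @param barcodes Cell barcodes (generated if NULL).
#' @return Sparse cells x guides count matrix; attribute \code{truth} is a
#'   data.frame of per-cell true labels, and \code{params} records the
#'   generating mixture values.
#' @export
make_guide_counts <- function(cfg, truth_labels = NULL, barcodes = NULL) {
  if (cfg$p_signal <= cfg$p_noise) stop("p_signal must exceed p_noise")
  withr_seed(cfg$seed + 1L, {
    if (is.null(truth_labels)) {
      truth_labels <- rep_len(seq_len(cfg$n_guides), cfg$n_cells)
    }
    n_cells <- length(truth_labels)
    if (is.null(barcodes)) {
      barcodes <- if (!is.null(names(truth_labels))) names(truth_labels)
      else random_barcodes(n_cells, cfg$barcode_len)
    }
    guides <- sprintf("guide%02d", seq_len(cfg$n_guides))
    n_i <- pmax(1L, stats::rnbinom(n_cells, mu = cfg$guide_total_mean,
                                   size = 20))
    counts <- matrix(0L, n_cells, cfg$n_guides,
                     dimnames = list(barcodes, guides))
    for (g in seq_len(cfg$n_guides)) {
      own <- truth_labels == g
      counts[own, g] <- stats::rbinom(sum(own), n_i[own], cfg$p_signal)
      counts[!own, g] <- stats::rbinom(sum(!own), n_i[!own], cfg$p_noise)
    }
    out <- Matrix::Matrix(counts, sparse = TRUE)
    attr(out, "truth") <- data.frame(cell = barcodes,
                                     true_guide = guides[truth_labels],
                                     stringsAsFactors = FALSE)
    attr(out, "params") <- c(p_noise = cfg$p_noise, p_signal = cfg$p_signal)
    out
  })
}

#' Perturb a control population at one target gene
#'
#' Samples a loss state per cell (biallelic with probability \code{f_full},
#' monoallelic with \code{f_mono}), then zeroes the target gene's raw counts
#' for biallelic cells and halves them by binomial thinning for monoallelic
#' cells. All other genes are untouched.
#'
#' @param control cells x genes raw count matrix.
#' @param target_gene Gene (column) name to perturb.
#' @param f_mono,f_full Loss fractions.
#' @param seed Seed.
#' @return The perturbed matrix; attribute \code{loss_state} is a per-cell
#'   factor in \code{none}, \code{mono}, \code{bi}.
#' @export
make_perturbed_population <- function(control, target_gene, f_mono, f_full,
                                      seed) {
  check_loss(f_mono, f_full)
  if (!target_gene %in% colnames(control)) {
    stop("target gene not in matrix: ", target_gene)
  }
  withr_seed(seed, {
    n <- nrow(control)
    u <- stats::runif(n)
    state <- ifelse(u < f_full, "bi", ifelse(u < f_full + f_mono, "mono",
                                             "none"))
    out <- control
    tg <- as.numeric(out[, target_gene])
    tg[state == "bi"] <- 0
    mono <- state == "mono"
    tg[mono] <- stats::rbinom(sum(mono), tg[mono], 0.5)
    out[, target_gene] <- tg
    attr(out, "loss_state") <- factor(stats::setNames(state, rownames(control)),
                                      levels = c("none", "mono", "bi"))
    out
  })
}

#' Generate a barcode total-count distribution with an ambient tail
#'
#' Real cell barcodes draw log-normal totals around \code{real_meanlog};
#' ambient barcodes draw heavy-tailed negative-binomial totals at about 0.5\%
#' of the real scale, producing the knee that barcode-rank filtering exploits.
#'
#' @param n_real,n_ambient Numbers of real and ambient barcodes.
#' @param real_meanlog,real_sdlog Log-normal parameters for real totals.
#' @param ambient_mean Mean total for ambient barcodes.
#' @param seed Seed.
#' @return Named numeric vector of totals; attribute \code{is_real} flags the
#'   real barcodes.
#' @export
make_barcode_distribution <- function(n_real = 1000, n_ambient = 20000,
                                      real_meanlog = log(4000),
                                      real_sdlog = 0.3, ambient_mean = 20,
                                      seed = 1L) {
  withr_seed(seed, {
    real <- pmax(1, round(stats::rlnorm(n_real, real_meanlog, real_sdlog)))
    ambient <- stats::rnbinom(n_ambient, mu = ambient_mean, size = 1)
    totals <- c(real, ambient)
    names(totals) <- c(sprintf("real%05d", seq_len(n_real)),
                       if (n_ambient > 0) sprintf("amb%06d", seq_len(n_ambient)))
    attr(totals, "is_real") <- c(rep(TRUE, n_real), rep(FALSE, n_ambient))
    totals
  })
}

#' @noRd
int_to_dna <- function(i, len) {
  bases <- c("A", "C", "G", "T")
  out <- character(length(i))
  i <- i - 1
  for (pos in seq_len(len)) {
    out <- paste0(bases[i %% 4 + 1], out)
    i <- i %/% 4
  }
  out
}

#' Generate paired gRNA-library FASTQ files from a guide count matrix
#'
#' For every UMI-unique (cell, guide) molecule in \code{counts}, emits
#' \code{reads_per_umi} read pairs: read 1 is the cell barcode followed by the
#' UMI (UMIs are distinct within each cell-guide pair); read 2 is a prefix of
#' the guide's full sequence with independent per-base substitution errors at
#' rate \code{error_rate}. At error rate zero, quantifying these reads
#' reproduces \code{counts} exactly.
#'
#' @param counts cells x guides count matrix; rownames must be DNA barcodes.
#' @param references Guide reference data.frame ([read_guide_reference()]);
#'   guide ids must match the matrix columns.
#' @param r1_path,r2_path Output FASTQ paths.
#' @param umi_len UMI length (default 10).
#' @param read_len Read-2 length (default 50, truncated to the guide length).
#' @param reads_per_umi Read pairs emitted per molecule (default 2).
#' @param error_rate Per-base substitution rate on read 2 (default 0).
#' @param seed Seed.
#' @return Invisibly, c(r1_path, r2_path).
#' @export
make_guide_reads <- function(counts, references, r1_path, r2_path,
                             umi_len = 10, read_len = 50, reads_per_umi = 2,
                             error_rate = 0, seed = 1L) {
  if (!all(colnames(counts) %in% references$guide_id)) {
    stop("count matrix guides missing from the reference")
  }
  withr_seed(seed, {
    r1 <- character(0); r2 <- character(0)
    tm <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "TsparseMatrix")
    cells <- rownames(counts)[tm@i + 1L]
    guides <- colnames(counts)[tm@j + 1L]
    nz <- tm@x
    ord <- order(cells, guides)
    cells <- cells[ord]; guides <- guides[ord]; nz <- nz[ord]
    seqs <- stats::setNames(references$full_sequence, references$guide_id)
    for (e in seq_along(nz)) {
      c_umis <- int_to_dna(sample.int(4^umi_len, nz[e]), umi_len)
      tpl <- substr(seqs[[guides[e]]], 1, read_len)
      for (u in c_umis) {
        for (rep in seq_len(reads_per_umi)) {
          s2 <- tpl
          if (error_rate > 0) {
            ch <- strsplit(s2, "")[[1]]
            hit <- stats::runif(length(ch)) < error_rate
            if (any(hit)) {
              ch[hit] <- vapply(ch[hit], function(b)
                sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
              s2 <- paste(ch, collapse = "")
            }
          }
          r1 <- c(r1, paste0(cells[e], u))
          r2 <- c(r2, s2)
        }
      }
    }
    write_fastq <- function(seqs, path) {
      if (length(seqs) == 0) {
        writeLines(character(0), path)
        return(invisible(path))
      }
      ids <- sprintf("@read%06d", seq_along(seqs))
      writeLines(as.vector(rbind(ids, seqs, "+",
                                 vapply(nchar(seqs), function(w)
                                   strrep("I", w), character(1)))), path)
    }
    write_fastq(r1, r1_path)
    write_fastq(r2, r2_path)
  })
  invisible(c(r1_path, r2_path))
}

#' Generate a random guide reference panel
#'
#' Random distinct spacers over a shared scaffold - the panel structure of a
#' pooled screen with one guide per population.
#'
#' @param n_guides Panel size.
#' @param spacer_len Spacer length (default 20).
#' @param scaffold Shared scaffold sequence.
#' @param seed Seed.
#' @return Guide reference data.frame as from [read_guide_reference()].
#' @export
make_guide_reference <- function(n_guides = 10, spacer_len = 20,
                                 scaffold = "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGC",
                                 seed = 1L) {
  withr_seed(seed, {
    spacers <- random_barcodes(n_guides, spacer_len)
    data.frame(guide_id = sprintf("guide%02d", seq_len(n_guides)),
               spacer = spacers, scaffold = scaffold,
               full_sequence = paste0(spacers, scaffold),
               stringsAsFactors = FALSE)
  })
}
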