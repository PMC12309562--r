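#' Observed-over-expected normalization of intrachromosomal contacts
#'
#' Each intrachromosomal contact frequency is divided by the genome-wide
#' average contact frequency between loci at the same linear distance
#' (in bins, pooled over all chromosomes). chrT is excluded from this
#' analysis. Entries whose expected value is zero are flagged missing
#' (\code{NA}).
#'
#' @param cm A \code{contact_matrix}.
#' @return An \code{oe_matrices} object: list with \code{oe} (named list of
#'   dense per-chromosome matrices), \code{expected} (mean contact per
#'   distance, index d+1), and the \code{binning}.
#' @export
observed_over_expected <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  binning <- cm$binning
  chroms <- names(binning$chrom_sizes)
  dense <- lapply(chroms, function(ch) {
    idx <- which(binning$bins$chrom == ch)
    as.matrix(cm$weights[idx, idx, drop = FALSE])
  })
  names(dense) <- chroms
  maxd <- max(vapply(dense, nrow, integer(1L))) - 1L
  sums <- numeric(maxd + 1L)
  counts <- numeric(maxd + 1L)
  for (W in dense) {
    n <- nrow(W)
    for (d in 0:(n - 1L)) {
      diag_vals <- W[cbind(seq_len(n - d), seq_len(n - d) + d)]
      sums[d + 1L] <- sums[d + 1L] + sum(diag_vals)
      counts[d + 1L] <- counts[d + 1L] + (n - d)
    }
  }
  expected <- ifelse(counts > 0, sums / counts, NA_real_)
  oe <- lapply(dense, function(W) {
    n <- nrow(W)
    E <- expected[abs(outer(seq_len(n), seq_len(n), "-")) + 1L]
    dim(E) <- c(n, n)
    out <- W / E
    out[E == 0 | is.na(E)] <- NA_real_
    out
  })
  structure(list(oe = oe, expected = expected, binning = binning),
            class = "oe_matrices")
}

#' Per-chromosome Pearson correlation matrix of O/E contacts
#'
#' Bins whose fraction of zero or missing O/E entries exceeds
#' \code{max_zero_fraction} ("loci that mostly had contact frequencies of
#' zero") are excluded; the remaining rows are correlated pairwise with
#' missing entries dropped pairwise, and the diagonal set to 1.
#'
#' @param oe An \code{oe_matrices} object or a single dense O/E matrix.
#' @param chrom Chromosome name when \code{oe} is an \code{oe_matrices}.
#' @param max_zero_fraction Exclusion threshold (default 0.5).
#' @return List with \code{cor} (correlation matrix over retained bins),
#'   \code{retained} (indices within the chromosome), \code{excluded}.
#' @export
pearson_matrix <- function(oe, chrom = NULL, max_zero_fraction = 0.5) {
  M <- if (inherits(oe, "oe_matrices")) {
    stopifnot(!is.null(chrom))
    oe$oe[[chrom]]
  } else oe
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  zf <- rowMeans(is.na(M) | M == 0, na.rm = FALSE)
  zf[is.na(zf)] <- 1
  retained <- which(zf <= max_zero_fraction)
  if (length(retained) < 3L)
    stop("fewer than 3 bins retained for correlation")
  S <- M[retained, retained, drop = FALSE]
  C <- suppressWarnings(stats::cor(t(S), use = "pairwise.complete.obs"))
  C[is.na(C)] <- 0
  diag(C) <- 1
  list(cor = C, retained = retained,
       excluded = setdiff(seq_len(nrow(M)), retained))
}

#' Select the A/B compartment eigenvector by gene density
#'
#' PCA (mean-centered, unscaled) of the Pearson correlation matrix. For
#' each of the first five principal components the bins are split by
#' eigenvector sign into two candidate compartments and the gene density of
#' each side is the mean gene count per bin. The first component whose
#' denser side has at least \code{ratio_cutoff} (default 1.5) times the
#' gene density of the other is selected; if none qualifies, the component
#' with the largest density discrepancy is taken (ties go to the lowest
#' component index). The sign is then set so that the more gene-dense
#' (A) compartment is positive.
#'
#' @param pearson A correlation matrix, or the list returned by
#'   \code{\link{pearson_matrix}}.
#' @param gene_counts Integer vector of gene counts per retained bin.
#' @param ratio_cutoff Gene-density ratio required for direct selection.
#' @param n_pcs Number of leading components examined (default 5).
#' @return A \code{compartment_result}: list with \code{pc_index},
#'   \code{eigenvector} (signed, per retained bin), \code{gene_ratio},
#'   \code{met_cutoff}, \code{retained}.
#' @export
select_compartment_pc <- function(pearson, gene_counts, ratio_cutoff = 1.5,
                                  n_pcs = 5L) {
  retained <- NULL
  if (is.list(pearson) && !is.null(pearson$cor)) {
    retained <- pearson$retained
    pearson <- pearson$cor
  }
  stopifnot(is.matrix(pearson), length(gene_counts) == nrow(pearson))
  if (all(gene_counts == 0)) stop("gene counts are zero everywhere")
  pc <- stats::prcomp(pearson, center = TRUE, scale. = FALSE)
  k_max <- min(n_pcs, ncol(pc$rotation))
  ratios <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    ev <- pc$rotation[, k]
    pos <- ev >= 0
    if (all(pos) || all(!pos)) next
    dens <- c(mean(gene_counts[pos]), mean(gene_counts[!pos]))
    if (all(dens == 0)) next
    ratios[k] <- max(dens) / max(min(dens), .Machine$double.xmin)
  }
  if (all(is.na(ratios)))
    stop("no principal component splits the bins into two compartments")
  hit <- which(!is.na(ratios) & ratios >= ratio_cutoff)
  k <- if (length(hit)) hit[1L] else which.max(ratios)
  ev <- pc$rotation[, k]
  pos <- ev >= 0
  if (mean(gene_counts[pos]) < mean(gene_counts[!pos])) ev <- -ev
  structure(list(pc_index = k, eigenvector = unname(ev),
                 gene_ratio = ratios[k],
                 met_cutoff = !is.na(ratios[k]) && ratios[k] >= ratio_cutoff,
                 retained = retained),
            class = "compartment_result")
}

#' @export
print.compartment_result <- function(x, ...) {
  cat(sprintf("compartment eigenvector: PC%d, gene-density ratio %.3g%s\n",
              x$pc_index, x$gene_ratio,
              if (x$met_cutoff) "" else " (cutoff not met; largest discrepancy)"))
  invisible(x)
}

#' Full A/B compartment pipeline per chromosome
#'
#' Runs O/E normalization, per-chromosome Pearson correlation and
#' gene-density PCA selection for each chromosome of a contact matrix.
#'
#' @param cm A \code{contact_matrix}.
#' @param genes A \code{GRanges} of gene intervals.
#' @param max_zero_fraction,ratio_cutoff,n_pcs Passed through.
#' @return Named list of \code{compartment_result} per chromosome; each
#'   result gains an \code{eigenvector_full} over all bins of that
#'   chromosome (\code{NA} at excluded bins).
#' @export
compartment_eigenvectors <- function(cm, genes, max_zero_fraction = 0.5,
                                     ratio_cutoff = 1.5, n_pcs = 5L) {
  oe <- observed_over_expected(cm)
  gc_all <- gene_counts_per_bin(cm$binning, genes)
  bins <- genomic_bins(cm$binning)
  out <- list()
  for (ch in names(oe$oe)) {
    pm <- tryCatch(pearson_matrix(oe, ch, max_zero_fraction),
                   error = function(e) NULL)
    if (is.null(pm)) next
    in_chrom <- which(bins$chrom == ch)
    gc <- gc_all[in_chrom][pm$retained]
    res <- tryCatch(select_compartment_pc(pm, gc, ratio_cutoff, n_pcs),
                    error = function(e) NULL)
    if (is.null(res)) next
    full <- rep(NA_real_, length(in_chrom))
    full[pm$retained] <- res$eigenvector
    res$eigenvector_full <- full
    res$chrom <- ch
    out[[ch]] <- res
  }
  out
}
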