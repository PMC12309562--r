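#' Pairwise contact weight of a SPRITE cluster
#'
#' Each unordered pair of members in a cluster of size n contributes weight
#' 2/n, so a cluster's total contribution to the matrix is C(n,2) * 2/n =
#' n - 1: the influence of any single interaction is inversely proportional
#' to cluster size. Clusters of size below 2 contain no pairs and
#' contribute nothing.
#'
#' @param n Cluster size(s).
#' @return Numeric weight(s); 0 when \code{n < 2}.
#' @examples
#' cluster_weight(c(2, 100, 1))
#' @export
cluster_weight <- function(n) {
  ifelse(n >= 2, 2 / n, 0)
}

#' Build the 2/N-downweighted contact matrix
#'
#' For every cluster with \code{min_size <= n <= max_size}, each unordered
#' pair of members adds 2/n to the corresponding bin pair; pairs whose
#' members share a bin are recorded on the diagonal. The matrix is
#' symmetric and its total unordered-pair mass equals the sum of (n - 1)
#' over the clusters used (see \code{\link{matrix_mass}}).
#'
#' @param clusters A \code{sprite_clusters} object (or a mapped-read data
#'   frame, grouped on the fly).
#' @param binning A \code{\link{genome_binning}}.
#' @param min_size,max_size Cluster size bounds (defaults 2 and unbounded;
#'   the size caps used for display plots are options, not defaults).
#' @return A \code{contact_matrix} object: list with \code{weights} (sparse
#'   symmetric matrix over global bin indices), \code{binning},
#'   \code{n_clusters}, \code{min_size}, \code{max_size}.
#' @export
build_matrix <- function(clusters, binning, min_size = 2L, max_size = Inf) {
  if (is.data.frame(clusters)) clusters <- build_clusters(clusters)
  stopifnot(inherits(clusters, "sprite_clusters"),
            inherits(binning, "genome_binning"), min_size >= 2L)
  m <- clusters$members
  nbin <- nrow(binning$bins)
  if (nrow(m) == 0L) {
    W <- Matrix::sparseMatrix(i = integer(0L), j = integer(0L), x = numeric(0L),
                              dims = c(nbin, nbin), symmetric = TRUE)
    return(structure(list(weights = W, binning = binning, n_clusters = 0L,
                          min_size = min_size, max_size = max_size),
                     class = "contact_matrix"))
  }
  sizes <- clusters$sizes[m$barcode]
  keep <- sizes >= min_size & sizes <= max_size
  m <- m[keep, , drop = FALSE]
  used <- unique(m$barcode)
  n <- clusters$sizes[used]
  cid <- match(m$barcode, used)
  bin <- bin_index(binning, m$chrom, m$start, what = "cluster member")

  # member-count matrix M (cluster x bin); with D = diag(2/n),
  # S = M' D M has S[i,j] = sum_c (2/n_c) m_ci m_cj, which is the
  # unordered-pair weight for i != j; the diagonal needs the m_ci^2 ->
  # C(m_ci, 2) correction.
  M <- Matrix::sparseMatrix(i = cid, j = bin, x = rep(1, length(cid)),
                            dims = c(length(used), nbin))
  d <- cluster_weight(n)
  S <- Matrix::crossprod(M * sqrt(d))
  colmass <- as.numeric(Matrix::crossprod(M, d))
  W <- methods::as(S, "generalMatrix")
  Matrix::diag(W) <- (Matrix::diag(S) - colmass) / 2
  W <- Matrix::forceSymmetric(Matrix::drop0(W))
  structure(list(weights = W, binning = binning,
                 n_clusters = length(used), min_size = min_size,
                 max_size = max_size),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact matrix: %d bins (incl. chrT), %d clusters, mass %.4g\n",
              nrow(x$weights), x$n_clusters, matrix_mass(x)))
  invisible(x)
}

#' Total unordered-pair mass of a contact matrix
#'
#' Equals the sum over included clusters of (n - 1); useful as an exact
#' conservation check of the 2/N weighting.
#'
#' @param cm A \code{contact_matrix}.
#' @return A number.
#' @export
matrix_mass <- function(cm) {
  W <- cm$weights
  (sum(W) + sum(Matrix::diag(W))) / 2
}

#' Extract the genome-wide telomere contact track
#'
#' The chrT row of the contact matrix, over genomic bins only; the
#' chrT-chrT diagonal entry (telomere-telomere clustering mass) is reported
#' separately rather than as part of the track.
#'
#' @param cm A \code{contact_matrix} whose binning includes chrT.
#' @return A \code{telomere_track} object: list with \code{track} (numeric
#'   per genomic bin), \code{chrT_self}, and the \code{binning}.
#' @export
telomere_track <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  ti <- cm$binning$chrT_index
  row <- as.numeric(cm$weights[ti, ])
  structure(list(track = row[-ti], chrT_self = row[ti],
                 binning = cm$binning),
            class = "telomere_track")
}

#' @export
print.telomere_track <- function(x, ...) {
  cat(sprintf("telomere contact track: %d bins, total %.4g (chrT self %.4g)\n",
              length(x$track), sum(x$track), x$chrT_self))
  invisible(x)
}

#' Aggregate a fine-resolution contact matrix to a coarser resolution
#'
#' Sums fine-bin pair weights into coarse-bin pairs; the coarse resolution
#' must be an integer multiple of the fine one. Building at 100 kb and
#' aggregating to 1 Mb equals building at 1 Mb directly.
#'
#' @param cm A \code{contact_matrix}.
#' @param resolution Target resolution in bp.
#' @return A \code{contact_matrix} at the coarser resolution.
#' @export
aggregate_matrix <- function(cm, resolution) {
  fine <- cm$binning
  if (resolution %% fine$resolution != 0)
    stop("target resolution must be a multiple of the source resolution")
  coarse <- genome_binning(fine$chrom_sizes, resolution)
  b <- fine$bins
  map <- integer(nrow(b))
  is_t <- b$chrom == "chrT"
  map[is_t] <- coarse$chrT_index
  map[!is_t] <- bin_index(coarse, b$chrom[!is_t], b$start[!is_t])
  P <- Matrix::sparseMatrix(i = seq_along(map), j = map,
                            x = rep(1, length(map)),
                            dims = c(nrow(b), nrow(coarse$bins)))
  S <- Matrix::t(P) %*% cm$weights %*% P
  # S double-counts off-diagonal fine pairs that land on the coarse
  # diagonal; restore unordered-pair semantics there.
  fine_diag_mass <- as.numeric(Matrix::crossprod(P, Matrix::diag(cm$weights)))
  W <- methods::as(S, "generalMatrix")
  Matrix::diag(W) <- (Matrix::diag(S) + fine_diag_mass) / 2
  W <- Matrix::forceSymmetric(Matrix::drop0(W))
  structure(list(weights = W, binning = coarse, n_clusters = cm$n_clusters,
                 min_size = cm$min_size, max_size = cm$max_size),
            class = "contact_matrix")
}

#' Per-cluster fine-resolution occupancy over a region
#'
#' Rows are clusters meeting the size/chrT criteria with at least one
#' genomic member in the region; columns are fine bins tiling the region;
#' a cell is TRUE when a member of that cluster falls in that fine bin.
#' This is the data behind per-cluster contact ("cluster") plots drawn at
#' 25-50 kb resolution for clusters up to a display size cap.
#'
#' @param clusters A \code{sprite_clusters} object.
#' @param chrom,start,end Region (0-based half-open).
#' @param fine_resolution Fine bin width in bp (e.g. 25000).
#' @param max_cluster_size Keep clusters up to this size (default
#'   unbounded).
#' @param require_chrT Keep only clusters containing at least one chrT
#'   (telomere) member.
#' @return Logical matrix (clusters x fine bins), row names = barcodes;
#'   zero rows when nothing qualifies.
#' @export
cluster_profile <- function(clusters, chrom, start, end, fine_resolution,
                            max_cluster_size = Inf, require_chrT = FALSE) {
  stopifnot(inherits(clusters, "sprite_clusters"), end > start,
            fine_resolution >= 1)
  m <- clusters$members
  sizes <- clusters$sizes
  ok_bc <- names(sizes)[sizes <= max_cluster_size]
  if (require_chrT)
    ok_bc <- intersect(ok_bc, unique(m$barcode[m$chrom == "chrT"]))
  sel <- m$barcode %in% ok_bc & m$chrom == chrom &
    m$start >= start & m$start < end
  nb <- as.integer(ceiling((end - start) / fine_resolution))
  if (!any(sel)) {
    out <- matrix(FALSE, 0L, nb)
    colnames(out) <- as.integer(start + fine_resolution * (seq_len(nb) - 1L))
    return(out)
  }
  hit <- m[sel, , drop = FALSE]
  bcs <- sort(unique(hit$barcode), method = "radix")
  col <- as.integer((hit$start - start) %/% fine_resolution) + 1L
  out <- matrix(FALSE, length(bcs), nb,
                dimnames = list(bcs, as.integer(start + fine_resolution *
                                                  (seq_len(nb) - 1L))))
  out[cbind(match(hit$barcode, bcs), col)] <- TRUE
  out
}

#' Export a contact matrix as triplet text plus a bin table
#'
#' Writes non-zero upper-triangle entries as \code{bin_i<TAB>bin_j<TAB>weight}
#' and the bin table as \code{index<TAB>chrom<TAB>start<TAB>end}.
#'
#' @param cm A \code{contact_matrix}.
#' @param path Triplet output path.
#' @param bin_path Bin table output path (default \code{path} +
#'   \code{".bins"}).
#' @return Invisibly, \code{path}.
#' @export
export_matrix <- function(cm, path, bin_path = paste0(path, ".bins")) {
  T3 <- methods::as(methods::as(cm$weights, "generalMatrix"), "TsparseMatrix")
  keep <- T3@i <= T3@j
  i <- T3@i[keep] + 1L
  j <- T3@j[keep] + 1L
  x <- T3@x[keep]
  ord <- order(i, j)
  writeLines(sprintf("%d\t%d\t%s", i[ord], j[ord],
                     format(x[ord], trim = TRUE, scientific = FALSE,
                            digits = 10)), path)
  b <- cm$binning$bins
  writeLines(sprintf("%d\t%s\t%d\t%d", b$index, b$chrom,
                     as.integer(b$start), as.integer(b$end)), bin_path)
  invisible(path)
}
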