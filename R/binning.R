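#' Tile a genome into fixed-width bins plus the artificial chrT bin
#'
#' Bins are 0-based half-open, tile each chromosome in the order given, and
#' the last bin of each chromosome is truncated to the chromosome length.
#' One extra single-bp bin named \code{chrT} is appended at the end; all
#' telomere-repeat reads are assigned there so that telomere-versus-genome
#' contacts occupy a single row of the contact matrix at any resolution.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (or a path
#'   to a chrom.sizes file).
#' @param resolution Bin width in bp (default 1 Mb).
#' @return A \code{genome_binning} object with a \code{bins} data frame
#'   (chrom, start, end, index), the resolution, the chromosome sizes, the
#'   chrT bin index and the number of genomic bins.
#' @examples
#' genome_binning(c(chr1 = 5e6, chr2 = 2.5e6), resolution = 1e6)
#' @export
genome_binning <- function(chrom_sizes, resolution = 1e6) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L)
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  stopifnot(!is.null(names(chrom_sizes)), all(chrom_sizes > 0),
            resolution >= 1)
  if ("chrT" %in% names(chrom_sizes))
    stop("'chrT' is reserved for the artificial telomere bin")
  nb <- as.integer(ceiling(chrom_sizes / resolution))
  chrom <- rep(names(chrom_sizes), nb)
  start <- unlist(lapply(seq_along(nb), function(i) {
    seq(0, by = resolution, length.out = nb[i])
  }), use.names = FALSE)
  end <- pmin(start + resolution, rep(unname(chrom_sizes), nb))
  bins <- data.frame(chrom = c(chrom, "chrT"),
                     start = c(start, 0),
                     end = c(end, 1),
                     index = seq_len(sum(nb) + 1L),
                     stringsAsFactors = FALSE)
  structure(
    list(bins = bins,
         resolution = resolution,
         chrom_sizes = chrom_sizes,
         bins_per_chrom = stats::setNames(nb, names(chrom_sizes)),
         chrom_offset = stats::setNames(c(0L, cumsum(nb)[-length(nb)]),
                                        names(chrom_sizes)),
         chrT_index = sum(nb) + 1L,
         n_genomic = sum(nb)),
    class = "genome_binning"
  )
}

#' @export
print.genome_binning <- function(x, ...) {
  cat(sprintf("genome binning: %d genomic bins (+chrT) over %d chromosomes at %g bp\n",
              x$n_genomic, length(x$chrom_sizes), x$resolution))
  invisible(x)
}

# genomic (non-chrT) bins as a data frame
genomic_bins <- function(binning) {
  binning$bins[binning$bins$chrom != "chrT", , drop = FALSE]
}

genomic_bins_granges <- function(binning) {
  b <- genomic_bins(binning)
  GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1L, b$end))
}

#' Map read positions to global bin indices
#'
#' @param binning A \code{\link{genome_binning}}.
#' @param chrom,pos Parallel vectors of chromosome names and 0-based
#'   positions; chrT maps to the chrT bin regardless of position.
#' @param what Label used in error messages when a position falls outside
#'   its chromosome.
#' @return Integer vector of global bin indices.
#' @export
bin_index <- function(binning, chrom, pos, what = "read") {
  idx <- integer(length(chrom))
  is_t <- chrom == "chrT"
  idx[is_t] <- binning$chrT_index
  if (any(!is_t)) {
    ch <- chrom[!is_t]
    p <- pos[!is_t]
    unknown <- !(ch %in% names(binning$chrom_sizes))
    if (any(unknown))
      stop("unknown chromosome for ", what, ": ",
           paste(unique(ch[unknown]), collapse = ", "))
    L <- binning$chrom_sizes[ch]
    bad <- p < 0 | p >= L
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("%s at %s:%g lies outside the chromosome (length %g)",
                   what, ch[i], p[i], L[i]))
    }
    idx[!is_t] <- binning$chrom_offset[ch] + p %/% binning$resolution + 1L
  }
  as.integer(idx)
}

#' Distance class of each genomic bin from the nearest chromosome end
#'
#' The terminal bin of each arm has class 1, the next bin class 2, and so
#' on; a bin's class is the minimum of its index counted from either end of
#' its chromosome. At 1 Mb resolution class d reads as "d Mb from the
#' nearest telomere".
#'
#' @param binning A \code{\link{genome_binning}}.
#' @return Integer vector over the genomic bins (chrT excluded).
#' @export
distance_classes <- function(binning) {
  unlist(lapply(names(binning$chrom_sizes), function(ch) {
    nb <- binning$bins_per_chrom[[ch]]
    i <- seq_len(nb)
    pmin(i, nb - i + 1L)
  }), use.names = FALSE)
}
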