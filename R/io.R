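#' Read a UCSC-style chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name and length in bp.
#'
#' @param path Path to the chrom.sizes file.
#' @return Named numeric vector of chromosome lengths, in file order.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$length, tab$chrom)
}

#' Read annotation intervals from a BED file
#'
#' Thin wrapper around \code{rtracklayer::import}; returns a \code{GRanges}
#' (1-based closed internally, converted from BED's 0-based half-open).
#'
#' @param path Path to a BED file.
#' @return A \code{GRanges}.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write a per-bin track as bedGraph
#'
#' One line per genomic bin (chrT excluded); \code{NA} values are written as
#' 0 unless \code{drop_na} is set.
#'
#' @param track Numeric vector over the genomic bins of \code{binning}, or a
#'   \code{telomere_track} object.
#' @param binning A \code{\link{genome_binning}}; ignored when \code{track}
#'   carries its own.
#' @param path Output path.
#' @param drop_na Drop \code{NA} bins instead of writing 0.
#' @return Invisibly, \code{path}.
#' @export
write_bedgraph <- function(track, binning = NULL, path, drop_na = FALSE) {
  if (inherits(track, "telomere_track")) {
    binning <- track$binning
    track <- track$track
  }
  bins <- genomic_bins(binning)
  stopifnot(length(track) == nrow(bins))
  keep <- rep(TRUE, length(track))
  if (drop_na) keep <- !is.na(track) else track[is.na(track)] <- 0
  lines <- sprintf("%s\t%d\t%d\t%s", bins$chrom[keep],
                   as.integer(bins$start[keep]), as.integer(bins$end[keep]),
                   format(track[keep], trim = TRUE, scientific = FALSE,
                          digits = 10))
  writeLines(lines, path)
  invisible(path)
}

# GRanges from 0-based half-open read coordinates
reads_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = pmax(df$end, df$start + 1L)))
}
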