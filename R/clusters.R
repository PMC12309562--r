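#' Assign telomeric reads to the artificial chrT locus
#'
#' Every telomeric read becomes a mapped read on the artificial single-bp
#' locus chrT with interval [0, 1), mapping quality 60 and its barcode
#' preserved, so that all telomere reads fall into one matrix bin at any
#' binning resolution.
#'
#' @param barcodes Character vector, one barcode per telomeric read.
#' @return A mapped-read data frame (barcode, chrom, start, end, mapq,
#'   strand).
#' @examples
#' assign_chrT(c("b1", "b1", "b2"))
#' @export
assign_chrT <- function(barcodes) {
  data.frame(barcode = as.character(barcodes),
             chrom = rep("chrT", length(barcodes)),
             start = rep(0L, length(barcodes)),
             end = rep(1L, length(barcodes)),
             mapq = rep(60L, length(barcodes)),
             strand = rep("*", length(barcodes)),
             stringsAsFactors = FALSE)
}

#' Remove reads overlapping repeat-mask intervals
#'
#' Genomic reads overlapping any mask interval by at least 1 bp (half-open
#' BED semantics) are removed; chrT reads are never affected by masking.
#' Mask intervals on chromosomes absent from \code{chrom_sizes} (when given)
#' are ignored with a warning.
#'
#' @param reads Mapped-read data frame with 0-based half-open coordinates.
#' @param mask A \code{GRanges} of mask intervals (e.g. from
#'   \code{\link{read_bed}}).
#' @param chrom_sizes Optional named vector used to detect unknown mask
#'   chromosomes.
#' @return The filtered mapped-read data frame.
#' @export
apply_mask <- function(reads, mask, chrom_sizes = NULL) {
  if (length(mask) == 0L || nrow(reads) == 0L) return(reads)
  if (!is.null(chrom_sizes)) {
    unknown <- !(as.character(GenomicRanges::seqnames(mask)) %in%
                   c(names(chrom_sizes), "chrT"))
    if (any(unknown)) {
      warning("ignoring ", sum(unknown),
              " mask interval(s) on unknown chromosome(s)")
      mask <- mask[!unknown]
    }
  }
  if (length(mask) == 0L) return(reads)
  mask <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(mask)), IRanges::ranges(mask))
  is_t <- reads$chrom == "chrT"
  gen <- reads[!is_t, , drop = FALSE]
  if (nrow(gen) > 0L) {
    hits <- GenomicRanges::countOverlaps(reads_to_granges(gen), mask,
                                         minoverlap = 1L)
    gen <- gen[hits == 0L, , drop = FALSE]
  }
  out <- rbind(gen, reads[is_t, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Group mapped reads into SPRITE clusters by shared barcode
#'
#' One cluster per distinct barcode. Within a barcode, reads with identical
#' (chrom, start) are collapsed to a single member (presumed PCR
#' duplicates); the number removed is recorded. Member order is
#' canonicalized by (chrom, start) and barcodes are sorted, so output is
#' bit-reproducible. Clusters smaller than \code{min_size} are retained but
#' flagged.
#'
#' @param reads Mapped-read data frame (genomic and/or chrT reads).
#' @param min_size Minimum cluster size below which a cluster is flagged
#'   (default 1, i.e. keep all unflagged).
#' @param dedup Collapse identical (barcode, chrom, start) members
#'   (default \code{TRUE}).
#' @return A \code{sprite_clusters} object: list with \code{members} (the
#'   canonicalized read data frame), \code{sizes} (named integer vector per
#'   barcode), \code{dup_removed}, and \code{flagged} (barcodes of clusters
#'   below \code{min_size}).
#' @export
build_clusters <- function(reads, min_size = 1L, dedup = TRUE) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0L) {
    return(structure(list(members = reads, sizes = integer(0L),
                          dup_removed = 0L, flagged = character(0L)),
                     class = "sprite_clusters"))
  }
  ord <- order(reads$barcode, reads$chrom, reads$start, method = "radix")
  m <- reads[ord, , drop = FALSE]
  dup_removed <- 0L
  if (dedup) {
    dup <- duplicated(m[c("barcode", "chrom", "start")])
    dup_removed <- sum(dup)
    m <- m[!dup, , drop = FALSE]
  }
  rownames(m) <- NULL
  sizes <- table(m$barcode)
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  structure(list(members = m, sizes = sizes, dup_removed = dup_removed,
                 flagged = names(sizes)[sizes < min_size]),
            class = "sprite_clusters")
}

#' @export
print.sprite_clusters <- function(x, ...) {
  cat(sprintf("%d SPRITE clusters, %d members (%d duplicate(s) removed)\n",
              length(x$sizes), nrow(x$members), x$dup_removed))
  if (length(x$sizes))
    cat(sprintf("  sizes: min %d, median %g, max %d; chrT members: %d\n",
                min(x$sizes), stats::median(x$sizes), max(x$sizes),
                sum(x$members$chrom == "chrT")))
  invisible(x)
}

#' Write a SPRITE cluster file
#'
#' One line per cluster: the barcode followed by tab-separated members in
#' \code{chrom:start-end} form (0-based half-open; chrT members serialize as
#' \code{chrT:0-1}), members sorted by (chrom, start). Reading then writing
#' a valid file reproduces it byte for byte.
#'
#' @param clusters A \code{sprite_clusters} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_cluster_file <- function(clusters, path) {
  m <- clusters$members
  member_str <- sprintf("%s:%d-%d", m$chrom, as.integer(m$start),
                        as.integer(m$end))
  bcs <- sort(unique(m$barcode), method = "radix")
  lines <- vapply(split(member_str, factor(m$barcode, levels = bcs)),
                  function(s) paste(s, collapse = "\t"), character(1L))
  writeLines(paste(bcs, lines, sep = "\t"), path)
  invisible(path)
}

#' Read a SPRITE cluster file
#'
#' @param path Path to a cluster file written by
#'   \code{\link{write_cluster_file}} (or the same dialect).
#' @return A \code{sprite_clusters} object. Members get mapq 60 and strand
#'   \code{*} (the dialect does not carry them).
#' @export
read_cluster_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(build_clusters(empty_reads()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1L)) < 2L)
  if (length(bad))
    stop("malformed cluster line ", bad[1L], ": expected barcode + members")
  barcode <- rep(vapply(fields, `[`, character(1L), 1L),
                 vapply(fields, length, integer(1L)) - 1L)
  members <- unlist(lapply(fields, `[`, -1L), use.names = FALSE)
  m <- regmatches(members, regexec("^([^:]+):([0-9]+)-([0-9]+)$", members))
  bad <- which(vapply(m, length, integer(1L)) != 4L)
  if (length(bad))
    stop("malformed member token '", members[bad[1L]], "'")
  reads <- data.frame(
    barcode = barcode,
    chrom = vapply(m, `[`, character(1L), 2L),
    start = as.integer(vapply(m, `[`, character(1L), 3L)),
    end = as.integer(vapply(m, `[`, character(1L), 4L)),
    mapq = 60L,
    strand = "*",
    stringsAsFactors = FALSE
  )
  build_clusters(reads, dedup = FALSE)
}

empty_reads <- function() {
  data.frame(barcode = character(0L), chrom = character(0L),
             start = integer(0L), end = integer(0L), mapq = integer(0L),
             strand = character(0L), stringsAsFactors = FALSE)
}
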