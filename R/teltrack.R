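#' Telomere contact decay with distance from the chromosome end
#'
#' Bins are grouped by their distance class (distance from the nearest
#' chromosome end of the reference, in bins; see
#' \code{\link{distance_classes}}). Bins with a contact frequency of
#' exactly zero are assumed to lack mappable DNA and excluded. Per class,
#' the mean track value over contributing bins is expressed as a ratio to
#' the class-1 (terminal bin) mean, with a standard error propagated from
#' the per-bin values.
#'
#' @param track A \code{telomere_track} or numeric vector over genomic bins.
#' @param binning Required when \code{track} is a bare vector.
#' @return Data frame with \code{class}, \code{mean_ratio}, \code{se},
#'   \code{n_bins}.
#' @export
decay_curve <- function(track, binning = NULL) {
  v <- track_vector(track, binning)
  cls <- distance_classes(v$binning)
  nz <- !is.na(v$track) & v$track > 0
  if (!any(nz & cls == 1L) || mean(v$track[nz & cls == 1L]) == 0)
    stop("degenerate track: no non-zero terminal (class 1) bins")
  ref <- mean(v$track[nz & cls == 1L])
  out <- do.call(rbind, lapply(sort(unique(cls[nz])), function(d) {
    x <- v$track[nz & cls == d]
    data.frame(class = d, mean_ratio = mean(x) / ref,
               se = stats::sd(x) / sqrt(length(x)) / ref,
               n_bins = length(x))
  }))
  rownames(out) <- NULL
  out
}

#' Distance-normalize a telomere contact track
#'
#' Divides each bin's contact frequency by the mean contact frequency over
#' the non-zero bins at the same distance from the nearest chromosome end,
#' removing the dominant linear-distance effect so that other influences on
#' telomere contact frequency (centromeres, heterochromatin, ectopic
#' repeats) become visible. Zero bins are flagged \code{NA} and excluded
#' from the class means; by construction the mean of the normalized values
#' within any class is exactly 1.
#'
#' @inheritParams decay_curve
#' @return A \code{telomere_track} whose \code{track} holds the normalized
#'   values (\code{NA} at zero bins).
#' @export
distance_normalize <- function(track, binning = NULL) {
  v <- track_vector(track, binning)
  cls <- distance_classes(v$binning)
  nz <- !is.na(v$track) & v$track > 0
  means <- tapply(v$track[nz], cls[nz], mean)
  norm <- rep(NA_real_, length(v$track))
  cm <- means[as.character(cls)]
  ok <- nz & !is.na(cm) & cm > 0
  norm[ok] <- v$track[ok] / cm[ok]
  structure(list(track = norm, chrT_self = v$chrT_self,
                 binning = v$binning, normalized = TRUE),
            class = "telomere_track")
}

#' Flag bins overlapping annotation intervals
#'
#' A bin is flagged when it overlaps any interval by at least 1 bp.
#' Intervals on chromosomes absent from the binning are ignored with a
#' warning.
#'
#' @param binning A \code{\link{genome_binning}}.
#' @param intervals A \code{GRanges} (e.g. centromeres or ectopic loci from
#'   \code{\link{read_bed}}).
#' @return Logical vector over the genomic bins.
#' @export
overlap_flags <- function(binning, intervals) {
  known <- as.character(GenomicRanges::seqnames(intervals)) %in%
    names(binning$chrom_sizes)
  if (!all(known)) {
    warning("ignoring ", sum(!known),
            " interval(s) on chromosome(s) absent from the binning")
    intervals <- intervals[known]
  }
  if (length(intervals) == 0L)
    return(rep(FALSE, binning$n_genomic))
  # rebuild on the binning's own seqlevels so overlap is purely by name
  intervals <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(intervals)),
    IRanges::ranges(intervals))
  GenomicRanges::countOverlaps(genomic_bins_granges(binning), intervals,
                               minoverlap = 1L) > 0L
}

#' Compare distance-normalized telomere contacts between bin groups
#'
#' Welch two-sample t-test of the distance-normalized track between flagged
#' bins (e.g. those containing centromere sequence) and the rest; zero
#' (\code{NA}) bins are excluded. The Welch form is used because group
#' sizes and variances differ drastically.
#'
#' @param norm_track A distance-normalized \code{telomere_track} (or
#'   numeric vector with \code{NA} at excluded bins).
#' @param flags Logical vector over genomic bins.
#' @param labels Length-2 character vector naming the flagged / unflagged
#'   groups (for error messages and output).
#' @return List with \code{statistic}, \code{p.value}, \code{mean_in},
#'   \code{mean_out}, \code{n_in}, \code{n_out}.
#' @export
group_compare <- function(norm_track, flags,
                          labels = c("flagged", "unflagged")) {
  v <- if (inherits(norm_track, "telomere_track")) norm_track$track
       else norm_track
  stopifnot(length(v) == length(flags))
  a <- v[flags & !is.na(v)]
  b <- v[!flags & !is.na(v)]
  if (length(a) < 2L) stop("group '", labels[1L], "' has fewer than 2 bins")
  if (length(b) < 2L) stop("group '", labels[2L], "' has fewer than 2 bins")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       mean_in = mean(a), mean_out = mean(b),
       n_in = length(a), n_out = length(b))
}

#' Read enrichment of telomere-containing clusters near peaks
#'
#' For each signed distance bin between -window and +window, the number of
#' genomic reads at that distance from the nearest peak center in
#' telomere-containing clusters is divided by the corresponding count in
#' clusters without telomeres; the whole curve is then divided by its
#' minimum so that the minimum is 1. Distance is measured from the read
#' midpoint to the nearest peak center. Distance bins with zero
#' non-telomere reads are reported as \code{NA}.
#'
#' @param clusters A \code{sprite_clusters} object (chrT members mark
#'   telomere-containing clusters).
#' @param peaks A \code{GRanges} of peaks (e.g. H3K9me3).
#' @param window Half-width of the profile in bp (default 50 kb).
#' @param step Distance bin width in bp (default 1 kb).
#' @return Data frame with \code{dist} (bin center, bp), \code{n_tel},
#'   \code{n_nontel}, \code{ratio} (min-normalized).
#' @export
peak_proximity_profile <- function(clusters, peaks, window = 50000L,
                                   step = 1000L) {
  stopifnot(inherits(clusters, "sprite_clusters"), length(peaks) > 0L)
  m <- clusters$members
  tel_bc <- unique(m$barcode[m$chrom == "chrT"])
  gen <- m[m$chrom != "chrT", , drop = FALSE]
  if (nrow(gen) == 0L) stop("no genomic reads in clusters")
  is_tel <- gen$barcode %in% tel_bc
  centers <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2
  pk_chrom <- as.character(GenomicRanges::seqnames(peaks))
  mid <- (gen$start + gen$end) / 2
  d <- rep(NA_real_, nrow(gen))
  for (ch in unique(gen$chrom)) {
    pc <- sort(centers[pk_chrom == ch])
    if (length(pc) == 0L) next
    sel <- which(gen$chrom == ch)
    i <- findInterval(mid[sel], pc)
    lo <- pc[pmax(i, 1L)]
    hi <- pc[pmin(i + 1L, length(pc))]
    dl <- mid[sel] - lo
    dh <- mid[sel] - hi
    d[sel] <- ifelse(i == 0L, dh,
                     ifelse(i == length(pc), dl,
                            ifelse(abs(dl) <= abs(dh), dl, dh)))
  }
  ok <- !is.na(d) & abs(d) <= window
  edges <- seq(-window, window, by = step)
  bin <- cut(d[ok], breaks = edges, include.lowest = TRUE)
  n_tel <- tapply(is_tel[ok], bin, sum, default = 0L)
  n_non <- tapply(!is_tel[ok], bin, sum, default = 0L)
  ratio <- ifelse(n_non > 0L, n_tel / n_non, NA_real_)
  if (all(is.na(ratio)))
    stop("no distance bin has non-telomere cluster reads")
  mn <- min(ratio, na.rm = TRUE)
  if (mn == 0) {
    # an all-zero telomere count bin makes the literal minimum unusable
    pos <- ratio[!is.na(ratio) & ratio > 0]
    if (length(pos) == 0L) stop("telomere cluster read counts are all zero")
    warning("curve minimum is 0; normalizing by the smallest positive ratio")
    mn <- min(pos)
  }
  ratio <- ratio / mn
  data.frame(dist = (edges[-1L] + edges[-length(edges)]) / 2,
             n_tel = as.integer(n_tel), n_nontel = as.integer(n_non),
             ratio = as.numeric(ratio), row.names = NULL)
}

#' Correlate a telomere track with a compartment eigenvector
#'
#' Pearson correlation between the (distance-normalized) telomere contact
#' track and an A/B compartment eigenvector over the same bins; bins where
#' either value is missing are dropped pairwise. A negative correlation
#' indicates enhanced telomere contacts with the B (heterochromatic)
#' compartment.
#'
#' @param norm_track Numeric vector or \code{telomere_track}.
#' @param eigenvector Numeric vector over the same bins.
#' @return List with \code{r}, \code{p.value}, \code{n}.
#' @export
eigencorrelation <- function(norm_track, eigenvector) {
  v <- if (inherits(norm_track, "telomere_track")) norm_track$track
       else norm_track
  stopifnot(length(v) == length(eigenvector))
  keep <- !is.na(v) & !is.na(eigenvector)
  if (sum(keep) < 3L) stop("fewer than 3 bins retained for correlation")
  ct <- stats::cor.test(v[keep], eigenvector[keep], method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = sum(keep))
}

track_vector <- function(track, binning) {
  if (inherits(track, "telomere_track")) return(track)
  stopifnot(inherits(binning, "genome_binning"),
            length(track) == binning$n_genomic)
  list(track = as.numeric(track), chrT_self = NA_real_, binning = binning)
}

#' Count gene intervals overlapping each bin
#'
#' @param binning A \code{\link{genome_binning}}.
#' @param genes A \code{GRanges} of gene intervals (BED or GTF import).
#' @return Integer vector over the genomic bins.
#' @export
gene_counts_per_bin <- function(binning, genes) {
  GenomicRanges::countOverlaps(genomic_bins_granges(binning), genes,
                               minoverlap = 1L)
}
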