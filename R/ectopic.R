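#' Scan a sequence for a 300-bp telomere repeat window
#'
#' Slides a fixed-width window anchored at every canonical repeat match
#' (either strand, counted per strand without mixing, as in
#' \code{\link{count_repeats}}) and greedily counts non-overlapping
#' canonical plus variant repeats inside the window. The window with the
#' maximal count is returned when that count reaches \code{min_repeats}
#' (45: a fully telomeric 300-bp window holds 50 hexamers, so 45 demands a
#' nearly pure repeat tract); sequences shorter than the window size are
#' ineligible.
#'
#' @param seq A single DNA sequence.
#' @param motifs A \code{\link{telomere_motifs}} object.
#' @param window Window width in bp (default 300).
#' @param min_repeats Minimum total repeats in the best window (default 45).
#' @return \code{NULL}, or a list with \code{offset} (0-based window start),
#'   \code{count}, \code{strand}.
#' @export
scan_telomere_window <- function(seq, motifs = telomere_motifs(),
                                 window = 300L, min_repeats = 45L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < window) return(NULL)
  hex <- hexamers(seq)
  best <- NULL
  for (strand in c("G", "C")) {
    can <- if (strand == "G") motifs$canonical_g else motifs$canonical_c
    var <- if (strand == "G") motifs$variant_g else motifs$variant_c
    can_at <- hex == can
    var_at <- hex %in% var
    anchors <- which(can_at)
    anchors <- anchors[anchors + window - 1L <= n]
    for (a in anchors) {
      cnt <- sum(greedy_scan(can_at, var_at, from = a,
                             to = min(a + window - 6L, length(hex))))
      if (is.null(best) || cnt > best$count)
        best <- list(offset = a - 1L, count = cnt, strand = strand)
    }
  }
  if (is.null(best) || best$count < min_repeats) return(NULL)
  best
}

#' Classify soft-clipped telomere evidence in a long-read alignment
#'
#' Runs \code{\link{scan_telomere_window}} on each soft-clipped segment of
#' the read independently; evidence is emitted only when a passing window
#' lies entirely within a clipped segment -- reads whose telomere tract sits
#' in the aligned portion are assumed to carry reference telomere sequence
#' and are ignored. The insertion position is the alignment start for a
#' left clip and the alignment end for a right clip. Orientation is
#' "standard" when the G-strand repeat extends away from the aligned
#' segment (TTAGGG matches on a right clip, CCCTAA on a left clip) and
#' "inverted" otherwise.
#'
#' @param aln One-row data frame (or list) with \code{read_id},
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open alignment
#'   span), \code{mapq}, \code{clip_left}, \code{clip_right}, \code{seq}
#'   (full read sequence in reference orientation).
#' @param motifs,window,min_repeats Passed to
#'   \code{\link{scan_telomere_window}}.
#' @return A data frame of evidence rows (possibly empty): \code{read_id},
#'   \code{chrom}, \code{position}, \code{side}, \code{orientation},
#'   \code{window_count}, \code{mapq}.
#' @export
classify_clip <- function(aln, motifs = telomere_motifs(), window = 300L,
                          min_repeats = 45L) {
  empty <- empty_evidence()
  seq <- aln$seq
  if (is.null(seq) || is.na(seq) || !nzchar(seq)) {
    warning("alignment ", aln$read_id, " has no stored sequence; skipped")
    return(empty)
  }
  n <- nchar(seq)
  rows <- list()
  for (side in c("left", "right")) {
    clip_len <- if (side == "left") aln$clip_left else aln$clip_right
    if (is.null(clip_len) || is.na(clip_len) || clip_len < 1L) next
    segment <- if (side == "left") substr(seq, 1L, clip_len)
               else substr(seq, n - clip_len + 1L, n)
    hit <- scan_telomere_window(segment, motifs, window, min_repeats)
    if (is.null(hit)) next
    standard <- (side == "right" && hit$strand == "G") ||
                (side == "left" && hit$strand == "C")
    rows[[side]] <- data.frame(
      read_id = aln$read_id, chrom = aln$chrom,
      position = if (side == "left") aln$start else aln$end,
      side = side,
      orientation = if (standard) "standard" else "inverted",
      window_count = hit$count, mapq = aln$mapq,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) empty else do.call(rbind, rows)
}

#' Collect clip evidence across a set of alignments
#'
#' @param alignments Data frame of long-read alignments (see
#'   \code{\link{classify_clip}}).
#' @param ... Passed to \code{\link{classify_clip}}.
#' @return Combined evidence data frame.
#' @export
classify_clips <- function(alignments, ...) {
  out <- lapply(seq_len(nrow(alignments)),
                function(i) classify_clip(alignments[i, ], ...))
  res <- do.call(rbind, out)
  if (is.null(res)) empty_evidence() else res
}

empty_evidence <- function() {
  data.frame(read_id = character(0L), chrom = character(0L),
             position = numeric(0L), side = character(0L),
             orientation = character(0L), window_count = integer(0L),
             mapq = integer(0L), stringsAsFactors = FALSE)
}

#' Locus-level mappability filter
#'
#' A candidate locus fails when at least \code{max_lowmapq_fraction}
#' (default 0.40) of the reads overlapping it in the original, unfiltered
#' alignment set have MAPQ below \code{low_mapq} (default 10). An
#' alignment overlaps the locus when its span contains the position. Zero
#' overlapping reads also fail (mappability is undeterminable).
#'
#' @param chrom,position Locus coordinates (0-based).
#' @param unfiltered Data frame of all alignments over the region
#'   (\code{chrom}, \code{start}, \code{end}, \code{mapq}).
#' @param low_mapq,max_lowmapq_fraction Filter parameters.
#' @return \code{TRUE} (pass) or \code{FALSE} (fail).
#' @export
locus_mappability_filter <- function(chrom, position, unfiltered,
                                     low_mapq = 10L,
                                     max_lowmapq_fraction = 0.40) {
  ov <- unfiltered$chrom == chrom & unfiltered$start <= position &
    unfiltered$end > position
  if (!any(ov)) return(FALSE)
  mean(unfiltered$mapq[ov] < low_mapq) < max_lowmapq_fraction
}

#' Call ectopic telomere repeat loci from clip evidence
#'
#' Evidence reads with MAPQ below \code{min_mapq} (30) or insertion
#' positions within \code{end_exclusion} (100 kb) of either chromosome end
#' are dropped. Remaining positions are merged per chromosome by single
#' linkage with a gap of at most \code{merge_gap} (100 bp); each merged
#' group takes the median member position as its representative, must pass
#' the \code{\link{locus_mappability_filter}} there, and must be supported
#' by at least \code{min_support} (2) distinct read ids.
#'
#' @param evidence Evidence data frame from \code{\link{classify_clips}}.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param unfiltered Unfiltered alignment data frame for the mappability
#'   filter.
#' @param min_mapq,end_exclusion,merge_gap,min_support,low_mapq,
#'   max_lowmapq_fraction Filter parameters as above.
#' @return Data frame of loci sorted by (chrom, position): \code{chrom},
#'   \code{position}, \code{n_reads}, \code{n_left}, \code{n_right},
#'   \code{n_standard}, \code{n_inverted}, \code{read_ids}
#'   (comma-separated).
#' @export
call_ectopic_loci <- function(evidence, chrom_sizes, unfiltered,
                              min_mapq = 30L, end_exclusion = 100000L,
                              merge_gap = 100L, min_support = 2L,
                              low_mapq = 10L, max_lowmapq_fraction = 0.40) {
  empty <- data.frame(chrom = character(0L), position = numeric(0L),
                      n_reads = integer(0L), n_left = integer(0L),
                      n_right = integer(0L), n_standard = integer(0L),
                      n_inverted = integer(0L), read_ids = character(0L),
                      stringsAsFactors = FALSE)
  if (nrow(evidence) == 0L) return(empty)
  L <- chrom_sizes[evidence$chrom]
  keep <- evidence$mapq >= min_mapq &
    pmin(evidence$position, L - evidence$position) >= end_exclusion
  ev <- evidence[keep & !is.na(keep), , drop = FALSE]
  if (nrow(ev) == 0L) return(empty)
  ev <- ev[order(ev$chrom, ev$position, ev$read_id, method = "radix"), ,
           drop = FALSE]
  new_chain <- c(TRUE, ev$chrom[-1L] != ev$chrom[-nrow(ev)] |
                   diff(ev$position) > merge_gap)
  ev$group <- cumsum(new_chain)
  loci <- lapply(split(ev, ev$group), function(g) {
    pos <- floor(stats::median(g$position))
    if (!locus_mappability_filter(g$chrom[1L], pos, unfiltered, low_mapq,
                                  max_lowmapq_fraction))
      return(NULL)
    ids <- sort(unique(g$read_id), method = "radix")
    if (length(ids) < min_support) return(NULL)
    data.frame(chrom = g$chrom[1L], position = pos,
               n_reads = length(ids),
               n_left = sum(g$side == "left"),
               n_right = sum(g$side == "right"),
               n_standard = sum(g$orientation == "standard"),
               n_inverted = sum(g$orientation == "inverted"),
               read_ids = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, loci[!vapply(loci, is.null, logical(1L))])
  if (is.null(loci)) return(empty)
  loci <- loci[order(loci$chrom, loci$position, method = "radix"), ,
               drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Annotate ectopic loci with overlapping genes
#'
#' A locus intersects a gene when its representative position falls
#' anywhere within the gene's transcriptional window; overlapping genes all
#' contribute labels.
#'
#' @param loci Locus data frame from \code{\link{call_ectopic_loci}}.
#' @param genes A \code{GRanges} of gene intervals whose names (or
#'   \code{name} metadata column) are the gene labels.
#' @return \code{loci} with an added \code{genes} column (comma-separated,
#'   empty when intergenic).
#' @export
annotate_loci_genes <- function(loci, genes) {
  labels <- names(genes)
  if (is.null(labels) && !is.null(genes$name)) labels <- genes$name
  if (is.null(labels)) labels <- as.character(seq_along(genes))
  if (nrow(loci) == 0L) {
    loci$genes <- character(0L)
    return(loci)
  }
  pts <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$position + 1L,
                                                 loci$position + 1L))
  hits <- GenomicRanges::findOverlaps(pts, genes)
  ann <- vapply(seq_len(nrow(loci)), function(i) {
    g <- labels[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
    paste(sort(g, method = "radix"), collapse = ",")
  }, character(1L))
  loci$genes <- ann
  loci
}

#' Read long-read alignments from a BAM file
#'
#' Extracts the fields the ectopic caller needs: read id, alignment span
#' (0-based half-open), MAPQ, soft-clip lengths from the CIGAR, the stored
#' sequence, and a primary-alignment flag. Unmapped records are skipped.
#'
#' @param path Path to a coordinate-sorted BAM file.
#' @return Long-read alignment data frame.
#' @export
read_long_reads <- function(path) {
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "mapq", "cigar", "seq", "flag"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  mapped <- !is.na(b$pos)
  cig <- b$cigar[mapped]
  ref_w <- cigar_ref_width(cig)
  data.frame(
    read_id = b$qname[mapped],
    chrom = as.character(b$rname)[mapped],
    start = b$pos[mapped] - 1L,
    end = b$pos[mapped] - 1L + ref_w,
    mapq = b$mapq[mapped],
    clip_left = as.integer(sub("^([0-9]+)S.*", "\\1",
                               ifelse(grepl("^[0-9]+S", cig), cig, "0S"))),
    clip_right = as.integer(sub(".*?([0-9]+)S$", "\\1",
                                ifelse(grepl("[0-9]+S$", cig), cig, "0S"))),
    seq = as.character(b$seq)[mapped],
    primary = bitwAnd(b$flag[mapped], 256L) == 0L,
    stringsAsFactors = FALSE
  )
}

# reference-space width of CIGAR strings (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1L), USE.NAMES = FALSE)
}

#' Write ectopic loci as BED6+
#'
#' Columns: chrom, position, position+1, locus id, supporting-read count,
#' strand ".", then side tally, orientation tally and gene labels.
#'
#' @param loci Annotated locus data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_ectopic_bed <- function(loci, path) {
  genes <- if ("genes" %in% names(loci)) loci$genes else ""
  lines <- sprintf("%s\t%d\t%d\tectopic_%d\t%d\t.\t%d,%d\t%d,%d\t%s",
                   loci$chrom, as.integer(loci$position),
                   as.integer(loci$position) + 1L,
                   seq_len(nrow(loci)), loci$n_reads,
                   loci$n_left, loci$n_right,
                   loci$n_standard, loci$n_inverted, genes)
  writeLines(lines, path)
  invisible(path)
}
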