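#' Count telomere repeats in a read sequence
#'
#' Scans the sequence greedily left to right, per strand, with non-overlapping
#' hexamer matches: at each position the canonical motif of the strand is
#' tried first, then any variant motif; a match advances the scan by 6 bp,
#' otherwise by 1 bp. The two strands are scanned independently and never
#' mixed -- a genuine telomere fragment derives from a single strand -- and
#' the strand with the larger total count is reported (ties go to the
#' G strand; for a mixed-strand sequence whose two scans tie, the reported
#' canonical count is therefore that of the G-strand tiling). N matches no
#' motif.
#'
#' @param seq A single DNA sequence (character scalar; case-insensitive;
#'   A/C/G/T/N only).
#' @param motifs A \code{\link{telomere_motifs}} object.
#' @return A list with \code{canonical}, \code{variant}, \code{total} counts
#'   and \code{strand} ("G" or "C").
#' @examples
#' count_repeats(strrep("TTAGGG", 14))
#' @export
count_repeats <- function(seq, motifs = telomere_motifs()) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains non-DNA characters (allowed: A/C/G/T/N)")
  hex <- hexamers(seq)
  g <- greedy_scan(hex == motifs$canonical_g, hex %in% motifs$variant_g)
  c_ <- greedy_scan(hex == motifs$canonical_c, hex %in% motifs$variant_c)
  if (sum(c_) > sum(g)) {
    list(canonical = c_[1L], variant = c_[2L], total = sum(c_), strand = "C")
  } else {
    list(canonical = g[1L], variant = g[2L], total = sum(g), strand = "G")
  }
}

#' Classify read sequences as telomeric
#'
#' Vectorized over sequences. A read is telomeric when its repeat count
#' (see \code{\link{count_repeats}}) satisfies both stringency conditions:
#' total repeats (canonical + variant) at or above \code{min_total} and
#' canonical repeats at or above \code{min_canonical}. Reads failing either
#' condition are assumed not to originate from telomeres.
#'
#' @param seqs Character vector of DNA sequences.
#' @param thresholds A \code{\link{stringency}} object.
#' @param motifs A \code{\link{telomere_motifs}} object.
#' @return Logical vector, one flag per sequence.
#' @examples
#' classify_reads(strrep("TTAGGG", 7), stringency("medium"))
#' @export
classify_reads <- function(seqs, thresholds = stringency("medium"),
                           motifs = telomere_motifs()) {
  vapply(seqs, function(s) {
    rc <- count_repeats(s, motifs)
    rc$total >= thresholds$min_total && rc$canonical >= thresholds$min_canonical
  }, logical(1L), USE.NAMES = FALSE)
}

#' Partition a barcode-annotated FASTQ into telomeric and non-telomeric reads
#'
#' Applies the stringency filter to the genomic-DNA read of each record and
#' writes every record to exactly one output stream, content and read name
#' unchanged. Records whose name lacks a barcode token (the suffix after the
#' last \code{barcode_delim}) are routed to a rejects stream with a warning.
#' Input and outputs are 4-line FASTQ; gzip is handled transparently by the
#' file extension.
#'
#' @param infile Input FASTQ path.
#' @param out_tel,out_gen Output FASTQ paths for telomeric and non-telomeric
#'   (genomic) reads.
#' @param out_rej Optional path for records without a barcode token; when
#'   \code{NULL} such records are still excluded from both main streams.
#' @param thresholds A \code{\link{stringency}} object.
#' @param motifs A \code{\link{telomere_motifs}} object.
#' @param barcode_delim Delimiter preceding the barcode token in read names.
#' @return Invisibly, a list with counts \code{n_tel}, \code{n_gen},
#'   \code{n_rej}.
#' @export
partition_reads <- function(infile, out_tel, out_gen, out_rej = NULL,
                            thresholds = stringency("medium"),
                            motifs = telomere_motifs(),
                            barcode_delim = "::") {
  reads <- read_fastq(infile)
  bc <- extract_barcodes(names(reads), barcode_delim)
  rejected <- is.na(bc)
  if (any(rejected))
    warning(sum(rejected), " record(s) without a '", barcode_delim,
            "' barcode token routed to rejects")
  tel <- logical(length(reads))
  keep <- !rejected
  tel[keep] <- classify_reads(as.character(reads[keep]), thresholds, motifs)
  write_fastq(reads[keep & tel], out_tel)
  write_fastq(reads[keep & !tel], out_gen)
  if (!is.null(out_rej))
    write_fastq(reads[rejected], out_rej)
  invisible(list(n_tel = sum(keep & tel), n_gen = sum(keep & !tel),
                 n_rej = sum(rejected)))
}

#' Extract barcode tokens from read names
#'
#' The barcode is the suffix of the read name after the last occurrence of
#' the delimiter; names without the delimiter yield \code{NA}.
#'
#' @param names Character vector of read names.
#' @param delim Delimiter string (default \code{"::"}).
#' @return Character vector of barcodes (\code{NA} where absent).
#' @export
extract_barcodes <- function(names, delim = "::") {
  has <- grepl(delim, names, fixed = TRUE)
  out <- rep(NA_character_, length(names))
  if (any(has)) {
    parts <- strsplit(names[has], delim, fixed = TRUE)
    out[has] <- vapply(parts, function(p) p[length(p)], character(1L))
  }
  out
}

read_fastq <- function(path) {
  # Biostrings notes that FASTQ cannot carry metadata columns; harmless here
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

write_fastq <- function(x, path) {
  S4Vectors::mcols(x) <- NULL
  # Biostrings warns that per-record metadata columns are not representable
  # in FASTQ; nothing we write carries meaningful mcols
  withCallingHandlers(
    Biostrings::writeQualityScaledXStringSet(x, path,
                                             compress = endsWith(path, ".gz")),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}

# all hexamer substrings starting at positions 1..(n-5)
hexamers <- function(seq) {
  n <- nchar(seq)
  if (n < 6L) return(character(0L))
  substring(seq, 1L:(n - 5L), 6L:n)
}

# greedy non-overlapping scan over hexamer start positions [from, to];
# canonical tried before variant at each position. Returns
# c(canonical, variant) counts.
greedy_scan <- function(can_at, var_at, from = 1L, to = length(can_at)) {
  canonical <- 0L
  variant <- 0L
  i <- from
  while (i <= to) {
    if (can_at[i]) {
      canonical <- canonical + 1L
      i <- i + 6L
    } else if (var_at[i]) {
      variant <- variant + 1L
      i <- i + 6L
    } else {
      i <- i + 1L
    }
  }
  c(canonical, variant)
}
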