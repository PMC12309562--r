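#' Telomere repeat motif sets
#'
#' Builds the set of hexamer motifs used to recognize telomere repeats on
#' either strand. The canonical repeat is TTAGGG on the G-rich strand and
#' its reverse complement CCCTAA on the C-rich strand. Human telomeres,
#' especially in ALT-positive cells, also contain near-cognate "variant"
#' hexamers; the default variant list covers the commonly reported human
#' variant repeats and is a documented stand-in -- every result can be
#' re-derived under a user-supplied list (see \code{variant_g} or
#' \code{\link{read_motif_file}}).
#'
#' @param variant_g Character vector of G-strand variant hexamers. The
#'   C-strand variants are always derived as their reverse complements.
#' @return An object of class \code{repeat_motifs} with fields
#'   \code{canonical_g}, \code{canonical_c}, \code{variant_g},
#'   \code{variant_c}.
#' @examples
#' m <- telomere_motifs()
#' m$canonical_g
#' @export
telomere_motifs <- function(variant_g = c("TCAGGG", "TGAGGG", "TTGGGG",
                                          "TTCGGG", "TTTGGG", "TAAGGG",
                                          "GTAGGG", "CTAGGG")) {
  canonical_g <- "TTAGGG"
  variant_g <- toupper(variant_g)
  if (any(nchar(variant_g) != 6L))
    stop("all variant motifs must be hexamers")
  if (any(grepl("[^ACGT]", variant_g)))
    stop("variant motifs must use the uppercase DNA alphabet (A/C/G/T)")
  variant_g <- setdiff(unique(variant_g), canonical_g)
  structure(
    list(
      canonical_g = canonical_g,
      canonical_c = revcomp(canonical_g),
      variant_g   = variant_g,
      variant_c   = revcomp(variant_g)
    ),
    class = "repeat_motifs"
  )
}

#' Read a motif configuration file
#'
#' Plain text, one G-strand hexamer per line; blank lines and lines starting
#' with \code{#} are ignored. The canonical TTAGGG is implicit and excluded
#' from the variant set if present.
#'
#' @param path Path to the motif file.
#' @return A \code{repeat_motifs} object.
#' @export
read_motif_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  telomere_motifs(variant_g = lines)
}

#' @export
print.repeat_motifs <- function(x, ...) {
  cat("telomere repeat motifs\n")
  cat("  canonical:", x$canonical_g, "/", x$canonical_c, "\n")
  cat("  variants (G-strand):", paste(x$variant_g, collapse = " "), "\n")
  invisible(x)
}

#' Stringency thresholds for telomere read classification
#'
#' A read is called telomeric when it carries at least \code{min_total}
#' repeats (canonical plus variant) and at least \code{min_canonical}
#' canonical repeats. The three presets correspond to low (4 total /
#' 2 canonical), medium (7/4) and high (14/7) stringency; SPRITE reads
#' yield roughly 85-90 bp of genomic sequence, so about 14 repeats is the
#' ceiling for a fully telomeric read.
#'
#' @param preset One of \code{"low"}, \code{"medium"}, \code{"high"} or
#'   \code{"custom"}.
#' @param min_total,min_canonical Counts used when \code{preset = "custom"}.
#' @return An object of class \code{stringency} with fields
#'   \code{min_total}, \code{min_canonical}, \code{preset}.
#' @examples
#' stringency("medium")
#' stringency("custom", min_total = 5, min_canonical = 3)
#' @export
stringency <- function(preset = c("medium", "low", "high", "custom"),
                       min_total = NULL, min_canonical = NULL) {
  preset <- match.arg(preset)
  vals <- switch(preset,
    low    = c(4L, 2L),
    medium = c(7L, 4L),
    high   = c(14L, 7L),
    custom = c(as.integer(min_total), as.integer(min_canonical))
  )
  if (preset == "custom" && (length(vals) != 2L || anyNA(vals)))
    stop("custom stringency needs both min_total and min_canonical")
  if (vals[2L] > vals[1L])
    stop("min_canonical must not exceed min_total")
  structure(list(min_total = vals[1L], min_canonical = vals[2L],
                 preset = preset),
            class = "stringency")
}

#' @export
print.stringency <- function(x, ...) {
  cat(sprintf("stringency '%s': >=%d total repeats, >=%d canonical\n",
              x$preset, x$min_total, x$min_canonical))
  invisible(x)
}

# reverse complement for plain uppercase DNA character vectors
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
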