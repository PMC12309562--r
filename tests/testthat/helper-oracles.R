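# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's scanning code paths.

# reverse complement, independent of the package helper
rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
        collapse = "")
}

# Maximum-count non-overlapping hexamer tiling by dynamic programming.
# Among tilings with maximal total count, prefers maximal canonical count.
# Returns list(total, canonical) for one motif set (one strand).
dp_tiling <- function(seq, canonical, variants) {
  n <- nchar(seq)
  if (n < 6) return(list(total = 0L, canonical = 0L))
  hex <- substring(seq, 1:(n - 5), 6:n)
  can_at <- hex == canonical
  var_at <- hex %in% variants
  m <- length(hex)
  # encode (total, canonical) as total * 1e4 + canonical
  best <- integer(m + 6)
  for (i in m:1) {
    v <- best[i + 1]
    if (can_at[i]) v <- max(v, 10001L + best[min(i + 6, m + 6)])
    if (var_at[i]) v <- max(v, 10000L + best[min(i + 6, m + 6)])
    best[i] <- v
  }
  list(total = best[1] %/% 10000L, canonical = best[1] %% 10000L)
}

# strand-resolved oracle matching the package's strand rule (larger total,
# tie -> G) but with exhaustive DP counting instead of a greedy scan
oracle_count <- function(seq, motifs) {
  seq <- toupper(seq)
  g <- dp_tiling(seq, motifs$canonical_g, motifs$variant_g)
  c_ <- dp_tiling(seq, motifs$canonical_c, motifs$variant_c)
  if (c_$total > g$total) c(c_, strand = "C") else c(g, strand = "G")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mosaic of telomere repeat hexamers and random spacers: exercises the
# scanner on realistic part-telomeric reads
rand_mosaic <- function(max_len = 120, motifs = telomere_motifs()) {
  pool <- c(motifs$canonical_g, motifs$canonical_c,
            motifs$variant_g, motifs$variant_c)
  parts <- character(0)
  len <- 0
  while (len < max_len) {
    if (runif(1) < 0.6) {
      p <- sample(pool, 1)
    } else {
      p <- rand_dna(sample(1:7, 1))
    }
    parts <- c(parts, p)
    len <- len + nchar(p)
  }
  substr(paste(parts, collapse = ""), 1, max_len)
}

# exhaustive 2/N pair enumeration oracle: dense symmetric matrix of
# unordered-pair weights (diagonal = same-bin pairs)
enumerate_matrix <- function(member_bins_by_cluster, n_bins) {
  W <- matrix(0, n_bins, n_bins)
  for (bins in member_bins_by_cluster) {
    n <- length(bins)
    if (n < 2) next
    w <- 2 / n
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        a <- min(bins[i], bins[j])
        b <- max(bins[i], bins[j])
        W[a, b] <- W[a, b] + w
      }
    }
  }
  out <- W + t(W)
  diag(out) <- diag(W)
  out
}

# random small cluster set over a toy genome, as a mapped-read data frame
random_clusters <- function(n_clusters, chrom_sizes, max_size = 8,
                            p_tel = 0.2) {
  rows <- lapply(seq_len(n_clusters), function(i) {
    n <- sample(2:max_size, 1)
    ch <- sample(names(chrom_sizes), n, replace = TRUE)
    pos <- floor(runif(n, 0, chrom_sizes[ch] - 100))
    tel <- runif(n) < p_tel
    data.frame(barcode = sprintf("C%04d", i),
               chrom = ifelse(tel, "chrT", ch),
               start = ifelse(tel, 0, pos),
               end = ifelse(tel, 1, pos + 90),
               mapq = 60L, strand = "*", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

granges_from_bed3 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
}
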