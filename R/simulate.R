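#' Toy genome for synthetic SPRITE and long-read data
#'
#' Six chromosomes of 40-60 Mb (300 Mb total) with: a 100-kb telomeric
#' tract anchored at both natural ends of every chromosome, thirteen
#' 50-kb interstitial (ectopic) telomeric tracts, and one centromere
#' interval per chromosome. The arms are kept long so that the first ten
#' distance classes (at 1 Mb binning) lie well clear of the chromosome
#' midpoints, and twelve chromosome ends contribute to every distance
#' class; interstitial tracts sit at distance classes 18 and beyond so
#' their heavy-tailed local contact spillover stays clear of the first
#' ten classes. Some tracts lie adjacent to centromeres, mirroring the
#' tendency of ectopic telomere repeats to occur near centromeric
#' sequence.
#'
#' @param end_tract Natural-end tract length in bp.
#' @param interstitial_tract Interstitial tract length in bp.
#' @return A \code{sim_genome} object: list with \code{chrom_sizes},
#'   \code{tracts} (chrom, start, end, kind), \code{centromeres}.
#' @export
sim_genome <- function(end_tract = 100e3, interstitial_tract = 50e3) {
  chrom_sizes <- c(chrA = 60e6, chrB = 55e6, chrC = 50e6, chrD = 50e6,
                   chrE = 45e6, chrF = 40e6)
  ends <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    L <- chrom_sizes[[ch]]
    data.frame(chrom = ch, start = c(0, L - end_tract),
               end = c(end_tract, L), kind = "end",
               stringsAsFactors = FALSE)
  }))
  inter_pos <- list(
    chrA = c(18.2e6, 22.3e6, 30.4e6),
    chrB = c(18.3e6, 23.4e6, 29.2e6),
    chrC = c(18.4e6, 27.3e6),
    chrD = c(19.3e6, 26.2e6),
    chrE = c(18.3e6, 23.2e6),
    chrF = c(17.4e6))
  inter <- do.call(rbind, lapply(names(inter_pos), function(ch) {
    data.frame(chrom = ch, start = inter_pos[[ch]],
               end = inter_pos[[ch]] + interstitial_tract,
               kind = "interstitial", stringsAsFactors = FALSE)
  }))
  centromeres <- data.frame(
    chrom = c("chrA", "chrB", "chrC", "chrD", "chrE", "chrF"),
    start = c(27e6, 25e6, 23e6, 24.5e6, 21.5e6, 19e6),
    end = c(28.5e6, 26.5e6, 24.5e6, 26e6, 23e6, 20.5e6),
    stringsAsFactors = FALSE)
  structure(list(chrom_sizes = chrom_sizes,
                 tracts = rbind(ends, inter),
                 centromeres = centromeres),
            class = "sim_genome")
}

#' Parameters of the synthetic SPRITE generator
#'
#' Cluster sizes are log-uniform between \code{size_min} and
#' \code{size_max}; members scatter around a uniformly drawn anchor with a
#' heavy-tailed (Pareto-like) displacement of scale \code{decay_scale} and
#' tail exponent \code{decay_alpha}, reproducing the precipitous decay of
#' contact frequency with linear distance. Members falling in a planted
#' telomeric tract become chrT reads with probability
#' \code{tel_emission}, multiplied by \code{cen_affinity} for clusters
#' anchored inside a centromere interval.
#'
#' @param n_clusters Number of clusters.
#' @param size_min,size_max Cluster-size bounds.
#' @param decay_scale Displacement scale in bp.
#' @param decay_alpha Pareto tail exponent.
#' @param tel_emission Telomere emission probability for in-tract members.
#' @param cen_affinity Emission multiplier for centromere-anchored
#'   clusters.
#' @return A \code{sim_sprite_params} list.
#' @export
sim_sprite_params <- function(n_clusters = 50000L, size_min = 2L,
                              size_max = 200L, decay_scale = 5e5,
                              decay_alpha = 0.65, tel_emission = 0.8,
                              cen_affinity = 3) {
  stopifnot(n_clusters >= 1L, size_min >= 1L, size_max >= size_min,
            decay_scale >= 0, decay_alpha > 0, tel_emission >= 0,
            cen_affinity > 0)
  structure(list(n_clusters = as.integer(n_clusters),
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 decay_scale = decay_scale, decay_alpha = decay_alpha,
                 tel_emission = tel_emission, cen_affinity = cen_affinity),
            class = "sim_sprite_params")
}

#' Simulate SPRITE clusters with planted telomeric tracts
#'
#' @param genome A \code{\link{sim_genome}}.
#' @param params A \code{\link{sim_sprite_params}}.
#' @param seed Integer seed; fixes all output.
#' @return List with \code{reads} (mapped-read data frame ready for
#'   \code{\link{build_clusters}}) and \code{truth} (genome, per-cluster
#'   size table, number of chrT reads emitted, per-read tract flags).
#' @export
simulate_sprite <- function(genome = sim_genome(),
                            params = sim_sprite_params(), seed = 1L) {
  set.seed(seed)
  sizes <- pmin(params$size_max,
                floor(exp(stats::runif(params$n_clusters,
                                       log(params$size_min),
                                       log(params$size_max + 1)))))
  sizes <- as.integer(sizes)
  n_mem <- sum(sizes)
  cid <- rep.int(seq_along(sizes), sizes)

  L <- genome$chrom_sizes
  cumlen <- cumsum(as.numeric(L))
  anchor_lin <- stats::runif(params$n_clusters, 0, cumlen[length(cumlen)])
  ci <- findInterval(anchor_lin, c(0, cumlen), rightmost.closed = TRUE)
  anchor_chrom <- names(L)[ci]
  anchor_pos <- anchor_lin - c(0, cumlen)[ci]

  Lm <- as.numeric(L[anchor_chrom])[cid]
  u <- stats::runif(n_mem)
  mag <- params$decay_scale * ((1 - u)^(-1 / params$decay_alpha) - 1)
  mag <- pmin(mag, Lm - 1)
  pos <- anchor_pos[cid] + ifelse(stats::runif(n_mem) < 0.5, -1, 1) * mag
  pos <- ifelse(pos < 0, -pos, pos)
  pos <- ifelse(pos > Lm - 1, 2 * (Lm - 1) - pos, pos)
  pos <- floor(pos)
  chrom <- anchor_chrom[cid]

  in_tract <- logical(n_mem)
  tr <- genome$tracts
  for (i in seq_len(nrow(tr))) {
    in_tract <- in_tract | (chrom == tr$chrom[i] & pos >= tr$start[i] &
                              pos < tr$end[i])
  }
  cen <- genome$centromeres
  anchored_cen <- logical(params$n_clusters)
  for (i in seq_len(nrow(cen))) {
    anchored_cen <- anchored_cen | (anchor_chrom == cen$chrom[i] &
                                      anchor_pos >= cen$start[i] &
                                      anchor_pos < cen$end[i])
  }
  p_emit <- pmin(1, params$tel_emission *
                   ifelse(anchored_cen[cid], params$cen_affinity, 1))
  is_tel <- in_tract & (stats::runif(n_mem) < p_emit)

  reads <- data.frame(
    barcode = sprintf("BC%06d", cid),
    chrom = ifelse(is_tel, "chrT", chrom),
    start = ifelse(is_tel, 0, pos),
    end = ifelse(is_tel, 1, pmin(pos + 90, Lm)),
    mapq = 60L,
    strand = "*",
    stringsAsFactors = FALSE)
  truth <- list(
    genome = genome,
    cluster_sizes = data.frame(barcode = sprintf("BC%06d", seq_along(sizes)),
                               size = sizes, stringsAsFactors = FALSE),
    n_tel_reads = sum(is_tel),
    tel_source = data.frame(chrom = chrom[is_tel], pos = pos[is_tel],
                            stringsAsFactors = FALSE),
    in_tract = in_tract)
  list(reads = reads, truth = truth)
}

#' Simulate a barcode-annotated read stream with planted telomeric reads
#'
#' Telomeric reads are tandem hexamer repeats (random strand, random phase
#' offset, a fraction of hexamers substituted by variant repeats);
#' non-telomeric reads are uniform random DNA. Read names carry a barcode
#' token after \code{"::"}.
#'
#' @param n_reads Number of records.
#' @param tel_fraction Planted telomeric fraction.
#' @param read_length Read length in bp (default 90, the genomic-DNA yield
#'   of a SPRITE read).
#' @param variant_rate Per-hexamer variant substitution probability in
#'   telomeric reads.
#' @param n_barcodes Barcode pool size.
#' @param seed Integer seed.
#' @return List with \code{names}, \code{seqs}, \code{telomeric} (truth
#'   flags).
#' @export
simulate_read_stream <- function(n_reads = 1000L, tel_fraction = 0.1,
                                 read_length = 90L, variant_rate = 0.2,
                                 n_barcodes = 100L, seed = 1L) {
  set.seed(seed)
  motifs <- telomere_motifs()
  telomeric <- stats::runif(n_reads) < tel_fraction
  seqs <- character(n_reads)
  n_hex <- ceiling(read_length / 6) + 1L
  for (i in which(telomeric)) {
    g_strand <- stats::runif(1) < 0.5
    can <- if (g_strand) motifs$canonical_g else motifs$canonical_c
    var <- if (g_strand) motifs$variant_g else motifs$variant_c
    hexes <- ifelse(stats::runif(n_hex) < variant_rate,
                    sample(var, n_hex, replace = TRUE), can)
    phase <- sample.int(6L, 1L) - 1L
    seqs[i] <- substr(paste(hexes, collapse = ""), phase + 1L,
                      phase + read_length)
  }
  n_bg <- sum(!telomeric)
  if (n_bg > 0L) {
    seqs[!telomeric] <- vapply(seq_len(n_bg), function(i) {
      paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
            collapse = "")
    }, character(1L))
  }
  bc <- sprintf("BC%04d", sample.int(n_barcodes, n_reads, replace = TRUE))
  list(names = sprintf("read%06d::%s", seq_len(n_reads), bc),
       seqs = seqs, telomeric = telomeric)
}

#' Write a read stream as FASTQ
#'
#' @param stream List with \code{names} and \code{seqs} (e.g. from
#'   \code{\link{simulate_read_stream}}).
#' @param path Output FASTQ path (gzip by extension).
#' @return Invisibly, \code{path}.
#' @export
write_read_stream <- function(stream, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stream$seqs),
    Biostrings::PhredQuality(strrep("I", nchar(stream$seqs))))
  names(x) <- stream$names
  write_fastq(x, path)
}

#' Simulate long-read alignments with soft-clipped telomere tracts
#'
#' Plants \code{n_loci} insertion loci (each supported by
#' \code{reads_per_locus} reads with tandem-repeat soft clips of
#' \code{clip_length} bp, MAPQ 60, more than 1 Mb from chromosome ends)
#' plus, optionally, decoy reads that each violate exactly one calling
#' rule: single-support loci, MAPQ-29 reads, loci 99 kb from a chromosome
#' end, telomere tracts inside the aligned portion (no soft clip),
#' 200-bp clips too short for the scan window, and poorly mapped loci
#' where half the overlapping unfiltered reads have MAPQ below 10.
#'
#' @param genome A \code{\link{sim_genome}}.
#' @param n_loci Number of planted (true) loci.
#' @param reads_per_locus Supporting reads per planted locus.
#' @param clip_length Soft-clip length in bp.
#' @param aligned_length Aligned span per read in bp.
#' @param mapq MAPQ of planted supporting reads.
#' @param jitter Maximum insertion-position jitter per read in bp.
#' @param decoys Include the decoy classes.
#' @param seed Integer seed.
#' @return List with \code{alignments} (candidate reads), \code{unfiltered}
#'   (alignments plus background coverage, for the mappability filter) and
#'   \code{truth} (\code{loci}, \code{decoys} with intended rejection
#'   reason).
#' @export
simulate_long_reads <- function(genome = sim_genome(), n_loci = 20L,
                                reads_per_locus = 3L, clip_length = 400L,
                                aligned_length = 5000L, mapq = 60L,
                                jitter = 30L, decoys = TRUE, seed = 1L) {
  set.seed(seed)
  L <- genome$chrom_sizes
  pick_positions <- function(n, min_gap = 5e5) {
    out <- NULL
    while (is.null(out) || nrow(out) < n) {
      ch <- sample(names(L), 1L)
      p <- floor(stats::runif(1, 1.2e6, L[[ch]] - 1.2e6))
      if (!is.null(out) &&
          any(out$chrom == ch & abs(out$pos - p) < min_gap)) next
      out <- rbind(out, data.frame(chrom = ch, pos = p,
                                   stringsAsFactors = FALSE))
    }
    out
  }
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  aln_rows <- list()
  bg_rows <- list()
  make_read <- function(id, chrom, ipos, side, q, clip, tract_in_aligned = FALSE) {
    if (tract_in_aligned) {
      start <- ipos - aligned_length
      tract <- substr(strrep("TTAGGG", ceiling(clip / 6)), 1L, clip)
      seqs <- paste0(rand_dna(2000L), tract,
                     rand_dna(aligned_length - 2000L - clip))
      return(data.frame(read_id = id, chrom = chrom, start = start,
                        end = ipos, mapq = q, clip_left = 0L,
                        clip_right = 0L, seq = seqs, primary = TRUE,
                        stringsAsFactors = FALSE))
    }
    tract <- strrep(if (side == "right") "TTAGGG" else "CCCTAA",
                    ceiling(clip / 6))
    tract <- substr(tract, 1L, clip)
    if (side == "right") {
      data.frame(read_id = id, chrom = chrom, start = ipos - aligned_length,
                 end = ipos, mapq = q, clip_left = 0L, clip_right = clip,
                 seq = paste0(rand_dna(aligned_length), tract),
                 primary = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(read_id = id, chrom = chrom, start = ipos,
                 end = ipos + aligned_length, mapq = q, clip_left = clip,
                 clip_right = 0L,
                 seq = paste0(tract, rand_dna(aligned_length)),
                 primary = TRUE, stringsAsFactors = FALSE)
    }
  }
  add_background <- function(chrom, pos, n_good = 8L, n_poor = 0L) {
    n <- n_good + n_poor
    data.frame(read_id = sprintf("bg_%s_%d_%d", chrom, pos, seq_len(n)),
               chrom = chrom,
               start = pos - 2000L + floor(stats::runif(n, 0, 1000)),
               end = pos + 1000L + floor(stats::runif(n, 0, 1000)),
               mapq = c(rep(60L, n_good), rep(5L, n_poor)),
               clip_left = 0L, clip_right = 0L, seq = NA_character_,
               primary = TRUE, stringsAsFactors = FALSE)
  }

  loci <- pick_positions(n_loci)
  loci$side <- rep(c("right", "left"), length.out = n_loci)
  loci$orientation <- "standard"
  for (i in seq_len(n_loci)) {
    for (j in seq_len(reads_per_locus)) {
      ipos <- loci$pos[i] + sample.int(2L * jitter + 1L, 1L) - jitter - 1L
      aln_rows[[length(aln_rows) + 1L]] <-
        make_read(sprintf("locus%02d_read%d", i, j), loci$chrom[i], ipos,
                  loci$side[i], mapq, clip_length)
    }
    bg_rows[[length(bg_rows) + 1L]] <- add_background(loci$chrom[i],
                                                      loci$pos[i])
  }

  decoy_truth <- NULL
  if (decoys) {
    dk <- pick_positions(9L)
    add_decoy <- function(row, reason) {
      decoy_truth <<- rbind(decoy_truth,
                            data.frame(chrom = row$chrom, pos = row$pos,
                                       reason = reason,
                                       stringsAsFactors = FALSE))
    }
    # single supporting read
    for (i in 1:3) {
      aln_rows[[length(aln_rows) + 1L]] <-
        make_read(sprintf("single%02d_read1", i), dk$chrom[i], dk$pos[i],
                  "right", mapq, clip_length)
      bg_rows[[length(bg_rows) + 1L]] <- add_background(dk$chrom[i], dk$pos[i])
      add_decoy(dk[i, ], "single_support")
    }
    # low-MAPQ supporting reads
    for (i in 4:5) {
      for (j in seq_len(reads_per_locus)) {
        aln_rows[[length(aln_rows) + 1L]] <-
          make_read(sprintf("lowmapq%02d_read%d", i, j), dk$chrom[i],
                    dk$pos[i] + j, "right", 29L, clip_length)
      }
      bg_rows[[length(bg_rows) + 1L]] <- add_background(dk$chrom[i], dk$pos[i])
      add_decoy(dk[i, ], "low_mapq")
    }
    # telomere tract inside the aligned portion (no soft clip)
    for (j in 1:3) {
      aln_rows[[length(aln_rows) + 1L]] <-
        make_read(sprintf("aligned_read%d", j), dk$chrom[6L], dk$pos[6L] + j,
                  "right", mapq, clip_length, tract_in_aligned = TRUE)
    }
    bg_rows[[length(bg_rows) + 1L]] <- add_background(dk$chrom[6L], dk$pos[6L])
    add_decoy(dk[6L, ], "aligned_tract")
    # clip too short for the 300-bp window
    for (i in 7:8) {
      for (j in 1:3) {
        aln_rows[[length(aln_rows) + 1L]] <-
          make_read(sprintf("short%02d_read%d", i, j), dk$chrom[i],
                    dk$pos[i] + j, "right", mapq, 200L)
      }
      bg_rows[[length(bg_rows) + 1L]] <- add_background(dk$chrom[i], dk$pos[i])
      add_decoy(dk[i, ], "short_clip")
    }
    # poorly mapped locus: half the unfiltered coverage below MAPQ 10
    for (j in 1:3) {
      aln_rows[[length(aln_rows) + 1L]] <-
        make_read(sprintf("poormap_read%d", j), dk$chrom[9L], dk$pos[9L] + j,
                  "right", mapq, clip_length)
    }
    bg_rows[[length(bg_rows) + 1L]] <- add_background(dk$chrom[9L],
                                                      dk$pos[9L],
                                                      n_good = 5L, n_poor = 5L)
    add_decoy(dk[9L, ], "poor_mappability")
    # near-end locus, 99 kb from the chromosome start
    ch <- names(L)[1L]
    near <- data.frame(chrom = ch, pos = 99000L, stringsAsFactors = FALSE)
    for (j in 1:2) {
      aln_rows[[length(aln_rows) + 1L]] <-
        make_read(sprintf("nearend_read%d", j), ch, near$pos + j, "left",
                  mapq, clip_length)
    }
    bg_rows[[length(bg_rows) + 1L]] <- add_background(ch, near$pos)
    add_decoy(near, "near_chromosome_end")
  }

  alignments <- do.call(rbind, aln_rows)
  unfiltered <- rbind(alignments[, c("read_id", "chrom", "start", "end",
                                     "mapq")],
                      do.call(rbind, bg_rows)[, c("read_id", "chrom",
                                                  "start", "end", "mapq")])
  list(alignments = alignments, unfiltered = unfiltered,
       truth = list(loci = loci, decoys = decoy_truth))
}

#' Write long-read alignments as SAM
#'
#' Minimal SAM with @SQ headers; soft clips are encoded in the CIGAR and
#' the stored sequence spans clips plus aligned portion.
#'
#' @param alignments Alignment data frame (see
#'   \code{\link{simulate_long_reads}}).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param path Output SAM path.
#' @return Invisibly, \code{path}.
#' @export
write_sam_alignments <- function(alignments, chrom_sizes, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                   as.integer(chrom_sizes)))
  a <- alignments[order(alignments$chrom, alignments$start,
                        method = "radix"), , drop = FALSE]
  if (is.null(a$clip_left)) a$clip_left <- 0L
  if (is.null(a$clip_right)) a$clip_right <- 0L
  if (is.null(a$seq)) a$seq <- NA_character_
  m_len <- a$end - a$start
  cigar <- paste0(ifelse(a$clip_left > 0L, paste0(a$clip_left, "S"), ""),
                  m_len, "M",
                  ifelse(a$clip_right > 0L, paste0(a$clip_right, "S"), ""))
  seqs <- a$seq
  # records without stored sequence (coverage-only) get placeholder bases
  no_seq <- is.na(seqs)
  seqs[no_seq] <- strrep("A", m_len[no_seq])
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                   a$read_id, 0L, a$chrom, as.integer(a$start) + 1L,
                   as.integer(a$mapq), cigar, seqs)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Simulate a multi-channel FISH nucleus image
#'
#' Disk-shaped nuclei in the DNA channel on a dark background; centromere
#' spots uniform within each nucleus (kept 8 px from the rim so their
#' adjacency neighborhoods stay inside the mask); a stated fraction of
#' telomere spots placed within 3.5 px of a randomly chosen centromere
#' spot, the remainder uniform over the nucleus. Spots are Gaussian with
#' enough bright area to exceed the 9-px focus threshold after Multi-Otsu
#' segmentation.
#'
#' @param shape Image dimensions c(rows, cols).
#' @param n_nuclei Number of nuclei.
#' @param n_tel,n_cen Telomere and centromere spots per nucleus.
#' @param adjacency_fraction Fraction of telomere spots planted adjacent to
#'   a centromere.
#' @param nucleus_radius Nucleus disk radius in px.
#' @param spot_sigma Gaussian spot width in px.
#' @param seed Integer seed.
#' @return List with channels \code{dna}, \code{tel}, \code{cen} and
#'   \code{truth} (planted nucleus centers and spot positions).
#' @export
simulate_fish_image <- function(shape = c(256L, 256L), n_nuclei = 2L,
                                n_tel = 40L, n_cen = 12L,
                                adjacency_fraction = 0,
                                nucleus_radius = 45, spot_sigma = 2.2,
                                seed = 1L) {
  set.seed(seed)
  nr <- shape[1L]; nc <- shape[2L]
  margin <- nucleus_radius + 4
  centers <- NULL
  tries <- 0L
  while (is.null(centers) || nrow(centers) < n_nuclei) {
    if ((tries <- tries + 1L) > 1000L)
      stop("cannot place ", n_nuclei, " non-overlapping nuclei in the image")
    p <- c(stats::runif(1, margin, nr - margin),
           stats::runif(1, margin, nc - margin))
    if (!is.null(centers) &&
        any((centers[, 1L] - p[1L])^2 + (centers[, 2L] - p[2L])^2 <
              (2 * nucleus_radius + 6)^2)) next
    centers <- rbind(centers, p)
  }
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dna <- matrix(stats::runif(nr * nc, 0, 0.03), nr, nc)
  tel <- matrix(stats::runif(nr * nc, 0, 0.02), nr, nc)
  cen <- matrix(stats::runif(nr * nc, 0, 0.02), nr, nc)
  in_disk <- function(p, r) (rows - p[1L])^2 + (cols - p[2L])^2 <= r^2
  stamp <- function(img, y, x, amp, sigma = spot_sigma) {
    half <- as.integer(ceiling(3 * sigma))
    r0 <- max(1L, floor(y) - half); r1 <- min(nr, floor(y) + half)
    c0 <- max(1L, floor(x) - half); c1 <- min(nc, floor(x) + half)
    rr <- r0:r1; cc <- c0:c1
    k <- exp(-(outer((rr - y)^2, (cc - x)^2, "+")) / (2 * sigma^2))
    img[rr, cc] <- img[rr, cc] + amp * k
    img
  }
  unif_in_disk <- function(p, r) {
    th <- stats::runif(1, 0, 2 * pi)
    rad <- r * sqrt(stats::runif(1))
    c(p[1L] + rad * sin(th), p[2L] + rad * cos(th))
  }
  # uniform draws with a minimum spacing so distinct foci stay resolvable
  # (real FISH foci are diffraction-limited separable objects)
  place_spaced <- function(n, p, r, min_d = 7) {
    out <- matrix(numeric(0L), 0L, 2L)
    tries <- 0L
    while (nrow(out) < n && tries < 4000L) {
      tries <- tries + 1L
      q <- unif_in_disk(p, r)
      if (nrow(out) == 0L ||
          min((out[, 1L] - q[1L])^2 + (out[, 2L] - q[2L])^2) >= min_d^2)
        out <- rbind(out, q)
    }
    out
  }
  truth <- list()
  for (i in seq_len(n_nuclei)) {
    p <- centers[i, ]
    dna[in_disk(p, nucleus_radius)] <- dna[in_disk(p, nucleus_radius)] + 0.35
    # bright chromocenter-like speckles make the DNA histogram trimodal,
    # as in real DAPI fields (background / nucleoplasm / heterochromatin)
    for (j in 1:8) {
      q <- unif_in_disk(p, nucleus_radius - 6)
      dna <- stamp(dna, q[1L], q[2L], 0.5, sigma = 3)
    }
    cen_pos <- place_spaced(n_cen, p, nucleus_radius - 8)
    adj <- stats::runif(n_tel) < adjacency_fraction
    # non-adjacent telomeres are iid uniform over the full nuclear disk:
    # the randomization test's null is iid uniformity over the mask, so
    # the planted distribution must match it exactly (no spacing)
    tel_uniform <- t(vapply(seq_len(sum(!adj)), function(j) {
      unif_in_disk(p, nucleus_radius)
    }, numeric(2L)))
    if (sum(!adj) == 0L) tel_uniform <- matrix(numeric(0L), 0L, 2L)
    tel_pos <- matrix(numeric(0L), 0L, 2L)
    ui <- 0L
    for (j in seq_len(n_tel)) {
      tel_pos <- rbind(tel_pos, if (adj[j] && nrow(cen_pos) > 0L) {
        anchor <- cen_pos[sample.int(nrow(cen_pos), 1L), ]
        unif_in_disk(anchor, 3.5)
      } else {
        ui <- ui + 1L
        tel_uniform[ui, ]
      })
    }
    amp_c <- stats::runif(nrow(cen_pos), 0.9, 1.1)
    amp_t <- stats::runif(nrow(tel_pos), 0.9, 1.1)
    for (j in seq_len(nrow(cen_pos)))
      cen <- stamp(cen, cen_pos[j, 1L], cen_pos[j, 2L], amp_c[j])
    for (j in seq_len(nrow(tel_pos)))
      tel <- stamp(tel, tel_pos[j, 1L], tel_pos[j, 2L], amp_t[j])
    truth[[i]] <- list(center = p, tel = tel_pos, cen = cen_pos,
                       adjacent = adj)
  }
  list(dna = dna, tel = tel, cen = cen, truth = truth)
}

#' Write a simulated FISH image as multi-frame TIFF
#'
#' Frames: DNA, telomere, centromere (clipped to [0, 1]).
#'
#' @param image List with \code{dna}, \code{tel}, \code{cen}.
#' @param path Output TIFF path.
#' @return Invisibly, \code{path}.
#' @export
write_fish_image <- function(image, path) {
  arr <- array(c(pmin(image$dna, 1), pmin(image$tel, 1),
                 pmin(image$cen, 1)),
               c(dim(image$dna), 3L))
  EBImage::writeImage(EBImage::Image(arr), path, type = "tiff")
  invisible(path)
}
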