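test_that("the 300-bp window scan applies the 45-repeat threshold", {
  # 66 tandem canonical copies: the best window holds 300/6 = 50 repeats
  hit <- scan_telomere_window(strrep("TTAGGG", 66))
  expect_equal(hit$count, 50L)
  expect_equal(hit$strand, "G")
  expect_equal(hit$offset, 0L)
  # 44 repeats embedded in a 300-bp stretch fail the threshold
  set.seed(14)
  s44 <- paste0(strrep("TTAGGG", 44), rand_dna(36))
  expect_equal(nchar(s44), 300L)
  expect_null(scan_telomere_window(s44))
  # sequences shorter than the window are ineligible
  expect_null(scan_telomere_window(strrep("TTAGGG", 49)))
  # C-strand windows are found symmetrically
  expect_equal(scan_telomere_window(strrep("CCCTAA", 66))$strand, "C")
})

test_that("window counts match a brute-force scan over mosaics", {
  motifs <- telomere_motifs()
  # independent oracle: DP tiling count inside every window anchored at a
  # canonical match, per strand
  oracle_window <- function(seq) {
    seq <- toupper(seq)
    n <- nchar(seq)
    if (n < 300) return(NULL)
    best <- NULL
    for (strand in c("G", "C")) {
      can <- if (strand == "G") motifs$canonical_g else motifs$canonical_c
      var <- if (strand == "G") motifs$variant_g else motifs$variant_c
      hex <- substring(seq, 1:(n - 5), 6:n)
      for (a in which(hex == can)) {
        if (a + 299 > n) next
        cnt <- dp_tiling(substr(seq, a, a + 299), can, var)$total
        if (is.null(best) || cnt > best) best <- cnt
      }
    }
    best
  }
  set.seed(23)
  for (i in 1:15) {
    parts <- lapply(1:8, function(j) {
      if (runif(1) < 0.6) strrep(sample(c("TTAGGG", "TCAGGG", "CCCTAA"), 1),
                                 sample(5:20, 1))
      else rand_dna(sample(10:80, 1))
    })
    s <- paste(unlist(parts), collapse = "")
    got <- scan_telomere_window(s, min_repeats = 1L)
    want <- oracle_window(s)
    if (is.null(want)) expect_null(got)
    else expect_equal(got$count, want)
  }
})

mk_aln <- function(read_id, chrom = "chrA", start, end, mapq = 60L,
                   clip_left = 0L, clip_right = 0L, seq = NA_character_) {
  data.frame(read_id = read_id, chrom = chrom, start = start, end = end,
             mapq = mapq, clip_left = clip_left, clip_right = clip_right,
             seq = seq, primary = TRUE, stringsAsFactors = FALSE)
}

test_that("clip classification emits evidence only for clipped tracts", {
  set.seed(31)
  body <- rand_dna(1000)
  # right soft clip of tandem TTAGGG: standard orientation, insertion at
  # the alignment end
  a <- mk_aln("r1", start = 999000, end = 1000000, clip_right = 400L,
              seq = paste0(body, strrep("TTAGGG", 67)))
  ev <- classify_clip(a)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$position, 1000000)
  expect_equal(ev$side, "right")
  expect_equal(ev$orientation, "standard")
  # left clip of CCCTAA: standard, insertion at alignment start
  b <- mk_aln("r2", start = 500000, end = 501000, clip_left = 400L,
              seq = paste0(strrep("CCCTAA", 67), body))
  evb <- classify_clip(b)
  expect_equal(evb$side, "left")
  expect_equal(evb$position, 500000)
  expect_equal(evb$orientation, "standard")
  # left clip of TTAGGG reads as inverted orientation
  c_ <- mk_aln("r3", start = 500000, end = 501000, clip_left = 400L,
               seq = paste0(strrep("TTAGGG", 67), body))
  expect_equal(classify_clip(c_)$orientation, "inverted")
  # telomere tract inside the aligned portion is ignored
  d <- mk_aln("r4", start = 0, end = 1400,
              seq = paste0(rand_dna(500), strrep("TTAGGG", 67),
                           rand_dna(498)))
  expect_equal(nrow(classify_clip(d)), 0L)
  # a 200-bp clip cannot hold the 300-bp window
  e <- mk_aln("r5", start = 0, end = 1000, clip_right = 200L,
              seq = paste0(body, strrep("TTAGGG", 34)[1:1]))
  e$seq <- paste0(body, substr(strrep("TTAGGG", 34), 1, 200))
  expect_equal(nrow(classify_clip(e)), 0L)
  # sequence-less records are skipped with a warning
  expect_warning(out <- classify_clip(mk_aln("r6", start = 0, end = 100)),
                 "sequence")
  expect_equal(nrow(out), 0L)
})

test_that("locus mappability uses the >= 40 percent low-MAPQ rule", {
  mk_cov <- function(n_low, n_high) {
    data.frame(chrom = "chrA", start = 0L, end = 1000L,
               mapq = c(rep(5L, n_low), rep(60L, n_high)))
  }
  expect_false(locus_mappability_filter("chrA", 500, mk_cov(4, 6)))
  expect_true(locus_mappability_filter("chrA", 500, mk_cov(3, 7)))
  expect_false(locus_mappability_filter("chrA", 500, mk_cov(1, 1)[0, ]))
  # overlap means the span contains the position
  cov <- mk_cov(0, 5)
  expect_false(locus_mappability_filter("chrA", 1000, cov))  # end-exclusive
  expect_true(locus_mappability_filter("chrA", 999, cov))
})

test_that("locus calling merges, filters ends and requires support", {
  sizes <- c(chrA = 10e6)
  cov <- data.frame(chrom = "chrA", start = 0L, end = 10e6, mapq = 60L)
  ev <- function(id, pos, mapq = 60L) {
    data.frame(read_id = id, chrom = "chrA", position = pos,
               side = "right", orientation = "standard",
               window_count = 50L, mapq = mapq, stringsAsFactors = FALSE)
  }
  # two reads 80 bp apart merge into one locus
  loci <- call_ectopic_loci(rbind(ev("a", 500000), ev("b", 500080)),
                            sizes, cov)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$position, 500040)
  expect_equal(loci$n_reads, 2L)
  # 101 bp apart: two chains, each unsupported
  loci2 <- call_ectopic_loci(rbind(ev("a", 500000), ev("b", 500101)),
                             sizes, cov)
  expect_equal(nrow(loci2), 0L)
  # a single read never calls a locus
  expect_equal(nrow(call_ectopic_loci(ev("a", 500000), sizes, cov)), 0L)
  # duplicate read ids count once toward support
  expect_equal(nrow(call_ectopic_loci(rbind(ev("a", 500000),
                                            ev("a", 500050)),
                                      sizes, cov)), 0L)
  # low-MAPQ evidence is dropped before merging
  expect_equal(nrow(call_ectopic_loci(rbind(ev("a", 500000),
                                            ev("b", 500050, mapq = 29L)),
                                      sizes, cov)), 0L)
  # positions within 100 kb of either end are excluded
  expect_equal(nrow(call_ectopic_loci(rbind(ev("a", 99999), ev("b", 99999)),
                                      sizes, cov)), 0L)
  expect_equal(nrow(call_ectopic_loci(rbind(ev("a", 9.95e6),
                                            ev("b", 9.95e6 + 10)),
                                      sizes, cov)), 0L)
  # output is invariant to evidence row order
  e3 <- rbind(ev("a", 500000), ev("b", 500080), ev("c", 2e6),
              ev("d", 2e6 + 5))
  l_fwd <- call_ectopic_loci(e3, sizes, cov)
  l_rev <- call_ectopic_loci(e3[4:1, ], sizes, cov)
  expect_identical(l_fwd, l_rev)
})

test_that("the caller recovers exactly the planted loci among decoys", {
  sim <- simulate_long_reads(n_loci = 8L, seed = 42)
  ev <- classify_clips(sim$alignments)
  loci <- call_ectopic_loci(ev, sim_genome()$chrom_sizes, sim$unfiltered)
  truth <- sim$truth$loci
  # precision and recall both 1: every call matches a planted locus
  expect_equal(nrow(loci), nrow(truth))
  match_dist <- vapply(seq_len(nrow(loci)), function(i) {
    min(abs(truth$pos[truth$chrom == loci$chrom[i]] - loci$position[i]))
  }, numeric(1))
  expect_true(all(match_dist <= 100))
  # every decoy class is absent from the calls for its intended reason
  dk <- sim$truth$decoys
  for (i in seq_len(nrow(dk))) {
    near <- loci$chrom == dk$chrom[i] & abs(loci$position - dk$pos[i]) < 1000
    expect_false(any(near), info = dk$reason[i])
  }
  expect_setequal(unique(dk$reason),
                  c("single_support", "low_mapq", "aligned_tract",
                    "short_clip", "poor_mappability",
                    "near_chromosome_end"))
})

test_that("gene annotation labels loci by containment of the position", {
  loci <- data.frame(chrom = "chrA", position = c(5000, 50000, 9000),
                     n_reads = 2L, n_left = 0L, n_right = 2L,
                     n_standard = 2L, n_inverted = 0L, read_ids = "a,b",
                     stringsAsFactors = FALSE)
  genes <- granges_from_bed3("chrA", c(4000, 8000, 8500),
                             c(6000, 9500, 9600))
  names(genes) <- c("G1", "G2", "G3")
  ann <- annotate_loci_genes(loci, genes)
  expect_equal(ann$genes, c("G1", "", "G2,G3"))
})

test_that("SAM written alignments read back with identical core fields", {
  dir <- withr::local_tempdir()
  sim <- simulate_long_reads(n_loci = 3L, decoys = FALSE, seed = 7)
  sam <- file.path(dir, "lr.sam")
  write_sam_alignments(sim$alignments, sim_genome()$chrom_sizes, sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "lr"),
                          overwrite = TRUE, indexDestination = TRUE)
  back <- read_long_reads(bam)
  ord <- order(back$read_id)
  orig <- sim$alignments[order(sim$alignments$read_id), ]
  expect_equal(back$read_id[ord], orig$read_id)
  expect_equal(back$start[ord], orig$start)
  expect_equal(back$end[ord], orig$end)
  expect_equal(back$clip_left[ord], orig$clip_left)
  expect_equal(back$clip_right[ord], orig$clip_right)
  expect_equal(back$mapq[ord], orig$mapq)
  # the full caller works identically from the BAM-derived frame
  ev_bam <- classify_clips(back)
  ev_mem <- classify_clips(sim$alignments)
  expect_equal(nrow(ev_bam), nrow(ev_mem))
})
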