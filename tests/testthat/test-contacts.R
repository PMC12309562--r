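toy_binning <- function() genome_binning(c(chr1 = 5e6, chr2 = 3e6), 1e6)

# one cluster as a mapped-read data frame, members given as bin centers
cluster_at <- function(barcode, binning, bins) {
  b <- binning$bins[bins, ]
  data.frame(barcode = barcode, chrom = b$chrom,
             start = ifelse(b$chrom == "chrT", 0, b$start),
             end = ifelse(b$chrom == "chrT", 1, b$start + 90),
             mapq = 60L, strand = "*", stringsAsFactors = FALSE)
}

test_that("cluster weight is 2/n with no pairs below size 2", {
  expect_equal(cluster_weight(2), 1.0)
  expect_equal(cluster_weight(100), 0.02)
  expect_equal(cluster_weight(1), 0)
})

test_that("pair weights match exhaustive enumeration on known clusters", {
  bn <- toy_binning()
  # members in bins A,B (n = 2): single pair at weight 1
  reads <- cluster_at("c1", bn, c(1L, 3L))
  W <- build_matrix(build_clusters(reads), bn)$weights
  expect_equal(W[1, 3], 1.0)
  expect_equal(sum(W), 2.0)  # symmetric storage, one off-diagonal pair
  # members in bins A,A,B,C (n = 4): C(4,2) = 6 pairs at weight 0.5 each;
  # duplicate-position members must differ in start to survive dedup
  reads <- rbind(cluster_at("c2", bn, c(1L, 1L, 2L, 4L)))
  reads$start[2] <- reads$start[2] + 500L
  cm <- build_matrix(build_clusters(reads), bn)
  W <- cm$weights
  expect_equal(W[1, 1], 0.5)
  expect_equal(W[1, 2], 1.0)
  expect_equal(W[1, 4], 1.0)
  expect_equal(W[2, 4], 0.5)
  expect_equal(matrix_mass(cm), 3)  # n - 1
})

test_that("matrix equals the brute-force oracle on random cluster sets", {
  bn <- toy_binning()
  set.seed(31)
  for (rep in 1:3) {
    reads <- random_clusters(40, bn$chrom_sizes)
    cl <- build_clusters(reads)
    cm <- build_matrix(cl, bn)
    bins_by_cluster <- split(
      bin_index(bn, cl$members$chrom, cl$members$start),
      cl$members$barcode)
    # only clusters with >= 2 members contribute
    oracle <- enumerate_matrix(bins_by_cluster, nrow(bn$bins))
    expect_equal(as.matrix(cm$weights), oracle, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("total matrix mass equals sum of (n - 1) over used clusters", {
  sim <- simulate_sprite(params = sim_sprite_params(n_clusters = 2000L),
                         seed = 13)
  cl <- build_clusters(sim$reads)
  bn <- genome_binning(sim$truth$genome$chrom_sizes, 1e6)
  cm <- build_matrix(cl, bn)
  expected <- sum(cl$sizes[cl$sizes >= 2] - 1L)
  expect_equal(matrix_mass(cm), expected, tolerance = 1e-9)
  # symmetry is exact by construction
  expect_identical(Matrix::isSymmetric(cm$weights), TRUE)
  # size bounds restrict the mass accordingly
  cm2 <- build_matrix(cl, bn, min_size = 2L, max_size = 10L)
  sz <- cl$sizes[cl$sizes >= 2 & cl$sizes <= 10]
  expect_equal(matrix_mass(cm2), sum(sz - 1L), tolerance = 1e-9)
})

test_that("fine-resolution matrices aggregate exactly to coarse ones", {
  sim <- simulate_sprite(params = sim_sprite_params(n_clusters = 1500L),
                         seed = 17)
  cl <- build_clusters(sim$reads)
  fine <- build_matrix(cl, genome_binning(sim$truth$genome$chrom_sizes,
                                          1e5))
  direct <- build_matrix(cl, genome_binning(sim$truth$genome$chrom_sizes,
                                            1e6))
  agg <- aggregate_matrix(fine, 1e6)
  expect_equal(agg$binning$bins, direct$binning$bins)
  expect_lt(max(abs(agg$weights - direct$weights)), 1e-9)
})

test_that("telomere track is the chrT row without its diagonal", {
  bn <- toy_binning()
  # no chrT members: zero track
  reads <- cluster_at("c1", bn, c(1L, 2L))
  tr <- telomere_track(build_matrix(build_clusters(reads), bn))
  expect_true(all(tr$track == 0))
  # single {chrT, bin A} cluster: track 1.0 at A
  reads <- cluster_at("c2", bn, c(bn$chrT_index, 2L))
  tr <- telomere_track(build_matrix(build_clusters(reads), bn))
  expect_equal(tr$track[2], 1.0)
  expect_equal(sum(tr$track), 1.0)
  expect_equal(tr$chrT_self, 0)
  expect_equal(length(tr$track), bn$n_genomic)
})

test_that("track maxima colocate with planted telomeric tracts", {
  sim <- simulate_sprite(params = sim_sprite_params(n_clusters = 8000L),
                         seed = 29)
  cl <- build_clusters(sim$reads)
  bn <- genome_binning(sim$truth$genome$chrom_sizes, 1e6)
  tr <- telomere_track(build_matrix(cl, bn))
  g <- sim$truth$genome
  ends <- g$tracts[g$tracts$kind == "end", ]
  inter <- g$tracts[g$tracts$kind == "interstitial", ]
  end_bins <- bin_index(bn, ends$chrom, ends$start)
  inter_bins <- bin_index(bn, inter$chrom, inter$start)
  # raw track maxima sit at the natural chromosome ends
  expect_true(which.max(tr$track) %in% end_bins)
  expect_true(all(end_bins %in% order(tr$track, decreasing = TRUE)[1:30]))
  # interstitial tracts stand out once the end-distance effect is removed
  nt <- distance_normalize(tr)
  others <- setdiff(which(!is.na(nt$track)), c(end_bins, inter_bins))
  expect_gt(mean(nt$track[inter_bins]), 1.2)
  expect_gt(mean(nt$track[inter_bins]), mean(nt$track[others]))
})

test_that("cluster profiles binarize member occupancy over fine bins", {
  bn <- toy_binning()
  reads <- rbind(cluster_at("c1", bn, c(1L, 1L, bn$chrT_index)),
                 cluster_at("c2", bn, c(1L, 2L)))
  reads$start[2] <- 60000L  # second member of c1 in another fine bin
  cl <- build_clusters(reads)
  prof <- cluster_profile(cl, "chr1", 0L, 1e6, fine_resolution = 25000L)
  expect_equal(nrow(prof), 2L)
  expect_equal(ncol(prof), 40L)
  expect_equal(sum(prof["c1", ]), 2L)
  expect_equal(sum(prof["c2", ]), 1L)
  # chrT requirement drops clusters without telomere members
  prof_t <- cluster_profile(cl, "chr1", 0L, 1e6, 25000L,
                            require_chrT = TRUE)
  expect_equal(rownames(prof_t), "c1")
  # empty selection is an empty table, not an error
  prof_0 <- cluster_profile(cl, "chr2", 0L, 1e6, 25000L,
                            max_cluster_size = 1L)
  expect_equal(nrow(prof_0), 0L)
})

test_that("matrix exports are deterministic triplet text", {
  dir <- withr::local_tempdir()
  sim <- simulate_sprite(params = sim_sprite_params(n_clusters = 200L),
                         seed = 5)
  cm <- build_matrix(build_clusters(sim$reads),
                     genome_binning(sim$truth$genome$chrom_sizes, 1e6))
  p1 <- file.path(dir, "m1.tsv"); p2 <- file.path(dir, "m2.tsv")
  export_matrix(cm, p1)
  export_matrix(cm, p2)
  expect_identical(readLines(p1), readLines(p2))
  trip <- read.table(p1, col.names = c("i", "j", "x"))
  expect_true(all(trip$i <= trip$j))
  expect_equal(sum(trip$x), matrix_mass(cm), tolerance = 1e-6)
})
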