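# a many-armed binning gives ~40 bins per distance class, so per-class
# statistics are well separated from single-bin effects
wide_binning <- function(n_chrom = 20L, chrom_mb = 12L) {
  sizes <- stats::setNames(rep(chrom_mb * 1e6, n_chrom),
                           sprintf("chr%02d", seq_len(n_chrom)))
  genome_binning(sizes, 1e6)
}

test_that("decay curve is a ratio to the terminal-bin mean", {
  bn <- wide_binning()
  cls <- distance_classes(bn)
  # constant track: every class ratio is 1
  dc <- decay_curve(rep(3.5, bn$n_genomic), bn)
  expect_true(all(abs(dc$mean_ratio - 1) < 1e-12))
  # value 10 at class-1 bins, 1 elsewhere
  tr <- ifelse(cls == 1L, 10, 1)
  dc <- decay_curve(tr, bn)
  expect_equal(dc$mean_ratio[dc$class == 1], 1.0)
  expect_true(all(abs(dc$mean_ratio[dc$class > 1] - 0.1) < 1e-12))
  # all-zero terminal bins are degenerate
  expect_error(decay_curve(ifelse(cls == 1L, 0, 1), bn), "degenerate")
})

test_that("decay slope recovers a planted exponential rate", {
  bn <- wide_binning()
  cls <- distance_classes(bn)
  lambda <- 0.45
  set.seed(101)
  tr <- exp(-lambda * cls) * exp(rnorm(bn$n_genomic, 0, 0.1))
  dc <- decay_curve(tr, bn)
  fit <- stats::lm(log(mean_ratio) ~ class, data = dc)
  ci <- stats::confint(fit)["class", ]
  expect_gt(-lambda, ci[1])
  expect_lt(-lambda, ci[2])
})

test_that("distance normalization has unit class means and is idempotent", {
  bn <- wide_binning()
  cls <- distance_classes(bn)
  set.seed(55)
  tr <- exp(-0.3 * cls) * runif(bn$n_genomic, 0.5, 1.5)
  tr[sample(bn$n_genomic, 30)] <- 0  # unmappable bins
  nt <- distance_normalize(tr, bn)
  expect_true(all(is.na(nt$track[tr == 0])))
  m <- tapply(nt$track[tr > 0], cls[tr > 0], mean)
  expect_true(all(abs(m - 1) < 1e-9))
  # constant track normalizes to all ones
  expect_true(all(distance_normalize(rep(2, bn$n_genomic),
                                     bn)$track == 1))
  # idempotence: renormalizing the normalized track changes nothing
  nt2 <- distance_normalize(nt)
  expect_equal(nt2$track, nt$track, tolerance = 1e-12)
})

test_that("a planted hotspot stands out after distance normalization", {
  bn <- wide_binning(40L)  # ~80 bins per class
  cls <- distance_classes(bn)
  tr <- exp(-0.5 * cls)
  hot <- which(cls == 6L)[1]
  tr[hot] <- 5 * tr[hot]
  nt <- distance_normalize(tr, bn)
  # raw value at the hotspot is smaller than any class-1 bin...
  expect_lt(tr[hot], min(tr[cls == 1L]))
  # ...but the normalized value is ~5 (self-dilution of the class mean
  # shrinks it slightly below 5)
  expect_gt(nt$track[hot], 4.5)
  expect_lt(nt$track[hot], 5.0)
})

test_that("bin overlap flags follow half-open any-overlap semantics", {
  bn <- genome_binning(c(chr1 = 5e6, chr2 = 3e6), 1e6)
  # interval exactly one bin
  fl <- overlap_flags(bn, granges_from_bed3("chr1", 1e6, 2e6))
  expect_equal(which(fl), 2L)
  # interval spanning a bin boundary flags both bins
  fl <- overlap_flags(bn, granges_from_bed3("chr1", 1.9e6, 2.1e6))
  expect_equal(which(fl), c(2L, 3L))
  # k disjoint bin-sized intervals flag exactly k bins
  fl <- overlap_flags(bn, granges_from_bed3(c("chr1", "chr2"),
                                            c(0, 2e6), c(1e6, 3e6)))
  expect_equal(sum(fl), 2L)
  expect_warning(overlap_flags(bn, granges_from_bed3("chrX", 0, 10)),
                 "absent")
})

test_that("group comparison is a Welch test on normalized values", {
  v <- c(rep(c(1, 2, 3), 4), rep(c(1, 2, 3), 4))
  flags <- rep(c(TRUE, FALSE), each = 12)
  gc <- group_compare(v, flags)
  expect_equal(gc$statistic, 0)
  expect_equal(gc$p.value, 1)
  # well separated groups
  set.seed(3)
  v2 <- c(rnorm(200, 3, 0.5), rnorm(2800, 1, 0.5))
  fl2 <- rep(c(TRUE, FALSE), c(200, 2800))
  expect_lt(group_compare(v2, fl2)$p.value, 1e-3)
  # invariance to common positive rescaling
  a <- group_compare(v2, fl2)
  b <- group_compare(v2 * 7.3, fl2)
  expect_equal(a$p.value, b$p.value)
  expect_equal(a$statistic, b$statistic)
  expect_error(group_compare(v2[1:10], rep(FALSE, 10)), "flagged")
})

test_that("empirical Welch power matches the analytic oracle", {
  # effect size d = 1 at n = 200 / 2800: power is essentially saturated;
  # the empirical rejection rate must agree with the closed form
  n1 <- 200L; n2 <- 2800L; d <- 1
  analytic <- stats::power.t.test(n = n1, delta = d, sd = 1,
                                  sig.level = 0.05)$power
  set.seed(77)
  rej <- mean(vapply(1:100, function(i) {
    v <- c(rnorm(n1, d), rnorm(n2, 0))
    group_compare(v, rep(c(TRUE, FALSE), c(n1, n2)))$p.value < 0.05
  }, logical(1)))
  expect_lt(abs(rej - analytic), 0.05)
})

test_that("peak proximity profiles are flat under identical placement", {
  bn_sizes <- c(chr1 = 10e6)
  peaks <- granges_from_bed3("chr1", c(2e6, 6e6), c(2.01e6, 6.01e6))
  # telomere and non-telomere clusters with identical genomic reads
  pos <- seq(1.96e6, 2.04e6, by = 2000)
  gen <- function(bc, with_tel) {
    r <- data.frame(barcode = bc, chrom = "chr1", start = pos,
                    end = pos + 90, mapq = 60L, strand = "*",
                    stringsAsFactors = FALSE)
    if (with_tel) r <- rbind(r, assign_chrT(bc))
    r
  }
  cl <- build_clusters(rbind(gen("t1", TRUE), gen("n1", FALSE)))
  prof <- peak_proximity_profile(cl, peaks, window = 50000L, step = 10000L)
  got <- prof$ratio[!is.na(prof$ratio)]
  expect_true(all(got == 1))
  # telomere reads concentrated at the peak center peak at d = 0
  near <- data.frame(barcode = "t2", chrom = "chr1",
                     start = rep(2e6 + 5, 30) + seq(-45, 100, length.out = 30),
                     end = rep(2e6 + 100, 30), mapq = 60L, strand = "*",
                     stringsAsFactors = FALSE)
  far <- data.frame(barcode = "n2", chrom = "chr1",
                    start = seq(1.96e6, 2.04e6, length.out = 50),
                    end = seq(1.96e6, 2.04e6, length.out = 50) + 90,
                    mapq = 60L, strand = "*", stringsAsFactors = FALSE)
  cl2 <- build_clusters(rbind(near, assign_chrT("t2"), far))
  # distance bins covered only by the diffuse non-telomere cluster make
  # the literal minimum zero; the profile falls back with a warning
  expect_warning(
    prof2 <- peak_proximity_profile(cl2, peaks, window = 50000L,
                                    step = 10000L),
    "smallest positive")
  center <- which(prof2$dist == 5000 | prof2$dist == -5000)
  expect_equal(which.max(prof2$ratio) %in% center ||
                 which.max(prof2$ratio) %in% (center + c(-1, 1)), TRUE)
  # no telomere clusters at all: ratios are all zero -> error path
  cl3 <- build_clusters(far)
  expect_error(suppressWarnings(
    peak_proximity_profile(cl3, peaks, 50000L, 10000L)))
})

test_that("eigenvector correlation handles exact and planted dependence", {
  set.seed(19)
  v <- rnorm(100)
  expect_equal(eigencorrelation(v, v)$r, 1)
  expect_equal(eigencorrelation(v, -v)$r, -1)
  expect_error(eigencorrelation(v[1:2], v[1:2]), "3 bins")
  # planted linear dependence r0 = -0.4 over n = 2500 bins
  r0 <- -0.4
  est <- vapply(1:5, function(s) {
    set.seed(400 + s)
    x <- rnorm(2500)
    y <- r0 * x + sqrt(1 - r0^2) * rnorm(2500)
    eigencorrelation(y, x)$r
  }, numeric(1))
  expect_true(all(abs(est - r0) < 0.05))
})
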