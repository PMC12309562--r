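#' Multi-Otsu thresholds of an intensity sample
#'
#' Exhaustive multi-class Otsu thresholding on a fixed-width histogram:
#' picks the class boundaries maximizing the between-class variance. With
#' the default three classes this separates background, nucleus (or focus
#' halo) and bright-focus intensities.
#'
#' @param values Numeric vector of pixel intensities.
#' @param n_classes Number of classes (2 or 3; default 3).
#' @param n_bins Histogram bins (default 128).
#' @return Numeric vector of \code{n_classes - 1} thresholds (ascending).
#' @export
multi_otsu <- function(values, n_classes = 3L, n_bins = 128L) {
  values <- values[is.finite(values)]
  stopifnot(length(values) > 0L, n_classes %in% c(2L, 3L))
  rng <- range(values)
  if (rng[1L] == rng[2L]) return(rep(rng[1L], n_classes - 1L))
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, edges, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  # class stat between histogram bins (a, b]: weight and weighted mean
  cls_stat <- function(a, b) {
    w <- cw[b] - if (a > 0L) cw[a] else 0
    m <- cm[b] - if (a > 0L) cm[a] else 0
    if (w <= 0) return(NULL)
    w * (m / w)^2
  }
  best <- -Inf
  th <- NULL
  if (n_classes == 2L) {
    for (t1 in 1L:(n_bins - 1L)) {
      s1 <- cls_stat(0L, t1); s2 <- cls_stat(t1, n_bins)
      if (is.null(s1) || is.null(s2)) next
      v <- s1 + s2
      if (v > best) { best <- v; th <- t1 }
    }
    return(edges[th + 1L])
  }
  for (t1 in 1L:(n_bins - 2L)) {
    s1 <- cls_stat(0L, t1)
    if (is.null(s1)) next
    for (t2 in (t1 + 1L):(n_bins - 1L)) {
      s2 <- cls_stat(t1, t2); s3 <- cls_stat(t2, n_bins)
      if (is.null(s2) || is.null(s3)) next
      v <- s1 + s2 + s3
      if (v > best) { best <- v; th <- c(t1, t2) }
    }
  }
  if (is.null(th)) {
    # fewer than three occupied intensity levels: fall back to two classes
    t1 <- multi_otsu(values, 2L, n_bins)
    return(c(t1, t1))
  }
  edges[th + 1L]
}

#' Segment nuclei from the DNA-stain channel
#'
#' Multi-Otsu (3 classes) thresholding of the DNA channel; foreground is
#' everything above the first threshold (nucleus plus any brighter
#' structure), labeled into connected components, with components below
#' \code{min_area} pixels discarded.
#'
#' @param dna Numeric matrix (DNA-stain intensities).
#' @param min_area Minimum nucleus area in pixels (default 500).
#' @return Integer matrix of nucleus labels (0 = background); zero nuclei
#'   produce an all-zero matrix with a warning.
#' @export
segment_nuclei <- function(dna, min_area = 500L) {
  stopifnot(is.matrix(dna))
  th <- multi_otsu(as.numeric(dna), 3L)[1L]
  lab <- EBImage::bwlabel(dna > th)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  if (length(keep) == 0L) {
    warning("no nucleus found")
    return(matrix(0L, nrow(dna), ncol(dna)))
  }
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(dna), ncol(dna))
  nz <- lab > 0L
  out[nz] <- relab[lab[nz]]
  out
}

#' Segment fluorescence foci within a nucleus
#'
#' Multi-Otsu (3 classes) thresholding of the channel restricted to the
#' nucleus mask; focus pixels are the top intensity class. Connected
#' components of at least \code{min_area} pixels (default 9) become foci
#' with centroid = mean pixel coordinate.
#'
#' @param channel Numeric matrix (telomere or centromere channel).
#' @param mask Logical matrix or labeled matrix (> 0 inside the nucleus).
#' @param min_area Minimum focus area in pixels.
#' @return Data frame with \code{row}, \code{col} (centroids) and
#'   \code{area}; zero rows when no focus qualifies.
#' @export
segment_foci <- function(channel, mask, min_area = 9L) {
  stopifnot(is.matrix(channel), all(dim(channel) == dim(mask)))
  mask <- mask > 0L
  empty <- data.frame(row = numeric(0L), col = numeric(0L),
                      area = integer(0L))
  if (!any(mask)) return(empty)
  vals <- as.numeric(channel[mask])
  th <- multi_otsu(vals, 3L)
  # focus pixels must also clear 3x the in-mask mean, so a channel with
  # no real foci does not segment its own noise
  fg <- channel > max(th[2L], 3 * mean(vals)) & mask
  if (!any(fg)) return(empty)
  lab <- EBImage::bwlabel(fg)
  idx <- which(lab > 0L, arr.ind = TRUE)
  ids <- lab[lab > 0L]
  area <- tabulate(ids)
  keep <- which(area >= min_area)
  if (length(keep) == 0L) return(empty)
  out <- data.frame(
    row = as.numeric(tapply(idx[, 1L], ids, mean))[keep],
    col = as.numeric(tapply(idx[, 2L], ids, mean))[keep],
    area = area[keep])
  rownames(out) <- NULL
  out
}

#' Mean number of adjacent telomere foci per centromere focus
#'
#' A telomere focus is centromere-adjacent when its centroid lies within
#' \code{radius} pixels (Euclidean, inclusive) of a centromere focus
#' centroid; the score is the mean count of adjacent telomeres over the
#' centromere foci of the nucleus.
#'
#' @param tel,cen Focus data frames (\code{row}, \code{col}).
#' @param radius Adjacency radius in pixels (default 5).
#' @return The mean count; \code{NA} with a warning when there is no
#'   centromere focus.
#' @export
score_adjacency <- function(tel, cen, radius = 5) {
  if (nrow(cen) == 0L) {
    warning("no centromere focus; nucleus skipped")
    return(NA_real_)
  }
  if (nrow(tel) == 0L) return(0)
  d2 <- outer(cen$row, tel$row, "-")^2 + outer(cen$col, tel$col, "-")^2
  mean(rowSums(d2 <= radius^2))
}

#' Randomization percentile of telomere-centromere adjacency
#'
#' Relocates every telomere centroid to an independent uniform draw over
#' the nucleus-mask pixels (centromeres fixed, counts preserved),
#' \code{n_random} times, scoring adjacency for each randomization. The
#' observed score's percentile uses mid-ranking: 100 * (#randomizations
#' strictly below + half the ties) / n_random.
#'
#' @param mask Logical (or labeled) matrix delimiting the nuclear area.
#' @param tel,cen Focus data frames.
#' @param radius Adjacency radius in pixels.
#' @param n_random Number of randomizations (default 1000).
#' @param seed Optional seed for reproducibility.
#' @return List with \code{observed}, \code{percentile}, \code{n_random}.
#' @export
randomization_percentile <- function(mask, tel, cen, radius = 5,
                                     n_random = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mask <- mask > 0L
  if (!any(mask)) stop("empty nuclear mask")
  observed <- score_adjacency(tel, cen, radius)
  if (is.na(observed)) return(list(observed = NA_real_,
                                   percentile = NA_real_,
                                   n_random = n_random))
  pix <- which(mask, arr.ind = TRUE)
  nt <- nrow(tel)
  scores <- numeric(n_random)
  if (nt > 0L) {
    draw <- matrix(sample.int(nrow(pix), n_random * nt, replace = TRUE),
                   n_random, nt)
    rr <- matrix(pix[draw, 1L], n_random, nt)
    cc <- matrix(pix[draw, 2L], n_random, nt)
    counts <- matrix(0L, n_random, nt)
    for (k in seq_len(nrow(cen))) {
      counts <- counts + ((rr - cen$row[k])^2 + (cc - cen$col[k])^2 <=
                            radius^2)
    }
    scores <- rowSums(counts) / nrow(cen)
  }
  pct <- 100 * (sum(scores < observed) + 0.5 * sum(scores == observed)) /
    n_random
  list(observed = observed, percentile = pct, n_random = n_random)
}

#' Per-nucleus telomere-centromere proximity analysis of one image
#'
#' Segments nuclei from the DNA channel, telomere and centromere foci
#' within each nucleus, scores adjacency and computes the randomization
#' percentile. Nuclei without centromere foci are skipped with a warning.
#'
#' @param image List with matrices \code{dna}, \code{tel}, \code{cen} of
#'   equal shape (e.g. from \code{\link{simulate_fish_image}} or
#'   \code{\link{read_fish_image}}).
#' @param radius Adjacency radius in pixels (default 5).
#' @param n_random Randomizations per nucleus (default 1000).
#' @param min_nucleus_area,min_focus_area Segmentation parameters.
#' @param seed Optional seed.
#' @return Data frame: \code{nucleus}, \code{n_tel}, \code{n_cen},
#'   \code{score}, \code{percentile}.
#' @export
analyze_fish_image <- function(image, radius = 5, n_random = 1000L,
                               min_nucleus_area = 500L, min_focus_area = 9L,
                               seed = NULL) {
  stopifnot(all(c("dna", "tel", "cen") %in% names(image)))
  if (!is.null(seed)) set.seed(seed)
  labels <- segment_nuclei(image$dna, min_nucleus_area)
  out <- list()
  for (nid in setdiff(sort(unique(as.integer(labels))), 0L)) {
    mask <- labels == nid
    tel <- segment_foci(image$tel, mask, min_focus_area)
    cen <- segment_foci(image$cen, mask, min_focus_area)
    if (nrow(cen) == 0L) {
      warning("nucleus ", nid, " has no centromere focus; skipped")
      next
    }
    rp <- randomization_percentile(mask, tel, cen, radius, n_random)
    out[[length(out) + 1L]] <- data.frame(
      nucleus = nid, n_tel = nrow(tel), n_cen = nrow(cen),
      score = rp$observed, percentile = rp$percentile)
  }
  if (length(out) == 0L)
    return(data.frame(nucleus = integer(0L), n_tel = integer(0L),
                      n_cen = integer(0L), score = numeric(0L),
                      percentile = numeric(0L)))
  do.call(rbind, out)
}

#' Read a multi-channel FISH image
#'
#' Reads a TIFF/PNG image via EBImage and maps frames to channels.
#'
#' @param path Image path.
#' @param channels Named integer vector mapping \code{dna}, \code{tel},
#'   \code{cen} to 1-based frame indices (default 1:3).
#' @return List of matrices \code{dna}, \code{tel}, \code{cen}.
#' @export
read_fish_image <- function(path, channels = c(dna = 1L, tel = 2L,
                                               cen = 3L)) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  get <- function(i) {
    if (i > dim(img)[3L]) stop("channel index ", i, " beyond image frames")
    matrix(img[, , i], dim(img)[1L], dim(img)[2L])
  }
  list(dna = get(channels[["dna"]]), tel = get(channels[["tel"]]),
       cen = get(channels[["cen"]]))
}
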