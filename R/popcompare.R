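# Does composition separate species or gene classes?  Histogram-intersection
# overlap of metric distributions, the overlap table, and unsupervised
# clustering (mean shift + density-based) of the feature matrix.

#' @rdname distributionOverlap
#' @export
setClass("OverlapResult",
         representation(metric = "character", pair = "character",
                        overlapPercent = "numeric", breaks = "numeric"),
         validity = function(object) {
           if (object@overlapPercent < -1e-9 || object@overlapPercent > 100 + 1e-9)
             return("overlapPercent must lie in [0, 100]")
           TRUE
         })

#' Percentage overlap of two empirical distributions
#'
#' Histogram-intersection overlap: both samples are binned on a shared grid
#' spanning the pooled range (Freedman-Diaconis width by default) and the
#' overlap is `100 * sum_b min(f_a(b), f_b(b))` over within-sample
#' proportions `f`.  Symmetric; 100 for identical samples; 0 for disjoint
#' supports.
#'
#' @param sampleA,sampleB numeric vectors (>= 30 values each).
#' @param nBins number of bins, or `NULL` (default) for the
#'   Freedman-Diaconis rule on the pooled sample.
#' @param metric,pair optional labels stored in the result.
#' @return an `OverlapResult`; [overlapPercent()] extracts the number.
#' @export
distributionOverlap <- function(sampleA, sampleB, nBins = NULL,
                                metric = NA_character_, pair = NA_character_) {
  .assert(length(sampleA) >= 30 && length(sampleB) >= 30,
          "both samples need >= 30 values (invalid-argument)")
  pooled <- c(sampleA, sampleB)
  rng <- range(pooled)
  if (is.null(nBins)) {
    h <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
    nBins <- if (h <= 0 || !is.finite(h)) 1L
    else max(1L, min(10000L, ceiling(diff(rng) / h)))
  }
  if (diff(rng) == 0) {
    breaks <- c(rng[1] - 0.5, rng[1] + 0.5)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = nBins + 1)
  }
  fa <- tabulate(findInterval(sampleA, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = length(breaks) - 1)
  fb <- tabulate(findInterval(sampleB, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = length(breaks) - 1)
  ov <- 100 * sum(pmin(fa / length(sampleA), fb / length(sampleB)))
  methods::new("OverlapResult", metric = metric, pair = pair,
               overlapPercent = ov, breaks = breaks)
}

#' @describeIn distributionOverlap extract the overlap percentage.
#' @param x an `OverlapResult`.
#' @export
overlapPercent <- function(x) {
  .assert(methods::is(x, "OverlapResult"), "not an OverlapResult")
  x@overlapPercent
}

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult%s%s: %.1f%% (%d bins)\n",
              if (is.na(object@metric)) "" else paste0(" [", object@metric, "]"),
              if (is.na(object@pair)) "" else paste0(" ", object@pair),
              object@overlapPercent, length(object@breaks) - 1L))
})

#' Metric-by-species overlap table
#'
#' One row per comparison set giving, for each metric, the percentage
#' overlap of its distribution with the reference set, plus a final
#' `Median` row computed per column.  Rows named in `medianExclude`
#' (by default anything containing "random") are excluded from the median,
#' mirroring the convention that random-sequence rows do not enter it.
#'
#' @param reference a [compositionProfiles()] object (the reference species).
#' @param others named list of `CompositionProfiles` to compare against.
#' @param metrics metric columns to use (default gc, gc3, cai, enc).
#' @param medianExclude row names excluded from the median (default: those
#'   matching `"random"`).
#' @return data.frame, rows = comparison sets plus `"Median"`.
#' @export
overlapTable <- function(reference, others,
                         metrics = c("gc", "gc3", "cai", "enc"),
                         medianExclude = grep("random", names(others),
                                              value = TRUE, ignore.case = TRUE)) {
  .assert(length(others) >= 1, "need at least one comparison set")
  refM <- metricsTable(reference)
  .assert(all(metrics %in% names(refM)), "metric not in profiles (invalid-argument)")
  rows <- lapply(names(others), function(nm) {
    om <- metricsTable(others[[nm]])
    vapply(metrics, function(met) {
      overlapPercent(distributionOverlap(refM[[met]], om[[met]],
                                         metric = met, pair = nm))
    }, numeric(1))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- names(others)
  keep <- setdiff(rownames(tab), medianExclude)
  med <- vapply(tab[keep, , drop = FALSE], median, numeric(1))
  rbind(tab, Median = med)
}

# ---------------------------------------------------------------------------
# Clustering

#' @rdname clusterModeSeeking
#' @export
setClass("ClusteringResult",
         representation(labels = "integer", nClusters = "integer",
                        method = "character", parameters = "list"),
         validity = function(object) {
           if (any(object@labels == 0)) return("labels are 1-based (-1 = noise)")
           TRUE
         })

#' @describeIn clusterModeSeeking per-point integer labels (-1 = noise).
#' @param x a `ClusteringResult`.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn clusterModeSeeking number of clusters (noise not counted).
#' @export
nClusters <- function(x) x@nClusters

setMethod("show", "ClusteringResult", function(object) {
  cat(sprintf("ClusteringResult (%s): %d points, %d cluster(s), %d noise\n",
              object@method, length(object@labels), object@nClusters,
              sum(object@labels == -1L)))
})

# z-score columns, dropping constant ones
.scaleFeatures <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, sd)
  x <- x[, sds > 0, drop = FALSE]
  if (!ncol(x)) return(x)
  scale(x)
}

#' Estimate the mean-shift bandwidth from nearest-neighbor distances
#'
#' The mean, over all points, of the distance to the `ceiling(quantile * n)`-th
#' nearest neighbor — the standard automatic bandwidth heuristic for mean
#' shift.
#'
#' @param x numeric feature matrix.
#' @param quantile fraction of neighbors to look out to (default 0.3).
#' @return a single bandwidth value (>= 0).
#' @export
estimateBandwidth <- function(x, quantile = 0.3) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- max(1L, min(n - 1L, ceiling(quantile * n)))
  D <- as.matrix(dist(x))
  mean(apply(D, 1, function(d) sort(d)[k + 1L]))
}

#' Mode-seeking (mean shift) clustering
#'
#' Flat-kernel mean shift: every point is iterated to the mean of the
#' points within `bandwidth` of it until convergence; converged modes
#' closer than the bandwidth are merged (larger windows win) and points are
#' assigned to their nearest surviving mode.  Features are z-scored per
#' column first (constant columns dropped).  If all points coincide a
#' single cluster is returned with a warning.
#'
#' @param x numeric feature matrix (>= 10 rows, finite values).
#' @param bandwidth kernel radius; `NULL` (default) uses
#'   [estimateBandwidth()] with `quantile`.
#' @param quantile neighbor quantile for the automatic bandwidth.
#' @param scale z-score columns first (default TRUE).
#' @param maxIter,tol iteration controls.
#' @return a `ClusteringResult`.
#' @export
clusterModeSeeking <- function(x, bandwidth = NULL, quantile = 0.3,
                               scale = TRUE, maxIter = 300, tol = 1e-4) {
  prescaled <- isTRUE(attr(x, "prescaled"))
  x <- as.matrix(x)
  .assert(nrow(x) >= 10, "need >= 10 rows (invalid-argument)")
  .assert(all(is.finite(x)), "feature matrix must be finite")
  feats <- if (scale && !prescaled) .scaleFeatures(x) else x
  n <- nrow(x)
  if (!ncol(feats)) {
    warning("all features constant: returning a single cluster")
    return(methods::new("ClusteringResult", labels = rep(1L, n),
                        nClusters = 1L, method = "mean_shift",
                        parameters = list(bandwidth = 0)))
  }
  if (is.null(bandwidth)) bandwidth <- estimateBandwidth(feats, quantile)
  if (bandwidth <= 0) {
    warning("zero bandwidth (all points identical): returning a single cluster")
    return(methods::new("ClusteringResult", labels = rep(1L, n),
                        nClusters = 1L, method = "mean_shift",
                        parameters = list(bandwidth = bandwidth)))
  }
  centers <- feats
  for (it in seq_len(maxIter)) {
    D2 <- .crossDist2(centers, feats)
    shifted <- centers
    for (i in seq_len(n)) {
      within <- D2[i, ] <= bandwidth^2
      shifted[i, ] <- colMeans(feats[within, , drop = FALSE])
    }
    moved <- sqrt(rowSums((shifted - centers)^2))
    centers <- shifted
    if (max(moved) < tol * bandwidth) break
  }
  # merge modes within one bandwidth, preferring denser windows
  D2 <- .crossDist2(centers, feats)
  sizes <- rowSums(D2 <= bandwidth^2)
  ord <- order(-sizes)
  keptIdx <- integer(0)
  for (i in ord) {
    if (!length(keptIdx)) { keptIdx <- i; next }
    d2 <- rowSums((centers[keptIdx, , drop = FALSE] -
                     matrix(centers[i, ], length(keptIdx), ncol(centers),
                            byrow = TRUE))^2)
    if (all(d2 > bandwidth^2)) keptIdx <- c(keptIdx, i)
  }
  modes <- centers[keptIdx, , drop = FALSE]
  assign2 <- .crossDist2(feats, modes)
  labels <- max.col(-assign2)
  methods::new("ClusteringResult", labels = as.integer(labels),
               nClusters = nrow(modes), method = "mean_shift",
               parameters = list(bandwidth = bandwidth, quantile = quantile,
                                 iterations = it))
}

.crossDist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Density-based clustering (DBSCAN)
#'
#' Classic density clustering: points with at least `minSamples` neighbors
#' (self included) within `eps` are core points; clusters are the connected
#' components of core points, border points join a neighboring cluster, and
#' everything else is noise (label -1).  Features are z-scored per column
#' first by default.
#'
#' @param x numeric feature matrix.
#' @param eps neighborhood radius (> 0).
#' @param minSamples minimum neighborhood size for a core point (>= 2).
#' @param scale z-score columns first (default TRUE).
#' @return a `ClusteringResult`.
#' @export
clusterDensity <- function(x, eps, minSamples = 5, scale = TRUE) {
  .assert(is.numeric(eps) && eps > 0, "eps must be > 0 (invalid-argument)")
  .assert(minSamples >= 2, "minSamples must be >= 2 (invalid-argument)")
  prescaled <- isTRUE(attr(x, "prescaled"))
  x <- as.matrix(x)
  feats <- if (scale && !prescaled) .scaleFeatures(x) else x
  n <- nrow(x)
  if (!ncol(feats)) feats <- matrix(0, n, 1)
  D2 <- .crossDist2(feats, feats)
  nb <- D2 <= eps^2
  core <- rowSums(nb) >= minSamples
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in which(nb[p, ])) {
        if (labels[q] == -1L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  methods::new("ClusteringResult", labels = labels, nClusters = cl,
               method = "dbscan",
               parameters = list(eps = eps, minSamples = minSamples))
}

#' Suggest a DBSCAN radius from the k-nearest-neighbor distance curve
#'
#' A quantile of the distances to the k-th nearest neighbor (an automatic
#' proxy for the elbow of the sorted k-distance plot).
#'
#' @param x feature matrix (will be z-scored if `scale`).
#' @param k neighbor rank (default `minSamples - 1 = 4`).
#' @param prob quantile of the k-distances (default 0.9).
#' @param scale z-score columns first (default TRUE).
#' @return a positive radius.
#' @export
suggestDensityEps <- function(x, k = 4, prob = 0.9, scale = TRUE) {
  prescaled <- isTRUE(attr(x, "prescaled"))
  feats <- if (scale && !prescaled) .scaleFeatures(as.matrix(x)) else as.matrix(x)
  D <- as.matrix(dist(feats))
  kd <- apply(D, 1, function(d) sort(d)[k + 1L])
  unname(quantile(kd, prob))
}

#' Assemble the clustering feature matrix from composition profiles
#'
#' Binds the four scalar metrics with the tetranucleotide frequencies,
#' optionally truncating the tetranucleotide block to its highest-variance
#' columns.  With `scale = TRUE` (default) every column is z-scored and
#' the tetranucleotide block is additionally down-weighted by
#' `1/sqrt(#tetra columns)` so that the whole signature carries the weight
#' of one feature group rather than letting 256 noise-dominated columns
#' swamp the four metrics; the result is marked as pre-scaled so the
#' clustering functions do not rescale it.
#'
#' @param profiles a [compositionProfiles()] object (or list of them,
#'   row-bound).
#' @param tetraTopVar keep only this many highest-variance tetranucleotide
#'   columns (`Inf` = all 256, the default).
#' @param scale z-score and balance the blocks (default TRUE).
#' @return numeric matrix, one row per gene.
#' @export
featureMatrix <- function(profiles, tetraTopVar = Inf, scale = TRUE) {
  if (!is.list(profiles)) profiles <- list(profiles)
  mets <- do.call(rbind, lapply(profiles, function(p)
    as.matrix(metricsTable(p)[, c("gc", "gc3", "cai", "enc")])))
  tetra <- do.call(rbind, lapply(profiles, tetraMatrix))
  if (is.finite(tetraTopVar) && tetraTopVar < ncol(tetra)) {
    v <- apply(tetra, 2, var)
    tetra <- tetra[, order(-v)[seq_len(tetraTopVar)], drop = FALSE]
  }
  if (!scale) return(cbind(mets, tetra))
  mets <- .scaleFeatures(mets)
  tetra <- .scaleFeatures(tetra)
  if (ncol(tetra)) tetra <- tetra / sqrt(ncol(tetra))
  out <- cbind(mets, tetra)
  attr(out, "prescaled") <- TRUE
  out
}
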