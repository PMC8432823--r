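# Evaluation metrics: normalized RMSE of images and T2 maps, T2 bias
# and standard deviation over a region of interest, Otsu-threshold
# edema segmentation with Jaccard overlap, and the percentage of
# unsuccessfully recovered voxels.

#' Normalized root-mean-square error over an ROI (percent)
#'
#' `100 * ||x - ref||_2 / ||ref||_2` restricted to the ROI voxels.
#'
#' @param x,ref numeric arrays of identical shape
#' @param roi logical array selecting the voxels compared
#' @return percent NRMSE
#' @export
nrmse <- function(x, ref, roi) {
  stopifnot(all(dim(x) == dim(ref)), all(dim(ref) == dim(roi)))
  if (!any(roi)) stop("empty ROI")
  xr <- x[roi]; rr <- ref[roi]
  denom <- sqrt(sum(rr^2))
  if (denom == 0) stop("reference has zero norm over the ROI")
  100 * sqrt(sum((xr - rr)^2)) / denom
}

#' T2 bias and standard deviation over an ROI
#'
#' Bias = mean(T2) - mean(T2_ref); SD is the population (denominator n)
#' standard deviation of T2 over the ROI. Each map contributes only its
#' own valid voxels (the evaluated map over `roi` AND its validity
#' mask; the reference mean likewise over its own valid voxels).
#'
#' @param maps evaluated `parameter_maps`
#' @param ref_maps reference `parameter_maps`
#' @param roi logical 3D array (e.g. the myocardial ROI)
#' @return list with `bias` and `sd`, both in ms
#' @export
t2_bias_sd <- function(maps, ref_maps, roi) {
  sel <- roi & maps$valid_mask
  sel_ref <- roi & ref_maps$valid_mask
  if (!any(sel) || !any(sel_ref)) stop("no valid voxels in ROI")
  v <- maps$t2_map[sel]
  vr <- ref_maps$t2_map[sel_ref]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  list(bias = mean(v) - mean(vr), sd = pop_sd(v))
}

#' Otsu's threshold of a sample of values
#'
#' Histogram-based threshold maximizing the between-class variance over
#' `n_bins` uniform bins spanning the observed range. Candidate
#' thresholds are the bin edges; ties resolve to the lowest edge.
#'
#' @param values numeric vector with at least two distinct values
#' @param n_bins number of histogram bins (default 256)
#' @return the threshold (a value separating the two classes)
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2) stop("need at least two distinct values")
  lo <- min(values); hi <- max(values)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  h <- graphics::hist(values, breaks = edges, plot = FALSE)$counts
  n <- sum(h)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(h) / n
  m0 <- cumsum(h * mids) / n
  mt <- m0[length(m0)]
  # between-class variance when splitting after bin t
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  t_star <- which.max(sigma_b)
  edges[t_star + 1L]
}

#' Jaccard index (intersection over union) of two masks
#'
#' Ranges from 0 (disjoint) to 1 (identical); two empty masks are
#' defined to agree (index 1).
#'
#' @param a,b logical arrays of identical shape
#' @return value in [0, 1]
#' @export
jaccard <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)) || length(a) == length(b))
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Percentage of unsuccessfully recovered voxels in an ROI
#'
#' Voxels whose fit failed or whose T2 falls outside the 15-100 ms
#' acceptance band count as unrecovered.
#'
#' @param maps a `parameter_maps`
#' @param roi logical 3D array
#' @return percent in [0, 100]
#' @export
pct_unrecovered <- function(maps, roi) {
  if (!any(roi)) stop("empty ROI")
  100 * sum(roi & !maps$valid_mask) / sum(roi)
}

#' Segment edematous (high-T2) tissue in an ROI by Otsu thresholding
#'
#' The threshold is computed from the valid in-ROI T2 values of the map
#' itself (each reconstruction is thresholded independently); the
#' returned mask marks valid ROI voxels above the threshold.
#'
#' @param maps a `parameter_maps`
#' @param roi logical 3D array
#' @return list with `mask` (logical 3D) and `threshold`
#' @export
segment_edema <- function(maps, roi) {
  vals <- maps$t2_map[roi & maps$valid_mask]
  thr <- otsu_threshold(vals)
  list(mask = roi & maps$valid_mask & maps$t2_map > thr, threshold = thr)
}
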