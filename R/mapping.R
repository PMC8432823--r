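# Voxelwise T2 estimation by log-transformed linear regression.
#
# The signal model is S(TE) = A0 * exp(-TE / T2); taking logs gives
# ln S = ln A0 - TE * R2 with R2 = 1/T2, an ordinary least-squares
# problem with a shared design across voxels, solved in closed form for
# the whole volume at once.

# Vectorized log-linear fit. V: (n_vox x n_te) non-negative magnitude
# matrix; te: echo times (ms). Returns intercept/slope per voxel and an
# ok flag (all intensities finite and strictly positive).
fit_loglin <- function(V, te) {
  stopifnot(ncol(V) == length(te), length(te) >= 2)
  ok <- rowSums(!is.finite(V) | V <= 0) == 0
  ln_a0 <- rep(NA_real_, nrow(V))
  r2 <- rep(NA_real_, nrow(V))
  if (any(ok)) {
    L <- log(V[ok, , drop = FALSE])
    tbar <- mean(te)
    ct <- te - tbar
    sstt <- sum(ct^2)
    slope <- as.vector(L %*% ct) / sstt
    ybar <- rowMeans(L)
    r2[ok] <- -slope                 # ln S = ln A0 - TE * R2
    ln_a0[ok] <- ybar - slope * tbar # intercept at TE = 0
  }
  list(ln_a0 = ln_a0, r2 = r2, ok = ok)
}

#' Fit voxelwise T2 and A0 maps from multi-echo magnitude volumes
#'
#' Ordinary least squares of log-intensity on echo time per voxel:
#' A0 = exp(intercept), T2 = 1/R2 with R2 the negated slope. A voxel is
#' marked invalid when any echo intensity is non-positive or
#' non-finite, when the fitted decay rate is non-positive, or when the
#' fitted T2 lies outside the acceptance band [15, 100] ms (boundary
#' values are valid). T2 values outside the band are retained in the
#' map but flagged.
#'
#' @param img an `mvimage` (magnitudes are taken) or a real 4D array
#' @param te_list echo times in ms (defaults to the image's)
#' @return object of class `parameter_maps` with `a0_map`, `t2_map`,
#'   `valid_mask` and `fit_ok` (3D arrays)
#' @export
fit_t2 <- function(img, te_list = NULL) {
  if (inherits(img, "mvimage")) {
    if (is.null(te_list)) te_list <- img$te_list
    v <- abs(img$volumes)
  } else {
    v <- abs(img)
  }
  stopifnot(length(dim(v)) == 4L, !is.null(te_list),
            dim(v)[4] == length(te_list), length(te_list) >= 2)
  d <- dim(v)
  V <- matrix(v, ncol = d[4])
  fit <- fit_loglin(V, te_list)
  a0 <- exp(fit$ln_a0)
  a0[!fit$ok] <- 0
  t2 <- ifelse(fit$r2 > 0, 1 / fit$r2,
               ifelse(fit$r2 == 0, Inf, 1 / fit$r2))
  maps <- structure(
    list(a0_map = array(a0, dim = d[1:3]),
         t2_map = array(t2, dim = d[1:3]),
         valid_mask = array(fit$ok & fit$r2 > 0, dim = d[1:3]),
         fit_ok = array(fit$ok & fit$r2 > 0, dim = d[1:3])),
    class = "parameter_maps")
  apply_validity(maps)
}

#' Apply the T2 acceptance band to a parameter map
#'
#' A voxel is valid iff its fit succeeded and 15 <= T2 <= 100 ms
#' (inclusive). Out-of-band values are retained but flagged; the
#' operation is idempotent.
#'
#' @param maps a `parameter_maps`
#' @return the `parameter_maps` with `valid_mask` updated
#' @export
apply_validity <- function(maps) {
  stopifnot(inherits(maps, "parameter_maps"))
  t2 <- maps$t2_map
  band <- is.finite(t2) & t2 >= 15 & t2 <= 100
  maps$valid_mask <- maps$fit_ok & band
  maps
}

#' @export
print.parameter_maps <- function(x, ...) {
  d <- dim(x$t2_map)
  v <- x$t2_map[x$valid_mask]
  cat(sprintf("<parameter_maps> %dx%dx%d, %.1f%% valid, median T2 %.1f ms\n",
              d[1], d[2], d[3], 100 * mean(x$valid_mask),
              if (length(v)) stats::median(v) else NA_real_))
  invisible(x)
}
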