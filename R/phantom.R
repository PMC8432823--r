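# Synthetic multi-coil cardiac phantom.
#
# A desk-scale stand-in for a T2-prepared 3D whole-heart acquisition:
# a short-axis-like slab with an annular left-ventricular myocardium
# (T2 ~ 44 ms), a bright blood pool inside it, surrounding body tissue,
# and an optional edematous sector of the annulus with elevated T2
# (~ 60 ms). Each voxel decays mono-exponentially with the T2-Prep echo
# time; multi-coil Cartesian k-space is produced by pointwise coil
# weighting followed by a unitary 3D FFT, with white complex Gaussian
# noise added in k-space.

#' Specification of the synthetic cardiac phantom
#'
#' @param grid_shape integer vector (nx, ny, nz), each >= 8
#' @param te_list T2-Prep echo times in ms, strictly increasing from 0
#' @param t2_myo,t2_blood,t2_body T2 (ms) of myocardium, blood pool and
#'   surrounding body tissue
#' @param a0_myo,a0_blood,a0_body proton-density weighted baseline
#'   intensities (arbitrary units)
#' @param lesion logical; include an edematous sector of the annulus?
#' @param lesion_t2 T2 (ms) of the lesion
#' @param lesion_frac angular fraction of the annulus covered by the
#'   lesion
#' @param noise_sigma complex noise SD relative to the peak baseline
#'   intensity
#' @param n_coils number of receive coils
#' @param seed integer seed controlling the stochastic parts
#'   (k-space noise)
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 8L),
                         te_list = c(0, 25, 35, 45),
                         t2_myo = 44, t2_blood = 250, t2_body = 35,
                         a0_myo = 0.8, a0_blood = 1.0, a0_body = 0.5,
                         lesion = FALSE, lesion_t2 = 60,
                         lesion_frac = 0.25,
                         noise_sigma = 0.01, n_coils = 8L,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  stopifnot(length(te_list) >= 2L, te_list[1] == 0,
            all(diff(te_list) > 0))
  stopifnot(t2_myo > 0, t2_blood > 0, t2_body > 0, lesion_t2 > 0)
  stopifnot(a0_myo >= 0, a0_blood >= 0, a0_body >= 0)
  stopifnot(noise_sigma >= 0, n_coils >= 1L)
  stopifnot(lesion_frac > 0, lesion_frac <= 1)
  structure(
    list(grid_shape = grid_shape, te_list = as.numeric(te_list),
         t2_myo = t2_myo, t2_blood = t2_blood, t2_body = t2_body,
         a0_myo = a0_myo, a0_blood = a0_blood, a0_body = a0_body,
         lesion = isTRUE(lesion), lesion_t2 = lesion_t2,
         lesion_frac = lesion_frac,
         noise_sigma = noise_sigma, n_coils = as.integer(n_coils),
         seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Build ground-truth tissue maps from a phantom specification
#'
#' Geometry: an elliptical "body" filling most of the field of view, a
#' concentric annulus ("myocardium") extruded over all slices, a disc
#' ("blood pool") inside the annulus, and an optional angular sector of
#' the annulus with elevated T2 ("edema"). All regions are analytically
#' countable, which the segmentation metrics rely on.
#'
#' @param spec a `phantom_spec`
#' @return list of class `ground_truth` with `a0_map`, `t2_map`
#'   (both 3D), logical ROIs `roi_lv` and `roi_edema`, and the spec
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  x <- matrix(seq_len(nx) - cx, nx, ny)
  y <- matrix(seq_len(ny) - cy, nx, ny, byrow = TRUE)
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)  # (-pi, pi]

  r_body_x <- 0.45 * nx; r_body_y <- 0.42 * ny
  r_out <- 0.30 * min(nx, ny)
  r_in <- 0.20 * min(nx, ny)
  if (r_out >= min(r_body_x, r_body_y))
    stop("myocardial annulus does not fit inside the body ellipse")

  body <- (x / r_body_x)^2 + (y / r_body_y)^2 <= 1
  annulus <- r <= r_out & r > r_in
  pool <- r <= r_in
  lesion2 <- matrix(FALSE, nx, ny)
  if (spec$lesion) {
    # sector of the annulus starting at angle 0, spanning
    # lesion_frac of the full circle
    ang <- theta %% (2 * pi)
    lesion2 <- annulus & ang < 2 * pi * spec$lesion_frac
  }

  a0_2 <- ifelse(pool, spec$a0_blood,
                 ifelse(annulus, spec$a0_myo,
                        ifelse(body, spec$a0_body, 0)))
  t2_2 <- ifelse(pool, spec$t2_blood,
                 ifelse(lesion2, spec$lesion_t2,
                        ifelse(annulus, spec$t2_myo,
                               ifelse(body, spec$t2_body, 1))))

  extrude <- function(m) array(rep(as.vector(m), nz), dim = c(nx, ny, nz))
  gt <- structure(
    list(a0_map = extrude(a0_2), t2_map = extrude(t2_2),
         roi_lv = extrude(annulus), roi_edema = extrude(lesion2),
         spec = spec),
    class = "ground_truth")
  stopifnot(!any(gt$roi_edema & !gt$roi_lv))
  gt
}

#' Smooth complex coil sensitivity maps
#'
#' Coils are modelled as wide Gaussian reception profiles centred at
#' points on a ring around the object, with a gentle linear phase and a
#' single slow cosine variation through-slab. Maps are normalized so
#' the root-sum-of-squares over coils equals one at every voxel, making
#' the fully sampled RSS reconstruction an unbiased reference.
#'
#' @param n_coils number of coils (>= 1)
#' @param grid_shape integer vector (nx, ny, nz)
#' @return complex array of dim (nx, ny, nz, n_coils), class `coil_sens`
#' @export
make_coils <- function(n_coils, grid_shape) {
  stopifnot(n_coils >= 1)
  d <- as.integer(grid_shape)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  x <- matrix(seq_len(nx) - cx, nx, ny)
  y <- matrix(seq_len(ny) - cy, nx, ny, byrow = TRUE)
  sig <- 0.6 * max(nx, ny)
  ring <- 0.55 * max(nx, ny)
  maps <- array(0 + 0i, dim = c(nx, ny, nz, n_coils))
  for (c in seq_len(n_coils)) {
    ang <- 2 * pi * (c - 1) / n_coils
    px <- ring * cos(ang); py <- ring * sin(ang)
    mag <- exp(-((x - px)^2 + (y - py)^2) / (2 * sig^2))
    # gentle linear phase, well below Nyquist/4
    ph <- 2 * pi * (0.01 * cos(ang) * x + 0.01 * sin(ang) * y) / max(nx, ny)
    s2 <- mag * exp(1i * (ph + ang / 3))
    # through-slab profile: single cosine harmonic (band-limited to
    # |kz| <= 1) with a per-coil phase so slices are distinguishable
    # when the slice direction is undersampled
    phz <- 2 * pi * ((c - 1) %% 4) / 4
    zprof <- 1 + 0.5 * cos(2 * pi * (seq_len(nz) - 1) / max(nz, 2L) + phz)
    for (z in seq_len(nz)) maps[, , z, c] <- s2 * zprof[z]
  }
  # enforce band-limitedness (|f| <= Nyquist/4 per axis): the ring
  # Gaussians are truncated at the array edge and the DFT's periodic
  # wrap-around would otherwise leak ~1% of energy into high
  # frequencies
  keep_axis <- function(n) {
    abs(seq_len(n) - kcenter(n)) <= max(floor(n / 8), 1L)
  }
  box <- outer(keep_axis(nx), keep_axis(ny))
  box <- outer(box, keep_axis(nz))
  for (c in seq_len(n_coils)) {
    maps[, , , c] <- ifft3c(fft3c(vol3(maps, c)) * box)
  }
  rss <- sqrt(apply(abs(maps)^2, 1:3, sum))
  rss[rss == 0] <- 1
  for (c in seq_len(n_coils)) maps[, , , c] <- vol3(maps, c) / rss
  structure(list(maps = maps), class = "coil_sens")
}

#' Multi-volume image container
#'
#' A complex 4D array (x, y, z, echo) together with its echo-time list.
#'
#' @param volumes complex (or numeric) 4D array
#' @param te_list echo times in ms, length matching the 4th dimension
#' @return object of class `mvimage`
#' @export
mvimage <- function(volumes, te_list) {
  stopifnot(length(dim(volumes)) == 4L,
            dim(volumes)[4] == length(te_list))
  structure(list(volumes = volumes, te_list = as.numeric(te_list)),
            class = "mvimage")
}

#' @export
print.mvimage <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<mvimage> %dx%dx%d, %d echoes (TE = %s ms)\n",
              d[1], d[2], d[3], d[4],
              paste(x$te_list, collapse = ", ")))
  invisible(x)
}

#' Noiseless multi-echo signal of a ground-truth phantom
#'
#' Mono-exponential decay per voxel:
#' \eqn{I(r, p) = A_0(r) \exp(-TE_p / T2(r))}. The TE = 0 volume equals
#' the baseline map.
#'
#' @param gt a `ground_truth`
#' @param te_list echo times in ms (defaults to the spec's)
#' @return an `mvimage` (real-valued volumes stored as complex)
#' @export
simulate_signal <- function(gt, te_list = gt$spec$te_list) {
  stopifnot(inherits(gt, "ground_truth"), length(te_list) >= 1)
  d <- dim(gt$a0_map)
  vols <- array(0 + 0i, dim = c(d, length(te_list)))
  for (p in seq_along(te_list)) {
    vols[, , , p] <- gt$a0_map * exp(-te_list[p] / gt$t2_map)
  }
  mvimage(vols, te_list)
}

#' Multi-coil Cartesian k-space of a multi-volume image
#'
#' Per coil and echo: unitary centered 3D FFT of (sensitivity x image),
#' plus i.i.d. complex Gaussian noise with total (complex) standard
#' deviation `noise_sigma` on every sample. The returned k-space is
#' fully sampled (mask `FULL`); retrospective undersampling is applied
#' afterwards with [apply_mask()].
#'
#' @param img an `mvimage`
#' @param coils a `coil_sens`
#' @param noise_sigma absolute complex-noise SD (same units as the
#'   image intensities, thanks to the unitary FFT)
#' @param seed integer seed for the noise draw
#' @return object of class `kspace_data` with fields `data`
#'   (complex 5D: x, y, z, coil, echo), `mask`, `te_list`
#' @export
simulate_kspace <- function(img, coils, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(img, "mvimage"), inherits(coils, "coil_sens"))
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  d <- dim(img$volumes)
  nc <- dim(coils$maps)[4]
  stopifnot(all(dim(coils$maps)[1:3] == d[1:3]))
  n_te <- d[4]
  ksp <- array(0 + 0i, dim = c(d[1:3], nc, n_te))
  for (p in seq_len(n_te)) {
    for (c in seq_len(nc)) {
      ksp[, , , c, p] <- fft3c(vol3(coils$maps, c) * vol3(img$volumes, p))
    }
  }
  if (noise_sigma > 0) {
    n <- length(ksp)
    noise <- withr::with_seed(as.integer(seed), {
      complex(real = stats::rnorm(n, sd = noise_sigma / sqrt(2)),
              imaginary = stats::rnorm(n, sd = noise_sigma / sqrt(2)))
    })
    ksp <- ksp + array(noise, dim = dim(ksp))
  }
  structure(
    list(data = ksp, mask = make_full(d[2], d[3], n_te),
         te_list = img$te_list),
    class = "kspace_data")
}

#' Apply a retrospective undersampling mask to k-space
#'
#' Zeroes every (ky, kz) line not present in the per-echo pattern and
#' attaches the mask. The readout (x) dimension is untouched.
#'
#' @param kspace a `kspace_data`
#' @param mask a `sampling_mask` matching the phase-encode grid and
#'   echo count
#' @return a `kspace_data`
#' @export
apply_mask <- function(kspace, mask) {
  stopifnot(inherits(kspace, "kspace_data"), inherits(mask, "sampling_mask"))
  d <- dim(kspace$data)
  dm <- dim(mask$pattern)
  stopifnot(dm[1] == d[2], dm[2] == d[3], dm[3] == d[5])
  nx <- d[1]; nc <- d[4]
  for (p in seq_len(d[5])) {
    m3 <- array(rep(as.vector(mask$pattern[, , p]), each = nx),
                dim = d[1:3])
    for (c in seq_len(nc)) {
      kspace$data[, , , c, p] <- vol3_cp(kspace$data, c, p) * m3
    }
  }
  kspace$mask <- mask
  kspace
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kspace_data> %dx%dx%d, %d coils, %d echoes, scheme=%s\n",
              d[1], d[2], d[3], d[4], d[5], x$mask$scheme))
  invisible(x)
}
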