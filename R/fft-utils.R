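# Centered, unitary discrete Fourier transforms.
#
# Convention used throughout the package: the k-space origin sits at the
# array centre index floor(n/2)+1 (1-based) along every transformed
# dimension, and both directions of the transform carry a 1/sqrt(N)
# factor so that Parseval's identity holds exactly and regularization
# weights are grid-size independent.

#' Index permutation moving the DC sample to the array centre
#'
#' @param n length of the dimension
#' @return integer vector such that `x[fftshift_idx(n)]` is the shifted
#'   vector
#' @keywords internal
fftshift_idx <- function(n) {
  h <- floor(n / 2)
  c(seq_len(h) + (n - h), seq_len(n - h))
}

#' @rdname fftshift_idx
#' @keywords internal
ifftshift_idx <- function(n) {
  h <- ceiling(n / 2)
  c(seq_len(h) + (n - h), seq_len(n - h))
}

#' Shift a 3D array so the centre sample moves to index 1 (and back)
#'
#' `fftshift3` moves the first element (DC in FFT-native order) to the
#' centre; `ifftshift3` is its inverse. For even dimensions the two
#' coincide.
#'
#' @param x 3D array
#' @return shifted array of the same shape
#' @keywords internal
fftshift3 <- function(x) {
  d <- dim(x)
  x[fftshift_idx(d[1]), fftshift_idx(d[2]), fftshift_idx(d[3]), drop = FALSE]
}

#' @rdname fftshift3
#' @keywords internal
ifftshift3 <- function(x) {
  d <- dim(x)
  x[ifftshift_idx(d[1]), ifftshift_idx(d[2]), ifftshift_idx(d[3]), drop = FALSE]
}

#' Unitary centered 3D Fourier transform
#'
#' Maps an image-domain volume (centre of field of view at the array
#' centre) to k-space with DC at the array centre. `ifft3c` is the exact
#' inverse (and adjoint, by unitarity).
#'
#' @param x complex (or numeric) 3D array
#' @return complex 3D array of the same shape
#' @export
fft3c <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  fftshift3(stats::fft(ifftshift3(x))) / sqrt(length(x))
}

#' @rdname fft3c
#' @export
ifft3c <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  fftshift3(stats::fft(ifftshift3(x), inverse = TRUE)) / sqrt(length(x))
}

# Native-order (wrap-around) unitary transforms used inside iterative
# solvers where the shift permutations would be dead weight: arrays are
# permuted once on entry and once on exit.
fft3u <- function(x) stats::fft(x) / sqrt(length(x))
ifft3u <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# Dimension-safe slicing: extract one 3D volume from a 4D array, or
# one (coil, echo) volume from a 5D array, without R's default
# dropping of singleton axes.
vol3 <- function(x, p) {
  d <- dim(x)
  y <- x[, , , p, drop = FALSE]
  dim(y) <- d[1:3]
  y
}

vol3_cp <- function(x, c, p) {
  d <- dim(x)
  y <- x[, , , c, p, drop = FALSE]
  dim(y) <- d[1:3]
  y
}

#' k-space centre index for a dimension of length n
#'
#' Centre convention: `floor(n/2) + 1` in 1-based indexing, matching the
#' centered-FFT layout for both even and odd lengths.
#'
#' @param n dimension length
#' @return integer index
#' @export
kcenter <- function(n) floor(n / 2) + 1L
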