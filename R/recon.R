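# Multi-volume parallel-imaging reconstruction.
#
# Five arms: the fully sampled RSS reference; volume-by-volume SENSE
# ("traditional"); jointly solved multi-volume CG-SENSE; joint-total-
# variation regularized SENSE; and model-based SENSE, which alternates
# data-consistency steps with a relaxation of the magnitude toward the
# voxelwise mono-exponential fit.
#
# Internally all iterative solvers work in FFT-native (wrap-around)
# order: sensitivities, masks and k-space are permuted once on entry so
# that every operator application is a plain unitary FFT plus pointwise
# products.

#' Reconstruction configuration
#'
#' @param method one of `"reference"`, `"traditional_sense"`,
#'   `"mv_sense"`, `"js_sense"`, `"mb_sense"`
#' @param lambda regularization weight; defaults per method: 0.1 for
#'   the joint-sparsity arm, 0.5 for the model-based arm, 0 otherwise.
#'   Applied on data normalized so the zero-filled RSS image has peak
#'   magnitude 1.
#' @param max_iter iteration budget of the (inner) CG / nonlinear-CG
#'   solver
#' @param tol relative-residual / relative-change stopping tolerance
#' @param jtv_epsilon smoothing constant of the joint total variation
#'   (in units of normalized intensity)
#' @param mb_outer outer (projection) iterations of the model-based arm
#' @param mb_inner data-consistency CG iterations per outer iteration
#' @param outer_tol relative-change stopping tolerance of the outer
#'   model-based loop
#' @return object of class `recon_config`
#' @export
recon_config <- function(method = c("mv_sense", "reference",
                                    "traditional_sense", "js_sense",
                                    "mb_sense"),
                         lambda = NULL, max_iter = 50L, tol = 1e-6,
                         jtv_epsilon = 1e-6, mb_outer = 20L,
                         mb_inner = 10L, outer_tol = 1e-4) {
  method <- match.arg(method)
  if (is.null(lambda)) {
    lambda <- switch(method, js_sense = 0.1, mb_sense = 0.5, 0)
  }
  stopifnot(lambda >= 0, max_iter >= 1)
  structure(list(method = method, lambda = lambda,
                 max_iter = as.integer(max_iter), tol = tol,
                 jtv_epsilon = jtv_epsilon, mb_outer = as.integer(mb_outer),
                 mb_inner = as.integer(mb_inner), outer_tol = outer_tol),
            class = "recon_config")
}

# ---- encoding operator -----------------------------------------------------

#' SENSE encoding operator
#'
#' Bundles coil sensitivities and a sampling mask into the forward model
#' k_c = M (F (S_c I)) per echo volume, with everything pre-permuted to
#' FFT-native order. [apply_encoding()] and [apply_adjoint()] expose the
#' operator pair; their adjoint identity is exact by construction
#' (unitary FFT, pointwise multiplications).
#'
#' @param coils a `coil_sens`
#' @param mask a `sampling_mask`
#' @return object of class `encoding_op`
#' @export
make_encoding_op <- function(coils, mask) {
  d <- dim(coils$maps)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nc <- d[4]
  dm <- dim(mask$pattern)
  stopifnot(dm[1] == ny, dm[2] == nz)
  sens <- vector("list", nc)
  for (c in seq_len(nc)) sens[[c]] <- ifftshift3(vol3(coils$maps, c))
  masks <- vector("list", dm[3])
  iy <- ifftshift_idx(ny); iz <- ifftshift_idx(nz)
  for (p in seq_len(dm[3])) {
    m2 <- mask$pattern[iy, iz, p]
    masks[[p]] <- array(rep(as.numeric(m2), each = nx), dim = c(nx, ny, nz))
  }
  structure(list(sens = sens, masks = masks, dims = c(nx, ny, nz),
                 n_coils = nc, n_te = dm[3]),
            class = "encoding_op")
}

#' Apply the encoding operator (image -> masked multi-coil k-space)
#'
#' @param op an `encoding_op`
#' @param x complex 3D image volume (native order)
#' @param p echo index selecting the per-volume mask
#' @return complex 4D array (x, y, z, coil) in native order
#' @export
apply_encoding <- function(op, x, p = 1L) {
  out <- array(0 + 0i, dim = c(op$dims, op$n_coils))
  m <- op$masks[[p]]
  for (c in seq_len(op$n_coils)) {
    out[, , , c] <- m * fft3u(op$sens[[c]] * x)
  }
  out
}

#' Apply the adjoint operator (masked multi-coil k-space -> image)
#'
#' @param op an `encoding_op`
#' @param y complex 4D array (x, y, z, coil) in native order
#' @param p echo index
#' @return complex 3D image volume (native order)
#' @export
apply_adjoint <- function(op, y, p = 1L) {
  acc <- array(0 + 0i, dim = op$dims)
  m <- op$masks[[p]]
  for (c in seq_len(op$n_coils)) {
    acc <- acc + Conj(op$sens[[c]]) * ifft3u(m * vol3(y, c))
  }
  acc
}

# Normal operator A = E^H D E for one echo volume, native order.
normal_op <- function(op, x, p) {
  acc <- array(0 + 0i, dim = op$dims)
  m <- op$masks[[p]]
  for (c in seq_len(op$n_coils)) {
    acc <- acc + Conj(op$sens[[c]]) * ifft3u(m * fft3u(op$sens[[c]] * x))
  }
  acc
}

# Right-hand side b = E^H D k per volume; k native 4D (x,y,z,coil).
rhs_vol <- function(op, k, p) {
  acc <- array(0 + 0i, dim = op$dims)
  m <- op$masks[[p]]
  for (c in seq_len(op$n_coils)) {
    acc <- acc + Conj(op$sens[[c]]) * ifft3u(m * vol3(k, c))
  }
  acc
}

cdot <- function(a, b) sum(Re(Conj(a) * b))

# Conjugate gradient on the (optionally Tikhonov-shifted) normal
# equations (A + shift I) x = b for one volume. Returns the iterate,
# the relative-residual history and a convergence flag. Starting from
# x0 = 0 with shift 0 yields the minimum-norm least-squares
# (pseudo-inverse) solution.
cg_normal <- function(op, b, p, x0 = NULL, max_iter = 50L, tol = 1e-6,
                      shift = 0) {
  x <- if (is.null(x0)) array(0 + 0i, dim = op$dims) else x0
  r <- b - normal_op(op, x, p) - shift * x
  d <- r
  rs <- cdot(r, r)
  bn <- sqrt(cdot(b, b))
  if (bn == 0) bn <- 1
  hist <- sqrt(rs) / bn
  converged <- hist[1] < tol
  it <- 0L
  while (!converged && it < max_iter) {
    it <- it + 1L
    Ad <- normal_op(op, d, p) + shift * d
    dAd <- cdot(d, Ad)
    if (dAd <= 0) break
    alpha <- rs / dAd
    x <- x + alpha * d
    r <- r - alpha * Ad
    rs_new <- cdot(r, r)
    hist <- c(hist, sqrt(rs_new) / bn)
    if (sqrt(rs_new) / bn < tol) { converged <- TRUE; break }
    d <- r + (rs_new / rs) * d
    rs <- rs_new
  }
  list(x = x, residuals = hist, converged = converged, iterations = it)
}

# k-space container -> native-order per-volume coil stacks.
kspace_native <- function(kspace) {
  d <- dim(kspace$data)
  ix <- ifftshift_idx(d[1]); iy <- ifftshift_idx(d[2]); iz <- ifftshift_idx(d[3])
  lapply(seq_len(d[5]), function(p) {
    x <- kspace$data[ix, iy, iz, , p, drop = FALSE]
    dim(x) <- d[1:4]
    x
  })
}

native_to_centered <- function(x3) fftshift3(x3)

# Peak magnitude of the zero-filled RSS image, used to normalize data
# before applying regularization weights.
zf_rss_peak <- function(kspace) {
  d <- dim(kspace$data)
  peak <- 0
  for (p in seq_len(d[5])) {
    acc <- array(0, dim = d[1:3])
    for (c in seq_len(d[4])) {
      acc <- acc + abs(ifft3c(vol3_cp(kspace$data, c, p)))^2
    }
    peak <- max(peak, sqrt(max(acc)))
  }
  peak
}

# ---- reference and SENSE arms ---------------------------------------------

#' Root-sum-of-squares reference reconstruction
#'
#' Direct inverse FFT per coil and echo followed by RSS coil
#' combination; requires fully sampled data (every line of the mask's
#' shutter present). Returns magnitude volumes.
#'
#' @param kspace a fully sampled `kspace_data`
#' @return an `mvimage` with real (magnitude) volumes
#' @export
recon_reference <- function(kspace) {
  m <- kspace$mask
  for (p in seq_len(dim(m$pattern)[3])) {
    if (any(m$shutter & !m$pattern[, , p]))
      stop("recon_reference requires fully sampled k-space")
  }
  d <- dim(kspace$data)
  vols <- array(0 + 0i, dim = c(d[1:3], d[5]))
  for (p in seq_len(d[5])) {
    acc <- array(0, dim = d[1:3])
    for (c in seq_len(d[4])) {
      acc <- acc + abs(ifft3c(vol3_cp(kspace$data, c, p)))^2
    }
    vols[, , , p] <- sqrt(acc)
  }
  mvimage(vols, kspace$te_list)
}

#' Multi-volume CG-SENSE reconstruction
#'
#' Solves \eqn{\min_I \|D E I - k\|_2^2} by conjugate gradient on the
#' normal equations, jointly over all echo volumes. The objective has
#' no cross-volume coupling, so the joint solve decouples into
#' independent per-volume CG solves, which the implementation exploits.
#'
#' @param kspace a masked `kspace_data`
#' @param coils a `coil_sens`
#' @param cfg a `recon_config`
#' @return an `mvimage` (complex volumes) with attributes `converged`
#'   and `residuals`
#' @export
recon_mv_sense <- function(kspace, coils, cfg = recon_config("mv_sense")) {
  op <- make_encoding_op(coils, kspace$mask)
  kn <- kspace_native(kspace)
  d <- dim(kspace$data)
  vols <- array(0 + 0i, dim = c(d[1:3], d[5]))
  conv <- logical(d[5])
  res <- vector("list", d[5])
  for (p in seq_len(d[5])) {
    b <- rhs_vol(op, kn[[p]], p)
    sol <- cg_normal(op, b, p, max_iter = cfg$max_iter, tol = cfg$tol)
    vols[, , , p] <- native_to_centered(sol$x)
    conv[p] <- sol$converged
    res[[p]] <- sol$residuals
  }
  if (!all(conv))
    warning("CG-SENSE did not reach tolerance within max_iter; ",
            "returning best iterate")
  out <- mvimage(vols, kspace$te_list)
  attr(out, "converged") <- all(conv)
  attr(out, "residuals") <- res
  out
}

#' Volume-by-volume (traditional) SENSE
#'
#' The second reference arm: the same CG solver as
#' [recon_mv_sense()], invoked separately per echo volume, as in
#' scanner-side SENSE with equally spaced undersampling.
#'
#' @inheritParams recon_mv_sense
#' @return an `mvimage`
#' @export
recon_traditional_sense <- function(kspace, coils,
                                    cfg = recon_config("traditional_sense")) {
  if (!kspace$mask$scheme %in% c("ES", "FULL"))
    warning("traditional SENSE is intended for equally spaced sampling")
  recon_mv_sense(kspace, coils, cfg)
}

# ---- joint total variation -------------------------------------------------

fwd_diff <- function(x, axis) {
  d <- dim(x)
  g <- array(0 + 0i, dim = d)
  n <- d[axis]
  if (n < 2) return(g)
  switch(axis,
         { g[-n, , ] <- x[-1, , ] - x[-n, , ] },
         { g[, -n, ] <- x[, -1, ] - x[, -n, ] },
         { g[, , -n] <- x[, , -1] - x[, , -n] })
  g
}

# Adjoint of the forward difference with replicate boundary.
fwd_diff_adj <- function(y, axis) {
  d <- dim(y)
  n <- d[axis]
  out <- array(0 + 0i, dim = d)
  if (n < 2) return(out)
  switch(axis,
         { out[1, , ] <- -y[1, , ]
           if (n > 2) out[2:(n - 1), , ] <- y[1:(n - 2), , ] - y[2:(n - 1), , ]
           out[n, , ] <- y[n - 1, , ] },
         { out[, 1, ] <- -y[, 1, ]
           if (n > 2) out[, 2:(n - 1), ] <- y[, 1:(n - 2), ] - y[, 2:(n - 1), ]
           out[, n, ] <- y[, n - 1, ] },
         { out[, , 1] <- -y[, , 1]
           if (n > 2) out[, , 2:(n - 1)] <- y[, , 1:(n - 2)] - y[, , 2:(n - 1)]
           out[, , n] <- y[, , n - 1] })
  out
}

#' Joint total variation of a multi-volume image
#'
#' \deqn{\|I\|_{JTV} = \sum_r \sqrt{\sum_p (|\nabla_x I|^2 +
#'   |\nabla_y I|^2 + |\nabla_z I|^2)}}
#' with forward differences and replicate boundary; the square modulus
#' couples gradients across all echo volumes, so a strong edge in any
#' volume protects the corresponding edge in the others.
#'
#' @param img an `mvimage` (or complex 4D array)
#' @param epsilon optional smoothing added inside the square root
#' @return non-negative scalar
#' @export
jtv_norm <- function(img, epsilon = 0) {
  v <- if (inherits(img, "mvimage")) img$volumes else img
  stopifnot(length(dim(v)) == 4L)
  d <- dim(v)
  s2 <- array(0, dim = d[1:3])
  for (p in seq_len(d[4])) {
    for (ax in 1:3) {
      g <- fwd_diff(vol3(v, p), ax)
      s2 <- s2 + Re(g * Conj(g))
    }
  }
  sum(sqrt(s2 + epsilon^2))
}

# Smoothed-JTV value and gradient (wrt conj(I), per volume) in one pass.
jtv_value_grad <- function(v, epsilon) {
  d <- dim(v)
  n_te <- d[4]
  gs <- vector("list", n_te)
  s2 <- array(0, dim = d[1:3])
  for (p in seq_len(n_te)) {
    gs[[p]] <- lapply(1:3, function(ax) fwd_diff(vol3(v, p), ax))
    for (ax in 1:3) {
      g <- gs[[p]][[ax]]
      s2 <- s2 + Re(g * Conj(g))
    }
  }
  s <- sqrt(s2 + epsilon^2)
  grad <- array(0 + 0i, dim = d)
  w <- 1 / (2 * s)
  for (p in seq_len(n_te)) {
    acc <- array(0 + 0i, dim = d[1:3])
    for (ax in 1:3) {
      acc <- acc + fwd_diff_adj(w * gs[[p]][[ax]], ax)
    }
    grad[, , , p] <- acc
  }
  list(value = sum(s), grad = grad)
}

#' l1,2 norm of the parametric fitting error
#'
#' \deqn{\|I - I_{fit}\|_{1,2} = \sqrt{\sum_r (\sum_p |I(r,p) -
#'   I_{fit}(r,p)|)^2}}: an l1 sum of residuals along the echo
#' dimension, combined in l2 over voxels.
#'
#' @param img,fitted `mvimage`s (or 4D arrays) of identical shape
#' @return non-negative scalar
#' @export
fit_error_norm <- function(img, fitted) {
  a <- if (inherits(img, "mvimage")) img$volumes else img
  b <- if (inherits(fitted, "mvimage")) fitted$volumes else fitted
  stopifnot(all(dim(a) == dim(b)))
  l1 <- apply(abs(a - b), 1:3, sum)
  sqrt(sum(l1^2))
}

# ---- joint-sparsity SENSE --------------------------------------------------

#' Joint-sparsity (JTV-regularized) SENSE
#'
#' Minimizes \eqn{\|D E I - k\|_2^2 + \lambda \|I\|_{JTV}} by nonlinear
#' conjugate gradient (Polak-Ribiere) on the smoothed JTV, with
#' backtracking line search; the objective is non-increasing across
#' accepted iterates. Before applying \eqn{\lambda} the k-space is
#' scaled so the zero-filled RSS image has peak magnitude 1, making the
#' printed default weight (0.1) transferable across data scales.
#'
#' @inheritParams recon_mv_sense
#' @return an `mvimage` with attributes `objective` (per-iteration
#'   values) and `converged`
#' @export
recon_js_sense <- function(kspace, coils, cfg = recon_config("js_sense")) {
  op <- make_encoding_op(coils, kspace$mask)
  kn <- kspace_native(kspace)
  scale <- zf_rss_peak(kspace)
  if (scale == 0) scale <- 1
  kn <- lapply(kn, function(k) k / scale)
  d <- dim(kspace$data)
  n_te <- d[5]
  lam <- cfg$lambda
  eps <- cfg$jtv_epsilon

  # initialize at the adjoint (zero-filled) image
  I <- array(0 + 0i, dim = c(d[1:3], n_te))
  b <- vector("list", n_te)
  for (p in seq_len(n_te)) {
    b[[p]] <- rhs_vol(op, kn[[p]], p)
    I[, , , p] <- b[[p]]
  }

  resid <- function(I) {
    # masked k-space residuals per volume
    lapply(seq_len(n_te), function(p) {
      apply_encoding(op, vol3(I, p), p) - kn[[p]]
    })
  }
  data_term <- function(rl) sum(vapply(rl, function(r) cdot(r, r), numeric(1)))

  grad_total <- function(I, rl) {
    g <- array(0 + 0i, dim = dim(I))
    for (p in seq_len(n_te)) {
      g[, , , p] <- apply_adjoint(op, rl[[p]], p)
    }
    if (lam > 0) {
      jv <- jtv_value_grad(I, eps)
      g <- g + lam * jv$grad
      attr(g, "jtv") <- jv$value
    } else {
      attr(g, "jtv") <- 0
    }
    g
  }

  rl <- resid(I)
  g <- grad_total(I, rl)
  f <- data_term(rl) + lam * attr(g, "jtv")
  dir <- -g
  obj <- f
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    # encoding of the search direction: quadratic data term along dir
    q <- lapply(seq_len(n_te), function(p) {
      apply_encoding(op, vol3(dir, p), p)
    })
    qq <- sum(vapply(q, function(x) cdot(x, x), numeric(1)))
    rq <- sum(vapply(seq_len(n_te),
                     function(p) cdot(rl[[p]], q[[p]]), numeric(1)))
    dphi0 <- 2 * cdot(g, dir)
    if (dphi0 >= 0) { # not a descent direction: restart once
      dir <- -g
      q <- lapply(seq_len(n_te), function(p) {
        apply_encoding(op, vol3(dir, p), p)
      })
      qq <- sum(vapply(q, function(x) cdot(x, x), numeric(1)))
      rq <- sum(vapply(seq_len(n_te),
                       function(p) cdot(rl[[p]], q[[p]]), numeric(1)))
      dphi0 <- 2 * cdot(g, dir)
      if (dphi0 >= 0) { converged <- TRUE; break }
    }
    alpha <- if (qq > 0) max(-dphi0 / (2 * qq), 1e-12) else 1
    f_data0 <- data_term(rl)
    accepted <- FALSE
    for (ls in seq_len(30)) {
      f_data <- f_data0 + 2 * alpha * rq + alpha^2 * qq
      f_jtv <- if (lam > 0) jtv_norm(I + alpha * dir, eps) else 0
      f_new <- f_data + lam * f_jtv
      if (f_new <= f + 1e-4 * alpha * dphi0) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!accepted) { converged <- TRUE; break }
    step <- sqrt(cdot(alpha * dir, alpha * dir)) /
      max(sqrt(cdot(I, I)), .Machine$double.eps)
    I <- I + alpha * dir
    rl <- lapply(seq_len(n_te), function(p) rl[[p]] + alpha * q[[p]])
    g_new <- grad_total(I, rl)
    f <- data_term(rl) + lam * attr(g_new, "jtv")
    obj <- c(obj, f)
    if (step < cfg$tol) { converged <- TRUE; break }
    beta <- max(0, cdot(g_new, g_new - g) / max(cdot(g, g),
                                                .Machine$double.eps))
    dir <- -g_new + beta * dir
    g <- g_new
  }

  vols <- array(0 + 0i, dim = dim(I))
  for (p in seq_len(n_te)) {
    vols[, , , p] <- native_to_centered(vol3(I, p)) * scale
  }
  out <- mvimage(vols, kspace$te_list)
  attr(out, "objective") <- obj
  attr(out, "converged") <- converged
  out
}

# ---- model-based SENSE -----------------------------------------------------

#' Model-based (exponential-decay constrained) SENSE
#'
#' An alternating scheme enforcing mono-exponential decay along the
#' echo dimension. Starting from the zero-filled adjoint image, each
#' outer iteration (a) fits every voxel's magnitude decay by
#' log-linear regression to \eqn{A_0 \exp(-TE \cdot R_2)}; (b) forms a
#' robust model-consistent target by soft-thresholding the fit
#' residual at its median absolute value (typical deviations snap
#' onto the fitted decay, strongly model-inconsistent voxels keep
#' their excess; phase is carried over; voxels without a valid
#' decaying fit are left at their current value); and (c) advances the
#' data-consistency problem with a quadratic penalty
#' \eqn{\lambda \|I - T\|^2} tying the iterate to the target — CG on
#' the Tikhonov-shifted normal equations, warm-started. The shifted
#' solves damp the noise amplification of an unregularized inversion
#' in poorly conditioned directions while the model term propagates
#' information along the echo dimension. \eqn{\lambda} (default 0.5)
#' balances SENSE data fidelity against the fitting-error term;
#' k-space is normalized to unit zero-filled peak before \eqn{\lambda}
#' is applied.
#'
#' @inheritParams recon_mv_sense
#' @return an `mvimage` with attribute `outer_iterations`
#' @export
recon_mb_sense <- function(kspace, coils, cfg = recon_config("mb_sense")) {
  op <- make_encoding_op(coils, kspace$mask)
  kn <- kspace_native(kspace)
  scale <- zf_rss_peak(kspace)
  if (scale == 0) scale <- 1
  kn <- lapply(kn, function(k) k / scale)
  d <- dim(kspace$data)
  n_te <- d[5]
  te <- kspace$te_list
  lam <- cfg$lambda

  b <- vector("list", n_te)
  I <- array(0 + 0i, dim = c(d[1:3], n_te))
  for (p in seq_len(n_te)) {
    b[[p]] <- rhs_vol(op, kn[[p]], p)
    I[, , , p] <- b[[p]]
  }

  if (lam == 0) {
    # no model term: the objective reduces to plain CG-SENSE
    for (p in seq_len(n_te)) {
      sol <- cg_normal(op, b[[p]], p, max_iter = cfg$max_iter,
                       tol = cfg$tol)
      I[, , , p] <- sol$x
    }
  }

  outer_done <- 0L
  if (lam > 0) {
    for (outer in seq_len(cfg$mb_outer)) {
      I_prev <- I
      # model-consistent target: voxelwise log-linear decay fit of the
      # current magnitudes, robustified by soft-thresholding the
      # residual at its median absolute value. Only voxels fitting a
      # genuine decay (R2 > 0) contribute: near-zero background
      # magnitudes can fit steeply growing exponentials that the
      # undersampled data could never correct.
      m <- abs(I)
      V <- matrix(m, ncol = n_te)
      fit <- fit_loglin(V, te)
      idx <- which(fit$ok & fit$r2 > 0)
      if (length(idx)) {
        pred <- exp(outer(fit$ln_a0[idx], rep(1, n_te)) -
                      outer(fit$r2[idx], te))
        sane <- rowSums(!is.finite(pred)) == 0
        idx <- idx[sane]
        pred <- pred[sane, , drop = FALSE]
      }
      T_mag <- V
      if (length(idx)) {
        # proximal map of the l1 deviation from the fitted decay:
        # voxels within tau of the model snap onto it, genuine
        # outliers keep their excess (robustness to voxels that do
        # not follow a mono-exponential). tau is the median absolute
        # residual over voxels with appreciable signal, so the vast
        # low-signal background cannot collapse it
        r <- V[idx, , drop = FALSE] - pred
        sig <- pred[, 1] > 0.05 * max(V)
        tau <- if (any(sig)) stats::median(abs(r[sig, ])) else
          stats::median(abs(r))
        T_mag[idx, ] <- pmax(pred + sign(r) * pmax(abs(r) - tau, 0), 0)
      }
      phase <- I / ifelse(m > 0, m, 1)
      Tc <- array(T_mag, dim = dim(m)) * phase
      # balance data fidelity against the fitting-error term: solve the
      # Tikhonov-shifted normal equations (A + lam) I = b + lam * T
      for (p in seq_len(n_te)) {
        sol <- cg_normal(op, b[[p]] + lam * vol3(Tc, p), p,
                         x0 = vol3(I, p),
                         max_iter = cfg$mb_inner, tol = cfg$tol,
                         shift = lam)
        I[, , , p] <- sol$x
      }
      outer_done <- outer
      rel <- sqrt(cdot(I - I_prev, I - I_prev)) /
        max(sqrt(cdot(I_prev, I_prev)), .Machine$double.eps)
      if (rel < cfg$outer_tol) break
    }
  }

  vols <- array(0 + 0i, dim = dim(I))
  for (p in seq_len(n_te)) {
    vols[, , , p] <- native_to_centered(vol3(I, p)) * scale
  }
  out <- mvimage(vols, kspace$te_list)
  attr(out, "outer_iterations") <- outer_done
  out
}

# ---- sensitivity estimation ------------------------------------------------

#' Estimate coil sensitivities from the auto-calibration region
#'
#' Per-coil low-resolution images are formed by windowing k-space to the
#' ACS block (Hamming apodization along both phase-encode axes to
#' suppress truncation ringing), inverse transforming, and dividing by
#' the root-sum-of-squares across coils. The result has unit RSS inside
#' the object support and is zeroed outside (support = RSS above 2% of
#' its peak). Uses the first echo volume (highest signal).
#'
#' @param kspace a `kspace_data` whose mask fully samples the ACS
#' @return a `coil_sens`
#' @export
estimate_sensitivities <- function(kspace) {
  m <- kspace$mask
  if (any(m$acs & !m$pattern[, , 1]))
    stop("ACS lines missing from the sampling pattern")
  d <- dim(kspace$data)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nc <- d[4]
  # Hamming window over the ACS extent, zero outside
  win_axis <- function(n, acs_col) {
    idx <- which(acs_col)
    w <- numeric(n)
    k <- length(idx)
    w[idx] <- if (k == 1) 1 else
      0.54 - 0.46 * cos(2 * pi * (seq_len(k) - 1) / (k - 1))
    w
  }
  acs_y <- apply(m$acs, 1, any)
  acs_z <- apply(m$acs, 2, any)
  wy <- win_axis(ny, acs_y)
  wz <- win_axis(nz, acs_z)
  w2 <- outer(wy, wz)
  w3 <- array(rep(as.vector(w2), each = nx), dim = c(nx, ny, nz))
  low <- array(0 + 0i, dim = c(nx, ny, nz, nc))
  for (c in seq_len(nc)) {
    low[, , , c] <- ifft3c(vol3_cp(kspace$data, c, 1) * w3)
  }
  rss <- sqrt(apply(abs(low)^2, 1:3, sum))
  support <- rss > 0.02 * max(rss)
  maps <- array(0 + 0i, dim = dim(low))
  denom <- ifelse(support, rss, 1)
  for (c in seq_len(nc)) {
    mc <- vol3(low, c) / denom
    mc[!support] <- 0 + 0i
    maps[, , , c] <- mc
  }
  structure(list(maps = maps), class = "coil_sens")
}
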