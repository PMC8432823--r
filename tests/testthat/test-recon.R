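# Fixtures here are deliberately small (32 x 32 x 8, 4 coils); the
# default-size study conditions are exercised by the acceptance tests.

noisy_ctx <- local({
  ctx <- NULL
  function() {
    if (is.null(ctx)) {
      spec <- small_spec()
      gt <- make_phantom(spec)
      coils <- make_coils(spec$n_coils, spec$grid_shape)
      img <- simulate_signal(gt)
      ksp <- simulate_kspace(img, coils,
                             spec$noise_sigma * max(gt$a0_map), seed = 3)
      ctx <<- list(spec = spec, gt = gt, coils = coils, img = img,
                   ksp = ksp, ref = recon_reference(ksp))
    }
    ctx
  }
})

test_that("encoding operator passes the randomized adjoint identity", {
  ctx <- noisy_ctx()
  mask <- make_caipi(32, 8, 3, 4, acs_size = c(8, 8))
  op <- make_encoding_op(ctx$coils, mask)
  for (i in 1:10) {
    x <- rand_cplx(c(32, 32, 8), seed = i)
    y <- rand_cplx(c(32, 32, 8, 4), seed = 100 + i)
    p <- 1L + (i %% 4L)
    lhs <- sum(Conj(y) * apply_encoding(op, x, p))
    rhs <- sum(Conj(apply_adjoint(op, y, p)) * x)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
})

test_that("CG-SENSE matches the dense pseudo-inverse on a tiny system", {
  dims <- c(8L, 8L, 1L)
  coils <- make_coils(4L, dims)
  mask <- make_es(8, 1, 2, 1, acs_size = c(2, 1))
  img <- mvimage(rand_cplx(c(dims, 1L), seed = 5), te_list = 0)
  ksp <- simulate_kspace(img, coils, noise_sigma = 0.05, seed = 6)
  ksp <- apply_mask(ksp, mask)

  sol <- recon_mv_sense(ksp, coils,
                        recon_config("mv_sense", max_iter = 300,
                                     tol = 1e-12))

  # dense stacked encoding matrix, column by column
  op <- make_encoding_op(coils, mask)
  n <- prod(dims)
  A <- matrix(0 + 0i, nrow = n * 4, ncol = n)
  for (i in seq_len(n)) {
    e <- array(0 + 0i, dim = dims); e[i] <- 1
    A[, i] <- as.vector(apply_encoding(op, e, 1))
  }
  kvec <- as.vector(kspace_native(ksp)[[1]])
  x_pinv <- MASS::ginv(A) %*% kvec
  x_img <- fftshift3(array(x_pinv, dim = dims))
  v1 <- sol$volumes[, , , 1, drop = FALSE]
  dim(v1) <- dims
  expect_lt(rel_l2(v1, x_img), 1e-6)
})

test_that("CG minimizes its quadratic objective monotonically", {
  # black-box check: the least-squares objective of the iterate after
  # k iterations never increases with k
  dims <- c(16L, 16L, 2L)
  coils <- make_coils(3L, dims)
  img <- mvimage(rand_cplx(c(dims, 1L), seed = 23), te_list = 0)
  ksp <- simulate_kspace(img, coils, 0.05, seed = 24)
  mask <- make_es(16, 2, 2, 1, acs_size = c(4, 2))
  ksp <- apply_mask(ksp, mask)
  op <- make_encoding_op(coils, mask)
  kn <- kspace_native(ksp)[[1]]
  objective <- function(x) {
    r <- apply_encoding(op, ifftshift3(x), 1) - kn
    sum(abs(r)^2)
  }
  objs <- vapply(1:10, function(k) {
    out <- suppressWarnings(
      recon_mv_sense(ksp, coils, recon_config("mv_sense", max_iter = k,
                                              tol = 1e-15)))
    objective(out$volumes[, , , 1])
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("traditional SENSE equals the joint solve (objective decouples)", {
  ctx <- noisy_ctx()
  mask <- make_es(32, 8, 2, 4, acs_size = c(8, 8))
  ksp <- apply_mask(ctx$ksp, mask)
  mv <- suppressWarnings(recon_mv_sense(ksp, ctx$coils))
  tr <- suppressWarnings(recon_traditional_sense(ksp, ctx$coils))
  expect_lt(rel_l2(tr$volumes, mv$volumes), 1e-8)
})

test_that("at ORF 1 SENSE agrees with the reference on band-limited data", {
  # smooth object, narrow enough that neither the array edge nor the
  # elliptical shutter removes appreciable energy
  dims <- c(32L, 32L, 8L)
  cx <- (dims[1] + 1) / 2
  g2 <- outer(exp(-((seq_len(32) - cx)^2) / (2 * 2.5^2)),
              exp(-((seq_len(32) - cx)^2) / (2 * 2.5^2)))
  vols <- array(0 + 0i, dim = c(dims, 2))
  for (p in 1:2) vols[, , , p] <- array(rep(g2 * c(1, 0.6)[p], 8), dim = dims)
  img <- mvimage(vols, te_list = c(0, 40))
  coils <- make_coils(4L, dims)
  ksp <- simulate_kspace(img, coils, 0)
  mask <- make_es(32, 8, 1, 2, acs_size = c(8, 8))
  ksp_m <- apply_mask(ksp, mask)
  ref <- recon_reference(ksp_m)
  tr <- recon_traditional_sense(ksp_m, coils,
                                recon_config("traditional_sense",
                                             max_iter = 400, tol = 1e-13))
  # the residual floor (~6e-6) is the energy of coil-normalization
  # harmonics beyond the elliptical shutter, which the zero-filled
  # reference discards but the coil-coupled solve recovers
  expect_lt(rel_l2(abs(tr$volumes), abs(ref$volumes)), 1e-5)
})

test_that("SENSE noise amplification grows with acceleration (g-factor)", {
  spec <- small_spec()
  gt <- make_phantom(spec)
  coils <- make_coils(4L, spec$grid_shape)
  img <- simulate_signal(gt, te_list = c(0, 45))
  sd_at <- function(orf) {
    mask <- make_es(32, 8, orf, 2, acs_size = c(8, 8))
    draws <- vapply(1:10, function(s) {
      ksp <- simulate_kspace(img, coils, 0.01 * max(gt$a0_map), seed = s)
      rec <- suppressWarnings(recon_traditional_sense(
        apply_mask(ksp, mask), coils))
      as.vector(abs(rec$volumes[, , , 1])[gt$roi_lv])
    }, numeric(sum(gt$roi_lv)))
    mean(apply(draws, 1, sd))
  }
  expect_gte(sd_at(4), sd_at(2))
})

test_that("joint total variation reproduces hand-computed values", {
  z <- array(0 + 0i, dim = c(3, 3, 1, 2))
  expect_equal(jtv_norm(z + 5), 0)
  # single discontinuity: gradient 3 in volume 1, 4 in volume 2 at the
  # same voxel, joined as sqrt(3^2 + 4^2) = 5
  a <- array(0, dim = c(2, 1, 1, 2))
  a[2, 1, 1, 1] <- 3
  a[2, 1, 1, 2] <- 4
  expect_equal(jtv_norm(a), 5)
  # absolute homogeneity
  x <- rand_cplx(c(4, 4, 2, 3), seed = 9)
  expect_equal(jtv_norm(-2.5 * x), 2.5 * jtv_norm(x), tolerance = 1e-10)
})

test_that("smoothed JTV gradient matches finite differences", {
  x <- rand_cplx(c(4, 3, 2, 2), seed = 13)
  eps <- 1e-3
  jv <- jtv_value_grad(x, eps)
  d <- rand_cplx(c(4, 3, 2, 2), seed = 14)
  h <- 1e-6
  num <- (jtv_norm(x + h * d, eps) - jtv_norm(x - h * d, eps)) / (2 * h)
  ana <- 2 * sum(Re(Conj(jv$grad) * d))
  expect_lt(abs(num - ana) / abs(num), 1e-4)
})

test_that("l1,2 fit-error norm reproduces hand-computed values", {
  a <- array(0, dim = c(2, 1, 1, 2))
  expect_equal(fit_error_norm(a, a), 0)
  b <- a; b[1, 1, 1, ] <- c(1, 2)
  expect_equal(fit_error_norm(b, a), 3)
  b[2, 1, 1, ] <- c(3, 1)   # second voxel l1 residual 4
  expect_equal(fit_error_norm(b, a), 5)
})

test_that("joint-sparsity SENSE reduces to CG-SENSE at lambda 0", {
  # tiny well-conditioned system so both solvers reach the minimizer
  dims <- c(16L, 16L, 2L)
  coils <- make_coils(2L, dims)
  img <- mvimage(rand_cplx(c(dims, 2L), seed = 17), te_list = c(0, 40))
  ksp <- simulate_kspace(img, coils, 0.02, seed = 18)
  ksp <- apply_mask(ksp, make_es(16, 2, 2, 2, acs_size = c(4, 2)))
  js0 <- recon_js_sense(ksp, coils,
                        recon_config("js_sense", lambda = 0,
                                     max_iter = 400, tol = 1e-12))
  mv <- recon_mv_sense(ksp, coils,
                       recon_config("mv_sense", max_iter = 400,
                                    tol = 1e-12))
  expect_lt(rel_l2(js0$volumes, mv$volumes), 1e-6)
})

test_that("joint-sparsity SENSE descends and improves the T2 maps", {
  ctx <- noisy_ctx()
  mask <- match_vdr_to_caipi(32, 8, 3, 4, seed = 8, acs_size = c(8, 8))
  ksp <- apply_mask(ctx$ksp, mask)
  ce <- estimate_sensitivities(ksp)
  js <- recon_js_sense(ksp, ce)
  expect_true(all(diff(attr(js, "objective")) <= 1e-9))

  # regularization pays off on the piecewise-constant phantom: T2 maps
  # from the joint-sparsity solve beat the unregularized CG solve
  mref <- fit_t2(ctx$ref)
  m_js <- fit_t2(js)
  m_mv <- fit_t2(suppressWarnings(recon_mv_sense(ksp, ce)))
  roi <- ctx$gt$roi_lv
  both_js <- roi & m_js$valid_mask & mref$valid_mask
  both_mv <- roi & m_mv$valid_mask & mref$valid_mask
  expect_lt(nrmse(m_js$t2_map, mref$t2_map, both_js),
            nrmse(m_mv$t2_map, mref$t2_map, both_mv))
})

test_that("model-based SENSE fixes exponential-consistent data and reduces to CG-SENSE at lambda 0", {
  ctx <- .small_ctx()  # noiseless, fully sampled, exponential truth
  mb <- recon_mb_sense(ctx$ksp, ctx$coils)
  expect_lt(rel_l2(abs(mb$volumes), abs(ctx$img$volumes)), 1e-6)
  expect_lte(attr(mb, "outer_iterations"), 2L)

  nctx <- noisy_ctx()
  mask <- make_es(32, 8, 2, 4, acs_size = c(8, 8))
  ksp <- apply_mask(nctx$ksp, mask)
  mb0 <- recon_mb_sense(ksp, nctx$coils,
                        recon_config("mb_sense", lambda = 0))
  mv <- suppressWarnings(recon_mv_sense(ksp, nctx$coils))
  # identical solver path up to the unit normalization of the data
  expect_lt(rel_l2(mb0$volumes, mv$volumes), 1e-10)
})

test_that("iterative reconstructions are deterministic", {
  dims <- c(16L, 16L, 2L)
  coils <- make_coils(2L, dims)
  img <- mvimage(rand_cplx(c(dims, 2L), seed = 19), te_list = c(0, 40))
  ksp <- simulate_kspace(img, coils, 0.02, seed = 20)
  ksp <- apply_mask(ksp, match_vdr_to_caipi(16, 2, 2, 2, seed = 8,
                                            acs_size = c(4, 2)))
  ce <- coils
  a <- recon_js_sense(ksp, ce, recon_config("js_sense", max_iter = 5))
  b <- recon_js_sense(ksp, ce, recon_config("js_sense", max_iter = 5))
  expect_identical(a$volumes, b$volumes)
  a <- recon_mb_sense(ksp, ce, recon_config("mb_sense", mb_outer = 2))
  b <- recon_mb_sense(ksp, ce, recon_config("mb_sense", mb_outer = 2))
  expect_identical(a$volumes, b$volumes)
})

test_that("sensitivity estimation recovers usable maps from the ACS", {
  ctx <- .small_ctx()
  full <- ctx$ksp
  est <- estimate_sensitivities(full)
  rss <- sqrt(apply(abs(est$maps)^2, 1:3, sum))
  support <- rss > 0.5
  expect_lt(max(abs(rss[support] - 1)), 1e-6)
  # reconstruction through estimated maps: in-object error below 2%
  mv <- recon_mv_sense(full, est)
  obj <- ctx$gt$a0_map > 0
  err <- abs(abs(mv$volumes[, , , 1])[obj] - abs(ctx$img$volumes[, , , 1])[obj])
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(abs(ctx$img$volumes[, , , 1])[obj]^2)),
            0.02)

  # constant-sensitivity coil: estimate is spatially constant
  dims <- c(16L, 16L, 4L)
  ones <- structure(list(maps = array(1 + 0i, dim = c(dims, 1L))),
                    class = "coil_sens")
  cx <- (dims[1] + 1) / 2
  g2 <- outer(exp(-((seq_len(16) - cx)^2) / 8),
              exp(-((seq_len(16) - cx)^2) / 8))
  img <- mvimage(array(rep(g2, 4), dim = c(dims, 1L)), te_list = 0)
  ksp1 <- simulate_kspace(img, ones, 0)
  est1 <- estimate_sensitivities(ksp1)
  rss1 <- abs(est1$maps[, , , 1])
  inside <- rss1 > 0
  expect_lt(max(abs(rss1[inside] - 1)), 1e-6)

  # ACS lines must be present
  bad <- apply_mask(ctx$ksp, make_es(32, 8, 2, 4, acs_size = c(8, 8)))
  bad$mask$pattern[kcenter(32), kcenter(8), 1] <- FALSE
  expect_error(estimate_sensitivities(bad), "ACS")
})
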