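test_that("elliptical shutter matches brute-force lattice enumeration", {
  # tiny grid: only the centre column/row survives the ellipse test
  s <- make_shutter(2, 2)
  expect_true(s[kcenter(2), kcenter(2)])

  ny <- 64L; nz <- 64L
  s <- make_shutter(ny, nz)
  brute <- 0L
  for (iy in seq_len(ny)) for (iz in seq_len(nz)) {
    dy <- 2 * (iy - kcenter(ny)) / ny
    dz <- 2 * (iz - kcenter(nz)) / nz
    if (dy^2 + dz^2 <= 1 + 1e-12) brute <- brute + 1L
  }
  expect_identical(sum(s), brute)
  # corner line sits at radius sqrt(2) and is excluded
  expect_false(s[1, 1])
})

test_that("ACS block has the stated size, position and error behaviour", {
  a <- make_acs(64, 64, c(16, 16))
  expect_identical(sum(a), 256L)
  expect_true(a[kcenter(64), kcenter(64)])
  expect_true(all(make_acs(16, 16, c(16, 16))))
  expect_error(make_acs(8, 8, c(16, 16)), "larger")
})

test_that("equally spaced sampling forms the advertised lattice", {
  # no reduction: pattern equals the shutter
  m1 <- make_es(64, 64, 1, 2)
  expect_true(all(m1$pattern[, , 1] == m1$shutter))
  # identical pattern across echo volumes
  m <- make_es(64, 64, 2, 4)
  for (p in 2:4) expect_identical(m$pattern[, , p], m$pattern[, , 1])
  # outside the ACS the sampled fraction matches the reduction factor
  out <- m$shutter & !m$acs
  frac <- sum(m$pattern[, , 1] & out) / sum(out)
  expect_lt(abs(frac - 0.5), 1 / 64)
})

test_that("CAIPI volumes tile complementary lattice cosets", {
  # orf 1: nothing to shear
  m1 <- make_caipi(64, 64, 1, 3)
  expect_true(all(m1$pattern[, , 1] == m1$shutter))

  # orf 4, 4 echoes: per-volume patterns pairwise disjoint outside ACS
  m <- make_caipi(64, 64, 4, 4)
  pats <- lapply(1:4, function(p) m$pattern[, , p] & !m$acs)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(any(pats[[i]] & pats[[j]]))
  }
  # equal per-volume line budgets
  counts <- vapply(1:4, function(p) sum(m$pattern[, , p]), integer(1))
  expect_true(all(counts == counts[1]))

  # shifts cycle with period orf: volumes p and p + orf coincide
  m2 <- make_caipi(64, 64, 2, 4)
  expect_identical(m2$pattern[, , 1], m2$pattern[, , 3])
  expect_identical(m2$pattern[, , 2], m2$pattern[, , 4])
  expect_false(identical(m2$pattern[, , 1], m2$pattern[, , 2]))

  # orf > n_te: only the first n_te shifts are used, all distinct
  m8 <- make_caipi(64, 64, 8, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_false(identical(m8$pattern[, , i], m8$pattern[, , j]))
  }
})

test_that("VDR draws the requested lines with a centre-weighted density", {
  # exhaustion: drawing every available line reproduces the shutter
  sh <- make_shutter(32, 32)
  acs <- make_acs(32, 32, c(8, 8))
  n_avail <- sum(sh & !acs)
  m_all <- make_vdr(32, 32, n_avail, 2, seed = 1, acs_size = c(8, 8))
  expect_true(all(m_all$pattern[, , 1] == sh))

  # exact count, no repeats, identical across echoes, seeded
  m <- make_vdr(32, 32, 100, 3, seed = 5, acs_size = c(8, 8))
  expect_identical(sum(m$pattern[, , 1] & !m$acs), 100L)
  expect_identical(m$pattern[, , 2], m$pattern[, , 1])
  m_again <- make_vdr(32, 32, 100, 3, seed = 5, acs_size = c(8, 8))
  expect_identical(m$pattern, m_again$pattern)
  expect_false(identical(
    make_vdr(32, 32, 100, 3, seed = 6, acs_size = c(8, 8))$pattern,
    m$pattern))
  expect_error(make_vdr(32, 32, n_avail + 1, 2, seed = 1,
                        acs_size = c(8, 8)), "exceeds")

  # Gaussian radial weighting concentrates lines near the centre:
  # mean sampled radius below that of uniform draws (Monte Carlo)
  dy <- (seq_len(32) - kcenter(32)) / 16
  rad <- sqrt(outer(dy^2, dy^2, `+`))
  avail <- which(sh & !acs)
  mean_r_vdr <- mean(vapply(1:200, function(s) {
    mm <- make_vdr(32, 32, 60, 1, seed = s, acs_size = c(8, 8))
    mean(rad[mm$pattern[, , 1] & !acs])
  }, numeric(1)))
  mean_r_unif <- mean(rad[avail])
  expect_lt(mean_r_vdr, mean_r_unif)
})

test_that("VDR matched to CAIPI has identical net reduction", {
  for (orf in c(1L, 3L, 4L)) {
    mc <- make_caipi(48, 16, orf, 4)
    mv <- match_vdr_to_caipi(48, 16, orf, 4, seed = 2)
    expect_equal(compute_rnet(mv)$mean, compute_rnet(mc)$mean,
                 tolerance = 1e-12)
  }
  # independent repeats: distinct patterns, identical line counts
  reps <- lapply(1:6, function(s) match_vdr_to_caipi(48, 16, 4, 4, seed = s))
  counts <- vapply(reps, function(m) sum(m$pattern[, , 1]), integer(1))
  expect_true(all(counts == counts[1]))
  expect_identical(length(unique(lapply(reps, function(m) m$pattern))), 6L)
})

test_that("net reduction accounting behaves like scan time", {
  full <- make_es(64, 64, 1, 2)
  expect_equal(compute_rnet(full)$mean, 1)

  # ES orf 4 with ACS: net factor strictly below the outer factor
  m4 <- make_es(64, 64, 4, 2)
  expect_lt(compute_rnet(m4)$mean, 4)
  expect_gt(compute_rnet(m4)$mean, 1)

  # monotone in ORF for all three schemes
  for (maker in list(
    function(orf) make_es(64, 64, orf, 2),
    function(orf) make_caipi(64, 64, orf, 2),
    function(orf) match_vdr_to_caipi(64, 64, orf, 2, seed = 3))) {
    rn <- vapply(1:8, function(orf) compute_rnet(maker(orf))$mean,
                 numeric(1))
    expect_true(all(diff(rn) >= -1e-12))
  }
})

test_that("every generated mask satisfies the containment invariants", {
  masks <- list(make_es(40, 12, 3, 3), make_caipi(40, 12, 4, 3),
                match_vdr_to_caipi(40, 12, 5, 3, seed = 9),
                make_full(40, 12, 3))
  for (m in masks) {
    for (p in seq_len(dim(m$pattern)[3])) {
      pat <- m$pattern[, , p]
      expect_true(all(pat[m$acs]))
      expect_false(any(pat & !m$shutter))
    }
  }
})

test_that("masks round-trip through the plain-text format", {
  m <- make_caipi(24, 10, 3, 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_mask(m, path)
  m2 <- read_mask(path)
  expect_identical(m2$pattern, m$pattern)
  expect_identical(m2$shutter, m$shutter)
  expect_identical(m2$acs, m$acs)
  expect_identical(m2$scheme, m$scheme)
  expect_identical(m2$orf, m$orf)
})
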