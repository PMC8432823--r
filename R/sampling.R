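# Retrospective phase-encode undersampling patterns.
#
# All patterns live on the (ky, kz) phase-encode plane; the readout
# direction is always fully sampled. Every generated mask keeps a fully
# sampled central auto-calibration (ACS) block and discards the corners
# of the plane beyond an inscribed ellipse (the "shutter"). The outer
# reduction factor (ORF) governs the density of sampling outside the
# ACS; the net reduction factor R_net — shutter lines divided by sampled
# lines — is what actually maps to scan-time saving.

#' Elliptical k-space shutter
#'
#' A phase-encode line (ky, kz) is retained iff
#' \eqn{(2 ky'/ny)^2 + (2 kz'/nz)^2 \le 1}, where ky', kz' are signed
#' offsets from the k-space centre index (boundary inclusive). Corners
#' of the phase-encode plane beyond the inscribed ellipse are never
#' acquired.
#'
#' @param ny,nz phase-encode grid dimensions (singleton dimensions are
#'   allowed and pass every line along that axis)
#' @return logical `ny x nz` matrix
#' @export
make_shutter <- function(ny, nz) {
  stopifnot(ny >= 1, nz >= 1)
  if (ny == 1 || nz == 1) {
    # degenerate ellipse: a single phase-encode row/column is kept whole
    return(matrix(TRUE, ny, nz))
  }
  dy <- (seq_len(ny) - kcenter(ny))
  dz <- (seq_len(nz) - kcenter(nz))
  r2 <- outer((2 * dy / ny)^2, (2 * dz / nz)^2, `+`)
  r2 <= 1 + 1e-12
}

#' Central auto-calibration (ACS) block
#'
#' Fully sampled central block of phase-encode lines, used both to
#' preserve low-frequency image contrast and to estimate coil
#' sensitivities. Default size 16 x 16 lines.
#'
#' @param ny,nz phase-encode grid dimensions
#' @param acs_size integer vector of length 2, block extent along (ky, kz)
#' @return logical `ny x nz` matrix
#' @export
make_acs <- function(ny, nz, acs_size = c(16L, 16L)) {
  acs_size <- as.integer(acs_size)
  if (length(acs_size) == 1L) acs_size <- rep(acs_size, 2L)
  if (acs_size[1] > ny || acs_size[2] > nz)
    stop("ACS block larger than the phase-encode grid")
  stopifnot(all(acs_size >= 1L))
  block <- function(n, w) {
    # centred block: centre index floor(n/2)+1 is always inside
    lo <- kcenter(n) - floor(w / 2)
    seq.int(lo, lo + w - 1L)
  }
  m <- matrix(FALSE, ny, nz)
  m[block(ny, acs_size[1]), block(nz, acs_size[2])] <- TRUE
  m
}

new_sampling_mask <- function(pattern, shutter, acs, orf, scheme,
                              seed = NA_integer_) {
  stopifnot(length(dim(pattern)) == 3L)
  structure(
    list(pattern = pattern, shutter = shutter, acs = acs,
         orf = as.integer(orf), scheme = scheme, seed = seed),
    class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  d <- dim(x$pattern)
  rn <- compute_rnet(x)
  cat(sprintf(
    "<sampling_mask> scheme=%s orf=%d grid=%dx%d volumes=%d R_net=%.3f\n",
    x$scheme, x$orf, d[1], d[2], d[3], rn$mean))
  invisible(x)
}

# Validate mask invariants: ACS inside every per-volume pattern, nothing
# sampled outside the shutter. Called by every generator.
assert_mask <- function(m) {
  for (p in seq_len(dim(m$pattern)[3])) {
    pat <- m$pattern[, , p]
    if (any(m$acs & !pat)) stop("ACS line missing from pattern")
    if (any(pat & !m$shutter)) stop("pattern extends outside shutter")
  }
  invisible(m)
}

# Balanced factorization of the outer reduction factor into per-axis
# factors Ry x Rz with Ry >= Rz: 2 -> 2x1, 3 -> 3x1, 4 -> 2x2,
# 5 -> 5x1, 6 -> 3x2, 7 -> 7x1, 8 -> 4x2.
orf_factors <- function(orf) {
  best <- c(orf, 1L)
  for (rz in seq_len(orf)) {
    if (orf %% rz == 0L) {
      ry <- orf %/% rz
      if (ry >= rz && abs(ry - rz) < abs(best[1] - best[2])) best <- c(ry, rz)
    }
  }
  best
}

#' Equally spaced (regular lattice) undersampling
#'
#' The classic Cartesian SENSE pattern: a regular lattice of reduction
#' `orf`, factored over the two phase-encode axes (balanced Ry x Rz with
#' Ry >= Rz), anchored so the k-space centre line is sampled. The same
#' pattern is used for every echo volume. ACS and shutter are applied.
#'
#' @param ny,nz phase-encode grid dimensions
#' @param orf outer reduction factor, 1..8
#' @param n_te number of echo volumes
#' @param acs_size ACS block extent
#' @return a `sampling_mask`
#' @export
make_es <- function(ny, nz, orf, n_te, acs_size = c(16L, 16L)) {
  stopifnot(orf >= 1, orf <= 8, n_te >= 1)
  shutter <- make_shutter(ny, nz)
  acs <- make_acs(ny, nz, pmin(acs_size, c(ny, nz))) & shutter
  f <- orf_factors(orf)
  dy <- (seq_len(ny) - kcenter(ny)) %% f[1]
  dz <- (seq_len(nz) - kcenter(nz)) %% f[2]
  lat <- outer(dy == 0, dz == 0, `&`)
  pat2 <- (lat | acs) & shutter
  pattern <- array(pat2, dim = c(ny, nz, n_te))
  assert_mask(new_sampling_mask(pattern, shutter, acs, orf, "ES"))
}

# ---- CAIPIRINHA-style sheared lattices ------------------------------------

# Membership test: is integer offset vector v = (vy, vz) an element of
# the sampling lattice generated by (Ry, 0) and (delta, Rz)?
lattice_member <- function(vy, vz, ry, rz, delta) {
  b_ok <- vz %% rz == 0
  b <- vz %/% rz
  b_ok & ((vy - b * delta) %% ry == 0)
}

# Aliasing-replica positions (in normalized field-of-view units, on the
# torus) of the lattice, and their minimum pairwise distance to the
# origin. Larger is better: replicas land further from the true voxel.
replica_min_dist <- function(ry, rz, delta) {
  a <- rep(seq_len(ry) - 1L, times = rz)
  b <- rep(seq_len(rz) - 1L, each = ry)
  py <- (a / ry) %% 1
  pz <- ((b - a * delta / ry) / rz) %% 1
  keep <- !(py == 0 & pz == 0)
  if (!any(keep)) return(Inf)
  dy <- pmin(py[keep], 1 - py[keep])
  dz <- pmin(pz[keep], 1 - pz[keep])
  min(sqrt(dy^2 + dz^2))
}

# Order of coset g in Z^2 / lattice (smallest m >= 1 with m*g in lattice).
coset_order <- function(g, ry, rz, delta) {
  n <- ry * rz
  for (m in seq_len(n)) {
    if (lattice_member(m * g[1], m * g[2], ry, rz, delta)) return(m)
  }
  n + 1L
}

# Choose the sheared-lattice geometry for a given ORF: exhaustive search
# over factorizations Ry x Rz = orf and intra-plane shifts delta,
# maximizing the minimum aliasing-replica distance; among optima prefer
# geometries whose quotient group is cyclic (so echo volumes can cycle
# through all orf lattice cosets) and smaller shear.
caipi_geometry <- function(orf) {
  best <- NULL
  for (rz in seq_len(orf)) {
    if (orf %% rz != 0L) next
    ry <- orf %/% rz
    for (delta in 0:(ry - 1L)) {
      d <- replica_min_dist(ry, rz, delta)
      gen <- caipi_generator(ry, rz, delta)
      cyc <- !is.null(gen)
      cand <- list(ry = ry, rz = rz, delta = delta, dist = d,
                   cyclic = cyc, gen = gen)
      if (is.null(best) ||
          d > best$dist + 1e-12 ||
          (abs(d - best$dist) <= 1e-12 && cyc && !best$cyclic)) {
        best <- cand
      }
    }
  }
  best
}

# A generator of the (cyclic) quotient group, preferring shifts along ky
# then kz; NULL if the quotient is not cyclic.
caipi_generator <- function(ry, rz, delta) {
  n <- ry * rz
  cands <- expand.grid(gy = 0:(ry * rz - 1L), gz = 0:(rz * ry - 1L))
  cands <- cands[order(cands$gz, cands$gy), ]  # prefer pure-ky shifts
  for (i in seq_len(nrow(cands))) {
    g <- c(cands$gy[i], cands$gz[i])
    if (all(g == 0)) next
    if (coset_order(g, ry, rz, delta) == n) return(g)
  }
  NULL
}

#' CAIPIRINHA-style sheared-lattice undersampling
#'
#' A sheared lattice of total reduction `orf` whose intra-plane shift is
#' chosen (by exhaustive search over factorizations and shears) to
#' maximize the minimum distance between aliasing replicas in the image
#' plane. Echo volume p additionally receives a cyclic lattice-coset
#' shift (p mod orf steps of a quotient-group generator, preferring the
#' ky axis), so successive echoes sample complementary interleaves; when
#' `orf` exceeds `n_te` only the first `n_te` shifts occur. Per-volume
#' sampled-line counts are equalized (largest-radius surplus lines are
#' dropped) so every echo has an identical line budget. ACS and shutter
#' are applied.
#'
#' @inheritParams make_es
#' @return a `sampling_mask`
#' @export
make_caipi <- function(ny, nz, orf, n_te, acs_size = c(16L, 16L)) {
  stopifnot(orf >= 1, orf <= 8, n_te >= 1)
  shutter <- make_shutter(ny, nz)
  acs <- make_acs(ny, nz, pmin(acs_size, c(ny, nz))) & shutter
  geo <- caipi_geometry(orf)
  shifts <- caipi_shift_table(geo, orf)

  dy <- seq_len(ny) - kcenter(ny)
  dz <- seq_len(nz) - kcenter(nz)
  vol_lattice <- function(p) {
    t_p <- shifts[[(p - 1L) %% orf + 1L]]
    vy <- outer(dy - t_p[1], rep(1L, nz))
    vz <- outer(rep(1L, ny), dz - t_p[2])
    matrix(lattice_member(as.vector(vy), as.vector(vz),
                          geo$ry, geo$rz, geo$delta), ny, nz)
  }
  pattern <- array(FALSE, dim = c(ny, nz, n_te))
  for (p in seq_len(n_te)) pattern[, , p] <- (vol_lattice(p) | acs) & shutter

  pattern <- equalize_counts(pattern, acs, shutter, ny, nz)
  assert_mask(new_sampling_mask(pattern, shutter, acs, orf, "CAIPI"))
}

# Per-volume lattice-coset shifts: p-th volume shifted by p steps of the
# quotient generator (cyclic in orf). Falls back to an enumeration of
# coset representatives when the quotient group is not cyclic.
caipi_shift_table <- function(geo, orf) {
  if (orf == 1L) return(list(c(0L, 0L)))
  if (geo$cyclic) {
    return(lapply(0:(orf - 1L), function(p) p * geo$gen))
  }
  # enumerate one representative per coset, deterministic order
  reps <- list()
  seen <- character()
  for (gz in 0:(geo$rz * geo$ry - 1L)) {
    for (gy in 0:(geo$ry * geo$rz - 1L)) {
      key <- NULL
      for (k in seq_along(reps)) {
        d <- c(gy, gz) - reps[[k]]
        if (lattice_member(d[1], d[2], geo$ry, geo$rz, geo$delta)) {
          key <- k; break
        }
      }
      if (is.null(key)) reps[[length(reps) + 1L]] <- c(gy, gz)
      if (length(reps) == orf) return(reps)
    }
  }
  reps
}

# Equalize per-volume sampled-line counts outside the ACS by dropping
# surplus lines at the largest k-space radius (deterministic tie-break
# on ky then kz index). Keeps every echo at an identical line budget.
equalize_counts <- function(pattern, acs, shutter, ny, nz) {
  n_te <- dim(pattern)[3]
  counts <- vapply(seq_len(n_te),
                   function(p) sum(pattern[, , p] & !acs), integer(1))
  target <- min(counts)
  if (all(counts == target)) return(pattern)
  dy <- (seq_len(ny) - kcenter(ny)) / (ny / 2)
  dz <- (seq_len(nz) - kcenter(nz)) / (nz / 2)
  rad <- outer(dy^2, dz^2, `+`)
  for (p in seq_len(n_te)) {
    extra <- counts[p] - target
    if (extra == 0L) next
    idx <- which(pattern[, , p] & !acs)
    ord <- order(-rad[idx], -((idx - 1L) %% ny), -((idx - 1L) %/% ny))
    drop <- idx[ord][seq_len(extra)]
    v <- pattern[, , p]
    v[drop] <- FALSE
    pattern[, , p] <- v
  }
  pattern
}

#' Variable-density random (VDR) undersampling
#'
#' Draws `n_lines` distinct phase-encode lines outside the ACS but
#' inside the shutter, without replacement, with probability
#' proportional to a Gaussian radial profile
#' \eqn{\exp(-d^2 / (2\sigma^2))} with \eqn{\sigma} = 0.5 x maximum
#' k-space radius (distance measured in normalized (ky, kz) units from
#' the k-space centre). The same pattern is applied to every echo
#' volume. Deterministic given `seed`.
#'
#' @inheritParams make_es
#' @param n_lines number of lines to draw outside the ACS
#' @param seed integer seed for the draw
#' @return a `sampling_mask`
#' @export
make_vdr <- function(ny, nz, n_lines, n_te, seed, acs_size = c(16L, 16L)) {
  shutter <- make_shutter(ny, nz)
  acs <- make_acs(ny, nz, pmin(acs_size, c(ny, nz))) & shutter
  avail <- which(shutter & !acs)
  if (n_lines > length(avail))
    stop("n_lines exceeds the number of available lines")
  dy <- (seq_len(ny) - kcenter(ny)) / (ny / 2)
  dz <- (seq_len(nz) - kcenter(nz)) / (nz / 2)
  d2 <- outer(dy^2, dz^2, `+`)
  rmax <- sqrt(max(d2[shutter]))
  sigma <- 0.5 * rmax
  w <- exp(-d2[avail] / (2 * sigma^2))
  pat2 <- acs & shutter
  if (n_lines > 0) {
    picked <- withr::with_seed(as.integer(seed),
      sample(avail, size = n_lines, replace = FALSE, prob = w))
    pat2[picked] <- TRUE
  }
  pattern <- array(pat2, dim = c(ny, nz, n_te))
  m <- new_sampling_mask(pattern, shutter, acs, orf = 1L, scheme = "VDR",
                         seed = as.integer(seed))
  assert_mask(m)
}

#' VDR mask with the line budget of the matching CAIPI pattern
#'
#' Builds the CAIPI mask for the requested ORF, counts its per-volume
#' non-ACS lines, and draws a VDR mask with exactly that count, so that
#' the two schemes have identical net reduction factors by construction.
#'
#' @inheritParams make_es
#' @param seed integer seed for the random draw
#' @return a `sampling_mask` with `scheme = "VDR"` and the requested `orf`
#'   recorded
#' @export
match_vdr_to_caipi <- function(ny, nz, orf, n_te, seed,
                               acs_size = c(16L, 16L)) {
  cai <- make_caipi(ny, nz, orf, n_te, acs_size)
  n_lines <- sum(cai$pattern[, , 1] & !cai$acs)
  m <- make_vdr(ny, nz, n_lines, n_te, seed, acs_size)
  m$orf <- as.integer(orf)
  m
}

#' Fully sampled mask
#'
#' The whole rectangular phase-encode plane (no shutter, no reduction);
#' used for the fully sampled reference arm.
#'
#' @inheritParams make_es
#' @return a `sampling_mask` with `scheme = "FULL"`
#' @export
make_full <- function(ny, nz, n_te, acs_size = c(16L, 16L)) {
  shutter <- matrix(TRUE, ny, nz)
  acs <- make_acs(ny, nz, pmin(acs_size, c(ny, nz)))
  pattern <- array(TRUE, dim = c(ny, nz, n_te))
  new_sampling_mask(pattern, shutter, acs, 1L, "FULL")
}

#' Net reduction factor of a sampling mask
#'
#' R_net = (number of lines inside the elliptical shutter) / (number of
#' sampled lines), reported per echo volume and as their mean. The ACS
#' overhead makes R_net smaller than the outer reduction factor.
#'
#' @param mask a `sampling_mask`
#' @return list with `per_volume` (numeric vector) and `mean`
#' @export
compute_rnet <- function(mask) {
  stopifnot(inherits(mask, "sampling_mask"))
  n_sh <- sum(mask$shutter)
  per <- vapply(seq_len(dim(mask$pattern)[3]), function(p) {
    ns <- sum(mask$pattern[, , p])
    if (ns == 0) stop("mask has zero sampled lines")
    n_sh / ns
  }, numeric(1))
  list(per_volume = per, mean = mean(per))
}

#' Write / read a sampling mask as plain text
#'
#' The pattern is stored as 0/1 characters (one phase-encode plane per
#' block) together with a JSON sidecar-style header carrying scheme,
#' ORF, seed and grid metadata. Round-trips exactly.
#'
#' @param mask a `sampling_mask`
#' @param path output file
#' @export
write_mask <- function(mask, path) {
  d <- dim(mask$pattern)
  hdr <- jsonlite::toJSON(list(
    scheme = mask$scheme, orf = mask$orf, seed = mask$seed,
    ny = d[1], nz = d[2], n_te = d[3]), auto_unbox = TRUE)
  body <- vapply(seq_len(d[3]), function(p) {
    paste(apply(mask$pattern[, , p], 1,
                function(r) paste(as.integer(r), collapse = "")),
          collapse = "\n")
  }, character(1))
  sh <- paste(apply(mask$shutter, 1,
                    function(r) paste(as.integer(r), collapse = "")),
              collapse = "\n")
  ac <- paste(apply(mask$acs, 1,
                    function(r) paste(as.integer(r), collapse = "")),
              collapse = "\n")
  writeLines(c(as.character(hdr), body, sh, ac), path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  ln <- readLines(path)
  hdr <- jsonlite::fromJSON(ln[1])
  parse_block <- function(rows) {
    out <- t(vapply(rows, function(r) as.integer(strsplit(r, "")[[1]]) == 1L,
                    logical(hdr$nz)))
    dimnames(out) <- NULL
    out
  }
  ln <- ln[-1]
  pattern <- array(FALSE, dim = c(hdr$ny, hdr$nz, hdr$n_te))
  for (p in seq_len(hdr$n_te)) {
    pattern[, , p] <- parse_block(ln[seq_len(hdr$ny)])
    ln <- ln[-seq_len(hdr$ny)]
  }
  shutter <- parse_block(ln[seq_len(hdr$ny)]); ln <- ln[-seq_len(hdr$ny)]
  acs <- parse_block(ln[seq_len(hdr$ny)])
  new_sampling_mask(pattern, shutter, acs, hdr$orf, hdr$scheme,
                    if (is.null(hdr$seed)) NA_integer_ else hdr$seed)
}
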