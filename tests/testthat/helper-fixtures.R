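# Small fixtures shared across tests. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

small_spec <- function(...) {
  args <- list(grid_shape = c(32L, 32L, 8L), n_coils = 4L,
               noise_sigma = 0.01)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# Cached noiseless context on the small grid (phantom, coils, signal,
# k-space) -- deterministic, built once per test run.
.small_ctx <- local({
  ctx <- NULL
  function() {
    if (is.null(ctx)) {
      spec <- small_spec(noise_sigma = 0)
      gt <- make_phantom(spec)
      coils <- make_coils(spec$n_coils, spec$grid_shape)
      img <- simulate_signal(gt)
      ksp <- simulate_kspace(img, coils, noise_sigma = 0)
      ctx <<- list(spec = spec, gt = gt, coils = coils, img = img,
                   ksp = ksp)
    }
    ctx
  }
})

rel_l2 <- function(a, b) {
  sqrt(sum(abs(a - b)^2)) / sqrt(sum(abs(b)^2))
}

rand_cplx <- function(dims, seed = 1) {
  n <- prod(dims)
  withr::with_seed(seed, {
    array(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)),
          dim = dims)
  })
}
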