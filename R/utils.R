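# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed; keeps results < 2^31.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 9973) %% 2147483629L)
}

# 3D Gaussian smoothing by FFT (circular); sigma per axis in voxels.
gaussianSmooth3 <- function(arr, sigma) {
  d <- dim(arr)
  kern1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1)))
    i <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-0.5 * (i / s)^2)
    k / sum(k)
  }
  kx <- kern1(d[1], sigma[1]); ky <- kern1(d[2], sigma[2]); kz <- kern1(d[3], sigma[3])
  K <- outer(outer(kx, ky), kz)
  dim(K) <- d
  Re(fft(fft(arr) * fft(K), inverse = TRUE)) / prod(d)
}

# Physical node coordinates (micrometres) of 0-based voxel indices.
voxelToUm <- function(idx0, voxelSize) idx0 * voxelSize

stopMsg <- function(...) stop(sprintf(...), call. = FALSE)
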