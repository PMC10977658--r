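# Separable Gaussian filtering and small morphology helpers for spot
# detection. Filtering is done as two banded-kernel matrix products
# (K_y %*% M %*% K_x), with truncated-and-renormalized kernels at the
# borders, so edge pixels are smoothed against their actual neighbors
# rather than wrapped or zero-padded.

.kernel_cache <- new.env(parent = emptyenv())

gaussian_kernel_matrix <- function(n, sigma) {
  key <- sprintf("%d_%g", n, sigma)
  K <- .kernel_cache[[key]]
  if (!is.null(K)) return(K)
  half <- ceiling(4 * sigma)
  idx <- seq_len(n)
  K <- matrix(0, n, n)
  offs <- -half:half
  w <- stats::dnorm(offs, sd = sigma)
  for (j in seq_along(offs)) {
    src <- idx + offs[j]
    ok <- src >= 1L & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + w[j]
  }
  K <- K / rowSums(K)
  .kernel_cache[[key]] <- K
  K
}

gaussian_blur <- function(mat, sigma) {
  Ky <- gaussian_kernel_matrix(nrow(mat), sigma)
  Kx <- gaussian_kernel_matrix(ncol(mat), sigma)
  Ky %*% mat %*% t(Kx)
}

# 2-D spatial median filter with replicate padding. radius 0 is identity.
median_filter <- function(mat, radius) {
  radius <- as.integer(radius)
  if (radius <= 0L) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  ri <- pmin(pmax(seq_len(nr + 2L * radius) - radius, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * radius) - radius, 1L), nc)
  pad <- mat[ri, ci]
  k <- (2L * radius + 1L)^2
  stack <- matrix(0, nr * nc, k)
  col <- 1L
  for (dy in 0:(2L * radius)) {
    for (dx in 0:(2L * radius)) {
      stack[, col] <- as.vector(pad[dy + seq_len(nr), dx + seq_len(nc)])
      col <- col + 1L
    }
  }
  matrix(apply(stack, 1L, stats::median), nr, nc)
}

# Logical matrix of strict 8-neighborhood local maxima (ties go to the
# earlier pixel in column-major order via >= on forward neighbors).
local_maxima <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mat
  res <- matrix(TRUE, nr, nc)
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      nb <- pad[2:(nr + 1L) + dy, 2:(nc + 1L) + dx]
      cmp <- if (dy > 0L || (dy == 0L && dx > 0L)) mat >= nb else mat > nb
      res <- res & cmp
    }
  }
  res
}
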