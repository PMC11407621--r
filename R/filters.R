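# Internal separable filtering machinery.
#
# All neighborhood operations in the ROI pipeline (Gaussian-weighted local
# means, box counts for erosion/dilation) are separable, so they are applied
# as banded-matrix products: out = By %*% X %*% t(Bx). This keeps the inner
# loops in BLAS, which is what makes frame-by-frame binarization of long
# stacks tractable in R.

#' Normalized 1-D Gaussian kernel truncated to the block
#' @noRd
gauss_kernel1d <- function(sigma, block_size) {
  r <- (block_size - 1L) %/% 2L
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g / sum(g)
}

#' Banded convolution matrix with reflected boundaries
#'
#' Row i of the result holds the kernel weights so that (B %*% x)[i] is the
#' kernel-weighted mean of x around i, with out-of-range indices reflected
#' about the edge (edge sample repeated: 0 -> 1, -1 -> 2, n+1 -> n, ...).
#' @noRd
band_reflect <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  B <- matrix(0, n, n)
  offs <- -r:r
  for (i in seq_len(n)) {
    idx <- i + offs
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    if (any(idx < 1L | idx > n)) {
      stopf("kernel of length %d too large for dimension %d", length(kernel), n)
    }
    for (k in seq_along(offs)) B[i, idx[k]] <- B[i, idx[k]] + kernel[k]
  }
  B
}

#' Banded sum matrix with zero padding, arbitrary window offsets
#' @noRd
band_zero <- function(n, offsets) {
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + offsets
    idx <- idx[idx >= 1L & idx <= n]
    B[i, idx] <- 1
  }
  B
}

#' Footprint offsets for a square structuring element of side fp
#'
#' Odd sides are centered; even sides anchor at the floor-center pixel
#' (offsets -fp%/%2 .. fp-1-fp%/%2), matching the usual image-processing
#' convention for even structuring elements.
#' @noRd
footprint_offsets <- function(fp) seq.int(0L, fp - 1L) - fp %/% 2L

#' Apply separable filter to one image
#' @noRd
sep_filter_image <- function(X, By, Bx) By %*% X %*% t(Bx)

#' Apply separable filter to a whole (H, W, T) stack
#'
#' The row (first-dimension) pass is a single batched BLAS product over all
#' frames; the column pass loops over frames with small products.
#' @noRd
sep_filter_stack <- function(arr, By, Bx) {
  d <- dim(arr)
  out <- array(By %*% matrix(arr, nrow = d[1L]), d)
  tBx <- t(Bx)
  for (t in seq_len(d[3L])) out[, , t] <- out[, , t] %*% tBx
  out
}

#' Label connected components of a binary image
#'
#' Union-find labeling; labels are assigned 1..K in order of each component's
#' first pixel in column-major (raster) order, so the labeling is
#' deterministic.
#'
#' @param mask binary matrix.
#' @param connectivity 8 (default, diagonal neighbors merge) or 4.
#' @return integer matrix of the same shape; 0 is background.
#' @noRd
label_components <- function(mask, connectivity = 8) {
  H <- nrow(mask)
  W <- ncol(mask)
  lab <- matrix(0L, H, W)
  fg <- which(mask != 0)
  nfg <- length(fg)
  if (nfg == 0L) return(lab)
  pos <- integer(H * W)
  pos[fg] <- seq_len(nfg)
  r <- (fg - 1L) %% H + 1L
  cc <- (fg - 1L) %/% H + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  ea <- integer(0)
  eb <- integer(0)
  for (o in offs) {
    ok <- r + o[1L] >= 1L & r + o[1L] <= H & cc + o[2L] >= 1L & cc + o[2L] <= W
    nidx <- fg[ok] + o[1L] + o[2L] * H
    hit <- pos[nidx] > 0L
    ea <- c(ea, pos[fg[ok]][hit])
    eb <- c(eb, pos[nidx][hit])
  }
  parent <- seq_len(nfg)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(ea)) {
    ra <- find(ea[k])
    rb <- find(eb[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nfg), find, integer(1))
  lab[fg] <- match(roots, unique(roots))
  lab
}
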