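# Brute-force reference implementations, written independently of the
# package internals (explicit loops, no shared helpers). These pin the
# package's boundary and connectivity conventions.

oracle_gauss_threshold <- function(img, sigma, block) {
  n1 <- nrow(img)
  n2 <- ncol(img)
  r <- (block - 1) %/% 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  refl <- function(i, n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
    i
  }
  thr <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      s <- 0
      for (a in -r:r) {
        for (b in -r:r) {
          s <- s + g[a + r + 1] * g[b + r + 1] *
            img[refl(i + a, n1), refl(j + b, n2)]
        }
      }
      thr[i, j] <- s
    }
  }
  thr
}

oracle_binarize <- function(img, sigma, block) {
  (img > oracle_gauss_threshold(img, sigma, block)) + 0
}

oracle_opening <- function(binary, fp) {
  n1 <- nrow(binary)
  n2 <- ncol(binary)
  offs <- seq.int(0, fp - 1) - fp %/% 2
  er <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      all1 <- TRUE
      for (a in offs) {
        for (b in offs) {
          ia <- i + a
          jb <- j + b
          v <- if (ia >= 1 && ia <= n1 && jb >= 1 && jb <= n2)
            binary[ia, jb] else 0  # zero padding
          if (v != 1) all1 <- FALSE
        }
      }
      er[i, j] <- as.numeric(all1)
    }
  }
  dil <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      any1 <- FALSE
      for (a in -offs) {  # reflected footprint
        for (b in -offs) {
          ia <- i + a
          jb <- j + b
          if (ia >= 1 && ia <= n1 && jb >= 1 && jb <= n2 &&
              er[ia, jb] == 1) any1 <- TRUE
        }
      }
      dil[i, j] <- as.numeric(any1)
    }
  }
  dil
}

# flood-fill connected-component labeling
oracle_label <- function(mask, connectivity = 8) {
  n1 <- nrow(mask)
  n2 <- ncol(mask)
  lab <- matrix(0L, n1, n2)
  nb <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  k <- 0L
  for (j in seq_len(n2)) {          # column-major scan, matching labels
    for (i in seq_len(n1)) {
      if (mask[i, j] != 0 && lab[i, j] == 0L) {
        k <- k + 1L
        queue <- list(c(i, j))
        lab[i, j] <- k
        while (length(queue)) {
          p <- queue[[1]]
          queue <- queue[-1]
          for (q in seq_len(nrow(nb))) {
            a <- p[1] + nb[q, 1]
            b <- p[2] + nb[q, 2]
            if (a >= 1 && a <= n1 && b >= 1 && b <= n2 &&
                mask[a, b] != 0 && lab[a, b] == 0L) {
              lab[a, b] <- k
              queue[[length(queue) + 1L]] <- c(a, b)
            }
          }
        }
      }
    }
  }
  lab
}

oracle_area_open <- function(binary, min_area) {
  lab <- oracle_label(binary, 8)
  out <- binary + 0
  if (max(lab) > 0) {
    for (l in seq_len(max(lab))) {
      if (sum(lab == l) < min_area) out[lab == l] <- 0
    }
  }
  out
}

random_binary <- function(n1, n2, p = 0.4) {
  matrix(as.numeric(runif(n1 * n2) < p), n1, n2)
}
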