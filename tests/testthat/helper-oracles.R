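# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with R/.

# Scan all 64 cells and every horizontal/vertical adjacency of a letter grid.
oracle_validate_layout <- function(lay) {
  expected <- c(H = 24, K = 2, L = 16, V = 1, W = 1, X = 8, Y = 8, Z = 4)
  counts <- table(factor(c(lay), levels = names(expected)))
  if (!all(counts == expected)) return(FALSE)
  xy <- zk <- zv <- zw <- 0
  for (r in 1:8) for (c in 1:8) {
    l <- lay[r, c]
    if (l == "X") {
      if (c == 8 || lay[r, c + 1] != "Y") return(FALSE)
      xy <- xy + 1
    }
    if (l == "Y" && (c == 1 || lay[r, c - 1] != "X")) return(FALSE)
    if (l %in% c("K", "V", "W")) {
      if (r == 1 || lay[r - 1, c] != "Z") return(FALSE)
      if (l == "K") zk <- zk + 1
      if (l == "V") zv <- zv + 1
      if (l == "W") zw <- zw + 1
    }
    if (l == "Z" && (r == 8 || !lay[r + 1, c] %in% c("K", "V", "W"))) {
      return(FALSE)
    }
  }
  xy == 8 && zk == 2 && zv == 1 && zw == 1
}

# Exhaustive nearest-center labeling over every pixel.
oracle_nearest_scan <- function(centers, size) {
  lab <- matrix(0L, size, size)
  for (r in seq_len(size)) for (c in seq_len(size)) {
    d <- (centers[, 1] - r)^2 + (centers[, 2] - c)^2
    lab[r, c] <- which.min(d)
  }
  lab
}

# Two-sample KS by direct ECDF enumeration on the pooled support.
oracle_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(p) {
    abs(sum(a <= p) / length(a) - sum(b <= p) / length(b))
  }, numeric(1)))
}

# Brute-force k-NN ball membership enumeration.
oracle_coverage_density <- function(real, gen, k) {
  n <- nrow(real); m <- nrow(gen)
  radius <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((real - matrix(real[i, ], n, ncol(real),
                                     byrow = TRUE))^2))
    radius[i] <- sort(d[-i])[k]
  }
  covered <- logical(n)
  total <- 0
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      dij <- sqrt(sum((gen[j, ] - real[i, ])^2))
      if (dij <= radius[i]) {
        covered[i] <- TRUE
        total <- total + 1
      }
    }
  }
  list(coverage = mean(covered), density = total / (k * m))
}

# Moran's I from the textbook double sum with rook weights.
oracle_morans_i <- function(tile) {
  nr <- nrow(tile); nc <- ncol(tile)
  n <- nr * nc
  x <- as.numeric(tile)
  xb <- mean(x)
  idx <- function(r, c) (c - 1) * nr + r
  num <- 0; s0 <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        num <- num + (x[idx(r, c)] - xb) * (x[idx(r2, c2)] - xb)
        s0 <- s0 + 1
      }
    }
  }
  (n / s0) * num / sum((x - xb)^2)
}

# Naive per-pixel GLCM features for one offset, symmetric counts.
oracle_glcm <- function(img, dr, dc, levels = 32) {
  q <- matrix(pmin(levels, floor(img / (256 / levels)) + 1),
              nrow(img), ncol(img))
  cnt <- matrix(0, levels, levels)
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
      cnt[q[r, c], q[r2, c2]] <- cnt[q[r, c], q[r2, c2]] + 1
    }
  }
  cnt <- cnt + t(cnt)
  p <- cnt / sum(cnt)
  i <- row(p); j <- col(p)
  mu <- sum(p * i); sg <- sqrt(sum(p * (i - mu)^2))
  c(contrast = sum(p * (i - j)^2),
    homogeneity = sum(p / (1 + (i - j)^2)),
    energy = sum(p^2),
    correlation = sum(p * (i - mu) * (j - mu)) / sg^2)
}
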