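# Independent brute-force oracles: plain per-pixel loops with the mask
# weights written out by hand, sharing no code with the package internals.

# The eight compass stencils, 0 = East, counter-clockwise, hand-transcribed.
oracle_masks <- list(
  matrix(c(-3, -3, 5,   -3, 0, 5,   -3, -3, 5), 3, byrow = TRUE),   # 0
  matrix(c(-3,  5, 5,   -3, 0, 5,   -3, -3, -3), 3, byrow = TRUE),  # 45
  matrix(c( 5,  5, 5,   -3, 0, -3,  -3, -3, -3), 3, byrow = TRUE),  # 90
  matrix(c( 5,  5, -3,   5, 0, -3,  -3, -3, -3), 3, byrow = TRUE),  # 135
  matrix(c( 5, -3, -3,   5, 0, -3,   5, -3, -3), 3, byrow = TRUE),  # 180
  matrix(c(-3, -3, -3,   5, 0, -3,   5,  5, -3), 3, byrow = TRUE),  # 225
  matrix(c(-3, -3, -3,  -3, 0, -3,   5,  5,  5), 3, byrow = TRUE),  # 270
  matrix(c(-3, -3, -3,  -3, 0, 5,   -3,  5,  5), 3, byrow = TRUE)   # 315
)

oracle_correlate <- function(image, mask) {
  h <- nrow(image); w <- ncol(image)
  out <- matrix(NA_real_, h - 2, w - 2)
  for (r in 2:(h - 1)) {
    for (c in 2:(w - 1)) {
      acc <- 0
      for (dr in -1:1) for (dc in -1:1) {
        acc <- acc + mask[dr + 2, dc + 2] * image[r + dr, c + dc]
      }
      out[r - 1, c - 1] <- acc
    }
  }
  out
}

# Naive LDDSCP code pair over the interior of an image.
oracle_lddscp <- function(image) {
  resp <- lapply(oracle_masks, oracle_correlate, image = image)
  h <- nrow(resp[[1]]); w <- ncol(resp[[1]])
  c1 <- matrix(0L, h, w); c2 <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      v <- vapply(resp, function(m) m[r, c], numeric(1))
      a1 <- mean(v[1:4]); a2 <- mean(v[5:8])
      b1 <- 0L; b2 <- 0L
      for (i in 0:3) {
        if (v[i + 1] >= a1) b1 <- b1 + as.integer(2^i)
        if (v[i + 5] >= a2) b2 <- b2 + as.integer(2^i)
      }
      c1[r, c] <- b1; c2[r, c] <- b2
    }
  }
  list(code1 = c1, code2 = c2)
}

# Naive LBP / CS-LBP / LDP codes (interior pixels only). Neighbor ring:
# E, NE, N, NW, W, SW, S, SE as (dr, dc) with row 1 on top.
oracle_ring <- rbind(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
                     c(0, -1), c(1, -1), c(1, 0), c(1, 1))

oracle_lbp <- function(image) {
  h <- nrow(image); w <- ncol(image)
  out <- matrix(0L, h - 2, w - 2)
  for (r in 2:(h - 1)) for (c in 2:(w - 1)) {
    v <- 0L
    for (i in 1:8) {
      nb <- image[r + oracle_ring[i, 1], c + oracle_ring[i, 2]]
      if (nb >= image[r, c]) v <- v + as.integer(2^(i - 1))
    }
    out[r - 1, c - 1] <- v
  }
  out
}

oracle_cslbp <- function(image, threshold = 0) {
  h <- nrow(image); w <- ncol(image)
  out <- matrix(0L, h - 2, w - 2)
  for (r in 2:(h - 1)) for (c in 2:(w - 1)) {
    v <- 0L
    for (i in 1:4) {
      a <- image[r + oracle_ring[i, 1], c + oracle_ring[i, 2]]
      b <- image[r + oracle_ring[i + 4, 1], c + oracle_ring[i + 4, 2]]
      if (a - b > threshold) v <- v + as.integer(2^(i - 1))
    }
    out[r - 1, c - 1] <- v
  }
  out
}

oracle_ldp <- function(image, k = 3) {
  resp <- lapply(oracle_masks, oracle_correlate, image = image)
  h <- nrow(resp[[1]]); w <- ncol(resp[[1]])
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    v <- abs(vapply(resp, function(m) m[r, c], numeric(1)))
    top <- order(-v, seq_len(8))[seq_len(k)]
    out[r, c] <- as.integer(sum(2^(top - 1)))
  }
  out
}

# Naive histogram tally of code values lo..hi.
oracle_hist <- function(codes, lo, hi) {
  counts <- integer(hi - lo + 1L)
  for (v in as.vector(codes)) {
    if (v >= lo && v <= hi) counts[v - lo + 1L] <- counts[v - lo + 1L] + 1L
  }
  counts
}

# Naive leave-one-sample-out KNN: all-pairs distance loops, majority vote,
# vote tie -> nearest neighbor's label, distance tie -> lower index.
oracle_loso_knn <- function(features, labels, k = 1, metric = "euclidean") {
  n <- nrow(features)
  pred <- character(n)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j == i) next
      if (metric == "euclidean") {
        d[j] <- sqrt(sum((features[i, ] - features[j, ])^2))
      } else {
        d[j] <- sum((features[i, ] - features[j, ])^2 /
                      (features[i, ] + features[j, ] + 1e-10))
      }
    }
    ord <- order(d, seq_len(n))
    nn <- ord[seq_len(k)]
    tab <- table(labels[nn])
    winners <- names(tab)[tab == max(tab)]
    pred[i] <- if (length(winners) == 1) winners else labels[ord[1]]
  }
  list(predictions = pred, accuracy = mean(pred == labels))
}

random_image <- function(h, w = h, max_val = 255) {
  matrix(sample.int(max_val + 1L, h * w, replace = TRUE) - 1L, h, w)
}
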