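# Shared fixture builders: all fixtures are generated in code.

# Small random grey matrix with reproducible content.
rand_gray <- function(nr, nc, seed, lo = 0L, hi = 255L) {
  withr::with_seed(seed, matrix(sample(lo:hi, nr * nc, replace = TRUE), nr, nc))
}

# Small random RGB array.
rand_rgb <- function(nr, nc, seed) {
  withr::with_seed(seed, {
    a <- array(sample(0:255, nr * nc * 3, replace = TRUE), dim = c(nr, nc, 3))
    storage.mode(a) <- "integer"
    a
  })
}

# Random logical mask with given foreground probability.
rand_mask <- function(nr, nc, seed, p = 0.3) {
  withr::with_seed(seed, matrix(stats::runif(nr * nc) < p, nr, nc))
}

# Brute-force median filter: per-pixel neighbourhood sort on a
# replicate-padded copy. The independent oracle for median_denoise.
naive_median <- function(image, window) {
  k <- (window - 1L) %/% 2L
  p <- image[c(rep(1, k), seq_len(nrow(image)), rep(nrow(image), k)),
             c(rep(1, k), seq_len(ncol(image)), rep(ncol(image), k))]
  out <- matrix(0L, nrow(image), ncol(image))
  for (i in seq_len(nrow(image)))
    for (j in seq_len(ncol(image)))
      out[i, j] <- stats::median(p[i:(i + 2 * k), j:(j + 2 * k)])
  out
}

# Naive two-pass local variance of a 0/1 mask, replicate borders,
# rescaled as in local_variance_map.
naive_variance_map <- function(mask, window) {
  k <- (window - 1L) %/% 2L
  m <- mask * 1
  p <- m[c(rep(1, k), seq_len(nrow(m)), rep(nrow(m), k)),
         c(rep(1, k), seq_len(ncol(m)), rep(ncol(m), k))]
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m))) {
      win <- p[i:(i + 2 * k), j:(j + 2 * k)]
      v <- mean(win^2) - mean(win)^2
      out[i, j] <- as.integer(floor(v / 0.25 * 255 + 0.5))
    }
  out
}

# Independent maximum-entropy threshold: direct loop over all 256 candidate
# splits, entropies computed term by term.
naive_entropy_threshold <- function(response) {
  lo <- min(response); hi <- max(response)
  bins <- floor((response - lo) / (hi - lo) * 255 + 0.5)
  n <- length(bins)
  best_t <- NA; best_psi <- -Inf
  for (t in 0:254) {
    pb <- sum(bins <= t) / n
    if (pb <= 0 || pb >= 1) next
    hb <- 0; hf <- 0
    for (b in 0:255) {
      p <- sum(bins == b) / n
      if (p == 0) next
      if (b <= t) hb <- hb - (p / pb) * log(p / pb)
      else hf <- hf - (p / (1 - pb)) * log(p / (1 - pb))
    }
    psi <- hb + hf
    if (psi > best_psi + 1e-12) { best_psi <- psi; best_t <- t }
  }
  lo + (best_t + 0.5) * (hi - lo) / 255
}

# Recursive flood-fill component counter (8-connectivity), independent of
# label_components.
flood_count <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    n <- n + 1L
    queue <- start
    seen[start] <- TRUE
    nr <- nrow(mask)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1) %% nr + 1; cl <- (cur - 1) %/% nr + 1
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- cl + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > ncol(mask)) next
        idx <- (c2 - 1) * nr + r2
        if (mask[idx] && !seen[idx]) { seen[idx] <- TRUE; queue <- c(queue, idx) }
      }
    }
  }
  n
}
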