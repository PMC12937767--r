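# In-code fixtures and independent brute-force oracles. Every oracle here
# recomputes its quantity with naive loops straight from the defining
# formulas, sharing no code with the implementation it checks.

rand_image <- function(h, w, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3, 0, 255), c(h, w, 3))
}

rand_standard_image <- function(seed = 1) rand_image(224, 224, seed)

const_image <- function(v, h = 224, w = 224) array(v, c(h, w, 3))

# --- convolution oracle: nested loops with edge-inclusive reflect padding --
oracle_convolve <- function(plane, kernel) {
  k <- (nrow(kernel) - 1) / 2
  n <- nrow(plane); m <- ncol(plane)
  reflect <- function(i, lim) {
    if (i < 1) 1 - i else if (i > lim) 2 * lim - i + 1 else i
  }
  out <- matrix(0, n, m)
  for (r in 1:n) for (c in 1:m) {
    acc <- 0
    for (dr in -k:k) for (dc in -k:k) {
      acc <- acc + kernel[dr + k + 1, dc + k + 1] *
        plane[reflect(r + dr, n), reflect(c + dc, m)]
    }
    out[r, c] <- acc
  }
  out
}

# --- GLCM oracle: enumerate every pixel pair at the offset, symmetrize -----
oracle_glcm <- function(gray, G, dr, dc) {
  n <- nrow(gray); m <- ncol(gray)
  C <- matrix(0, G, G)
  for (r in 1:n) for (c in 1:m) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= n && c2 >= 1 && c2 <= m) {
      i <- gray[r, c] + 1; j <- gray[r2, c2] + 1
      C[i, j] <- C[i, j] + 1
      C[j, i] <- C[j, i] + 1
    }
  }
  C / sum(C)
}

# --- Haralick oracle: literal per-statistic sums, no shared intermediates --
oracle_haralick <- function(P) {
  G <- nrow(P)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(P); py <- colSums(P)
  mu_x <- 0; for (i in 1:G) mu_x <- mu_x + (i - 1) * px[i]
  mu_y <- 0; for (j in 1:G) mu_y <- mu_y + (j - 1) * py[j]
  sd_x <- sqrt(sum(((0:(G - 1)) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((0:(G - 1)) - mu_y)^2 * py))

  asm <- 0; contrast <- 0; corr_num <- 0; variance <- 0; idm <- 0; ent <- 0
  psum <- rep(0, 2 * G - 1)   # k = 0 .. 2G-2
  pdif <- rep(0, G)           # k = 0 .. G-1
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    corr_num <- corr_num + (i - 1 - mu_x) * (j - 1 - mu_y) * p
    variance <- variance + (i - 1 - mu_x)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    ent <- ent - p * lg(p)
    psum[i + j - 1] <- psum[i + j - 1] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
  }
  sumavg <- sum((0:(2 * G - 2)) * psum)
  sumvar <- sum(((0:(2 * G - 2)) - sumavg)^2 * psum)
  sument <- -sum(sapply(psum, function(p) p * lg(p)))
  mudif <- sum((0:(G - 1)) * pdif)
  difvar <- sum(((0:(G - 1)) - mudif)^2 * pdif)
  difent <- -sum(sapply(pdif, function(p) p * lg(p)))
  hx <- -sum(sapply(px, function(p) p * lg(p)))
  hy <- -sum(sapply(py, function(p) p * lg(p)))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:G) for (j in 1:G) {
    q <- px[i] * py[j]
    hxy1 <- hxy1 - P[i, j] * lg(q)
    hxy2 <- hxy2 - q * lg(q)
  }
  corr <- if (sd_x * sd_y > 0) corr_num / (sd_x * sd_y) else 0
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(asm, contrast, corr, variance, idm, sumavg, sumvar, sument, ent,
    difvar, difent, imc1, imc2)
}

# --- moment oracle: naive double loop, x = column, y = row, 0-based --------
oracle_central_moment <- function(gray, p, q) {
  tot <- sum(gray)
  xb <- 0; yb <- 0
  for (r in 1:nrow(gray)) for (c in 1:ncol(gray)) {
    xb <- xb + (c - 1) * gray[r, c]
    yb <- yb + (r - 1) * gray[r, c]
  }
  xb <- xb / tot; yb <- yb / tot
  acc <- 0
  for (r in 1:nrow(gray)) for (c in 1:ncol(gray)) {
    acc <- acc + (c - 1 - xb)^p * (r - 1 - yb)^q * gray[r, c]
  }
  acc
}

# --- histogram oracle: per-pixel tally ------------------------------------
oracle_histogram <- function(v, lo, hi, bins) {
  counts <- rep(0L, bins)
  w <- (hi - lo) / bins
  for (x in v) {
    b <- min(floor((x - lo) / w) + 1, bins)
    counts[b] <- counts[b] + 1L
  }
  counts
}

# A filled disk image (unit intensity scaled to 255) centred in the frame.
disk_gray <- function(n, radius) {
  Y <- matrix(0:(n - 1), n, n)
  X <- t(Y)
  ifelse((X - (n - 1) / 2)^2 + (Y - (n - 1) / 2)^2 <= radius^2, 255, 0)
}

gray_as_image <- function(gray) {
  array(rep(gray, 3), c(dim(gray), 3))
}

# Small metadata tibble used across metadata tests.
toy_records <- function() {
  tibble::tibble(
    age = c(40, 60, 50, NA),
    gender = c("Male", "Female", "Female", "Male"),
    diameter_1 = c(5, 7, 6, 8),
    diameter_2 = c(4, 6, 5, 7),
    smoke = c(TRUE, FALSE, FALSE, TRUE),
    drink = c(FALSE, FALSE, TRUE, FALSE),
    itch = c(TRUE, TRUE, FALSE, FALSE),
    grew = c(FALSE, TRUE, FALSE, TRUE),
    hurt = c(FALSE, FALSE, FALSE, TRUE),
    changed = c(TRUE, FALSE, TRUE, FALSE),
    bleed = c(FALSE, FALSE, FALSE, FALSE),
    elevation = c(TRUE, TRUE, TRUE, FALSE)
  )
}

# Six-class, well-separated Gaussian feature table for ensemble tests.
gaussian_blobs <- function(n_per_class, n_features = 10, sep = 8, seed = 1) {
  set.seed(seed)
  classes <- lesion_classes()
  x <- do.call(rbind, lapply(seq_along(classes), function(k) {
    centre <- rep(0, n_features)
    centre[((k - 1) %% n_features) + 1] <- sep
    centre[(k %% n_features) + 1] <- -sep
    matrix(rnorm(n_per_class * n_features), n_per_class) +
      matrix(centre, n_per_class, n_features, byrow = TRUE)
  }))
  colnames(x) <- paste0("f", seq_len(n_features))
  list(x = x, y = rep(classes, each = n_per_class))
}
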