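# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately brute-force and kept separate from the
# package's own code paths.

# the 8-object worked-example decision system (two continuous conditional
# attributes, binary decision)
worked_example_ds <- function() {
  decision_system(
    data.frame(a = c(0.7, 0.7, 0.7, 0.3, 0.2, 0.5, 0.4, 0.5),
               b = c(0.7, 0.3, 0.3, 0.3, 0.2, 0.5, 0.4, 0.5)),
    c(1, 0, 1, 0, 0, 1, 0, 1))
}

# naive O(N^4) 2-D DFT (and inverse), summed term by term
naive_dft2 <- function(x, inverse = FALSE) {
  n <- nrow(x); m <- ncol(x)
  s <- if (inverse) 1 else -1
  out <- matrix(0 + 0i, n, m)
  for (u in 0:(n - 1)) {
    for (v in 0:(m - 1)) {
      acc <- 0 + 0i
      for (p in 0:(n - 1)) {
        for (q in 0:(m - 1)) {
          acc <- acc + x[p + 1, q + 1] *
            exp(s * 2i * pi * (u * p / n + v * q / m))
        }
      }
      out[u + 1, v + 1] <- acc
    }
  }
  if (inverse) out / (n * m) else out
}

# quadrant swaps matching a centered spectrum layout
oracle_fftshift <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c(seq(floor(h / 2) + 1, h), seq_len(floor(h / 2))),
    c(seq(floor(w / 2) + 1, w), seq_len(floor(w / 2)))]
}
oracle_ifftshift <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c(seq(ceiling(h / 2) + 1, h), seq_len(ceiling(h / 2))),
    c(seq(ceiling(w / 2) + 1, w), seq_len(ceiling(w / 2)))]
}

# brute-force homomorphic / anti-homomorphic pipelines on the naive DFT
oracle_homomorphic <- function(img, H, eps = 1e-6) {
  z <- log(img + eps)
  S <- H * oracle_fftshift(naive_dft2(z))
  o <- exp(Re(naive_dft2(oracle_ifftshift(S), inverse = TRUE))) - eps
  (o - min(o)) / (max(o) - min(o))
}
oracle_anti_homomorphic <- function(img, H, eps = 1e-6) {
  e <- exp(img)
  S <- (1 / H) * oracle_fftshift(naive_dft2(e))
  o <- log(pmax(Re(naive_dft2(oracle_ifftshift(S), inverse = TRUE)), eps))
  (o - min(o)) / (max(o) - min(o))
}

# direct dense 2-D convolution with replicate padding (independent of the
# package's separable implementation)
oracle_conv2 <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  hh <- (kh - 1) %/% 2; hw <- (kw - 1) %/% 2
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      acc <- 0
      for (a in seq_len(kh)) {
        for (b in seq_len(kw)) {
          ii <- min(max(i + a - 1 - hh, 1), n)
          jj <- min(max(j + b - 1 - hw, 1), m)
          acc <- acc + kernel[a, b] * img[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# brute-force disk rasterizer (pixel-center inclusion test)
oracle_disk_pixels <- function(height, width, cr, cc, radius) {
  count <- 0L
  for (i in seq_len(height)) {
    for (j in seq_len(width)) {
      if ((i - cr)^2 + (j - cc)^2 <= radius^2) count <- count + 1L
    }
  }
  count
}

# independent positive region / gamma from first principles (nested loops,
# no partition machinery shared with the package)
oracle_gamma <- function(df, dec, B) {
  n <- nrow(df)
  pos <- 0L
  for (i in seq_len(n)) {
    block <- which(vapply(seq_len(n), function(j) {
      all(df[j, B, drop = FALSE] == df[i, B, drop = FALSE])
    }, TRUE))
    if (length(unique(dec[block])) == 1L) pos <- pos + 1L
  }
  pos / n
}

oracle_pos_count <- function(df, dec, B) {
  round(oracle_gamma(df, dec, B) * nrow(df))
}

oracle_n_blocks <- function(df, B) {
  if (length(B) == 0) return(1L)
  keys <- apply(df[, B, drop = FALSE], 1, paste, collapse = "|")
  length(unique(keys))
}

# brute-force neighborhood of object i (1-based index) on raw columns
oracle_neighborhood <- function(df, i, B, delta) {
  d <- vapply(seq_len(nrow(df)), function(j) {
    sqrt(sum((as.numeric(df[j, B]) - as.numeric(df[i, B]))^2))
  }, numeric(1))
  which(d <= delta + 1e-12)
}

# brute-force neighborhood conditional entropy (base 2)
oracle_cie <- function(df, dec, B, delta) {
  n <- nrow(df)
  total <- 0
  for (i in seq_len(n)) {
    nb <- oracle_neighborhood(df, i, B, delta)
    ratio <- sum(dec[nb] == dec[i]) / length(nb)
    total <- total + log2(ratio)
  }
  -total / n
}

# random small decision tables: discrete attribute values, decision either
# random or a consistent function of the attributes
random_table <- function(seed, n_obj = 8, n_attr = 4, n_vals = 3,
                         consistent = TRUE) {
  set.seed(seed)
  df <- as.data.frame(matrix(sample.int(n_vals, n_obj * n_attr, TRUE),
                             n_obj, n_attr))
  names(df) <- paste0("c", seq_len(n_attr))
  dec <- if (consistent) {
    keysrc <- df[, sample.int(n_attr, min(2L, n_attr)), drop = FALSE]
    keys <- apply(keysrc, 1, paste, collapse = "|")
    as.integer(factor(keys)) %% 2L
  } else {
    sample(0:1, n_obj, TRUE)
  }
  decision_system(df, dec)
}

# tiny flat lesion phantom for filter energy checks
toy_lesion_image <- function(n = 32) {
  img <- matrix(0.3, n, n)
  a <- round(n / 3); b <- round(2 * n / 3)
  img[a:(a + 2), a:(a + 2)] <- 0.8
  img[b:(b + 1), (b - 1):b] <- 0.8
  img
}

# well-conditioned random SPD system (finite termination of conjugate
# gradients is an exact-arithmetic property; moderate conditioning keeps
# it observable in doubles)
random_spd_system <- function(seed, n_max = 20) {
  set.seed(seed)
  n <- sample(5:n_max, 1)
  M <- matrix(rnorm(n * n), n)
  list(A = crossprod(M) / n + diag(n), b = rnorm(n), n = n)
}
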