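# Fixed random filter-bank observation encoder.
#
# A seeded bank of zero-mean random local filters applied at two image scales;
# each filter's rectified response is average-pooled over the frame, yielding
# a translation-invariant multi-band "texture energy" embedding (plus the
# frame's mean and standard deviation). Defocus blur attenuates each band in a
# sigma-dependent way, so the embedding carries the blur level of a frame in a
# form that transfers across textures — unlike raw-pixel coordinates, which an
# unconstrained dense network tends to memorize per stack. The bank is fixed
# (never trained); the Q-network's fully connected layers are trained on top,
# in the spirit of random-feature methods. See the methods vignette.

.make_encoder <- function(seed = 777L,
                          scales = list(c(down = 1L, size = 5L, n = 64L),
                                        c(down = 2L, size = 5L, n = 64L),
                                        c(down = 4L, size = 5L, n = 48L))) {
  filters <- with_seed(seed, lapply(scales, function(sc) {
    W <- matrix(stats::rnorm(sc[["n"]] * sc[["size"]]^2), sc[["n"]])
    W <- W - rowMeans(W)              # zero-mean: insensitive to brightness
    W / sqrt(rowSums(W^2))            # unit-norm rows
  }))
  dim_out <- 3L * sum(vapply(scales, `[[`, numeric(1), "n")) + 3L
  list(seed = as.integer(seed), scales = scales, filters = filters,
       dim = as.integer(dim_out))
}

# 2x2 block average downsampling (odd trailing row/col dropped)
.downsample2 <- function(img) {
  h <- nrow(img) %/% 2L; w <- ncol(img) %/% 2L
  i1 <- seq_len(h) * 2L; j1 <- seq_len(w) * 2L
  (img[i1 - 1L, j1 - 1L] + img[i1, j1 - 1L] + img[i1 - 1L, j1] + img[i1, j1]) / 4
}

# valid-region im2col: s^2 x n_positions matrix of sliding patches
.im2col <- function(img, s) {
  h <- nrow(img); w <- ncol(img)
  oh <- h - s + 1L; ow <- w - s + 1L
  out <- matrix(0, s * s, oh * ow)
  k <- 0L
  for (dj in 0:(s - 1L)) for (di in 0:(s - 1L)) {
    k <- k + 1L
    out[k, ] <- img[di + seq_len(oh), dj + seq_len(ow)]
  }
  out
}

# encode one frame -> feature vector of length enc$dim
#
# Each band contributes its rectified mean response and the log response:
# texture content scales bands multiplicatively while defocus attenuates them
# as a function of sigma, so in log space the blur signature is (approximately)
# an additive pattern of band ratios that transfers across textures.
.encode_frame <- function(img, enc) {
  feats <- numeric(0)
  cur <- img
  for (si in seq_along(enc$scales)) {
    sc <- enc$scales[[si]]
    if (si > 1L) cur <- .downsample2(cur)
    if (min(dim(cur)) < sc[["size"]]) {      # frame too small for this scale
      feats <- c(feats, numeric(3L * sc[["n"]]))
      next
    }
    P <- .im2col(cur, sc[["size"]])
    R <- enc$filters[[si]] %*% P
    m <- rowMeans(abs(R))
    # raw band energy, log band energy (texture scaling becomes additive,
    # band ratios — the transferable blur signature — become differences)
    # and the scale-free spectral shape (fractions within the scale)
    feats <- c(feats, m, 0.1 * log(m + 1e-8), m / (sum(m) + 1e-8))
  }
  s <- stats::sd(img)
  c(feats, mean(img), s, 0.1 * log(s + 1e-8))
}
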