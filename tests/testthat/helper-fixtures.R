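# Shared fixture builders. Everything is generated in code at test time.

# A volume whose slices are constant stored values; slope 1, intercept 0,
# so stored values are HU directly.
constant_volume <- function(values, pid = "CONST", size = 12L) {
  ct_volume(pid, lapply(values, function(v) matrix(v, size, size)),
            rescale_slope = 1, rescale_intercept = 0,
            slice_positions = seq_along(values))
}

# A display window that maps HU x to display value x exactly on [0, 255].
identity_window <- function() window_spec(level = 127.5, width = 255)

# A reproducible random volume in stored values around soft tissue.
noise_volume <- function(n = 4L, size = 20L, pid = "RND", seed = 99L) {
  set.seed(seed)
  ct_volume(pid,
            lapply(seq_len(n), function(i)
              matrix(round(stats::runif(size * size, 900, 1200)), size, size)),
            rescale_slope = 1, rescale_intercept = -1024,
            slice_positions = seq_len(n) * 3)
}

# Independent byte-level ImageJ ROI writer used as an oracle for the
# package's parser: big-endian header written field by field from the
# published format description (magic "Iout", version short, type byte at
# offset 6, top/left/bottom/right shorts at offsets 8..15).
oracle_roi_bytes <- function(top, left, bottom, right, type = 1L) {
  be <- function(x) as.raw(c(x %/% 256, x %% 256))
  r <- raw(64)
  r[1:4] <- charToRaw("Iout")
  r[5:6] <- be(227L)
  r[7] <- as.raw(type)
  r[9:10] <- be(top); r[11:12] <- be(left)
  r[13:14] <- be(bottom); r[15:16] <- be(right)
  r
}

# Brute-force AUC by pair counting: the independent oracle for the
# rank-based implementation.
auc_brute_force <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# A tiny separable image set for training sanity checks: class 1 images are
# brighter in the centre. Resolution kept at the minimum the CNN accepts.
tiny_separable_set <- function(n_per_class = 20L, res = 18L, seed = 1L,
                               shift = 0.35) {
  set.seed(seed)
  d <- res * res * 3
  mask <- rep(0, d)
  centre <- as.vector(outer(seq_len(res), seq_len(res), function(i, j)
    (i - res / 2)^2 + (j - res / 2)^2 < (res / 4)^2))
  mask[rep(centre, 3)] <- 1
  n <- 2L * n_per_class
  x <- matrix(stats::runif(d * n, 0.2, 0.8), d, n)
  y <- rep(c(0, 1), each = n_per_class)
  x[, y == 1] <- pmin(x[, y == 1] + shift * mask, 1)
  list(x = x, y = y)
}

# Random manifest generator for fold-integrity properties.
random_manifest <- function(seed, k = 3L) {
  set.seed(seed)
  n_pat <- sample(k:(k + 6L), 2)           # patients per class
  rows <- list()
  pid <- 0L
  for (cls in c("a", "b")) {
    for (i in seq_len(n_pat[match(cls, c("a", "b"))])) {
      pid <- pid + 1L
      n_img <- sample(1:8, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("p%02d_i%02d", pid, seq_len(n_img)),
        patient_id = sprintf("p%02d", pid),
        label = cls, fold = NA_integer_,
        fake = stats::runif(n_img) < 0.15,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
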