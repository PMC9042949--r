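# Shared fixtures: all built in code, nothing read from disk.

# a small, fast ground truth for generator/pipeline tests
tiny_truth <- function(...) {
  args <- list(n_raters = 12L, rater_noise_sd = 0.8)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(ground_truth, args)
}

# apply a random similarity transform (rotation + positive scale +
# translation, no reflection) to a k x 2 configuration
similarity_transform <- function(points, theta, scale, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  scale * (points %*% R) + matrix(shift, nrow(points), 2, byrow = TRUE)
}

# a deliberately asymmetric 4-landmark shape (unit square with one corner
# pulled out) used by the alignment oracles
displaced_square <- function(delta = 0.3) {
  ref <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  tgt <- ref
  tgt[3, ] <- tgt[3, ] + c(delta, delta / 2)
  list(ref = ref, tgt = tgt)
}

# brute-force rotation-grid oracle for the pairwise alignment distance:
# both shapes centred and scaled to unit centroid size, then the minimum
# distance over a fine grid of rotation angles
grid_opa_distance <- function(ref, tgt, step = 1e-5) {
  centre <- function(X) sweep(X, 2, colMeans(X))
  A <- centre(ref); A <- A / sqrt(sum(A^2))
  B <- centre(tgt); B <- B / sqrt(sum(B^2))
  # ||A - B R(theta)||^2 = 2 - 2 * (c1 cos + c2 sin) for unit-size shapes
  c1 <- sum(A * B)
  c2 <- sum(A[, 1] * B[, 2]) - sum(A[, 2] * B[, 1])
  theta <- seq(0, 2 * pi, by = step)
  d2 <- sum(A^2) + sum(B^2) - 2 * (c1 * cos(theta) + c2 * sin(theta))
  sqrt(min(d2))
}
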