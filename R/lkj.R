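## LKJ correlation-matrix prior via the C-vine construction
## (Lewandowski, Kurowicka & Joe 2009).  A d x d correlation matrix is
## parameterised by its d(d-1)/2 canonical partial correlations (CPCs),
## stored row-wise for the lower triangle: (2,1), (3,1), (3,2), (4,1), ...
## Under LKJ(eta), the CPC in column j is independently distributed as
## 2 * Beta(b_j, b_j) - 1 with b_j = eta + (d - 1 - j) / 2, which is what
## makes both prior sampling and slice updates on atanh(CPC) coordinates
## straightforward.

cpc_pairs <- function(d) {
  idx <- which(lower.tri(matrix(0, d, d)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

## lower-triangular Cholesky factor of the correlation matrix implied by a
## CPC vector (row-wise order as above); row i is c_j * prod_{l<j} sqrt(1 - c_l^2)
cpc_to_chol <- function(cpc, d) {
  L <- matrix(0, d, d)
  L[1, 1] <- 1
  pos <- 0L
  for (i in 2:d) {
    ci <- cpc[pos + seq_len(i - 1L)]
    s <- sqrt(cumprod(c(1, 1 - ci^2)))
    L[i, seq_len(i - 1L)] <- ci * s[seq_len(i - 1L)]
    L[i, i] <- s[i]
    pos <- pos + i - 1L
  }
  L
}

cpc_to_corr <- function(cpc, d) {
  L <- cpc_to_chol(cpc, d)
  R <- tcrossprod(L)
  # enforce exact unit diagonal against rounding
  diag(R) <- 1
  R
}

## recover the CPC vector from a correlation matrix (inverse transform)
corr_to_cpc <- function(R) {
  d <- nrow(R)
  L <- t(chol(R))
  cpc <- numeric(d * (d - 1) / 2)
  pos <- 1L
  for (i in 2:d) {
    ssq <- 0
    for (j in 1:(i - 1)) {
      cpc[pos] <- L[i, j] / sqrt(1 - ssq)
      ssq <- ssq + L[i, j]^2
      pos <- pos + 1L
    }
  }
  cpc
}

## Beta shape for the CPC in column j of a d-dimensional matrix
lkj_cpc_shape <- function(d, eta) {
  pairs <- cpc_pairs(d)
  eta + (d - 1 - pairs[, 2]) / 2
}

## log prior of atanh-CPC coordinates z implying R ~ LKJ(eta); includes
## the tanh Jacobian so this is a proper density over z (up to the Beta
## normalising constants, which are included too)
lkj_z_log_prior <- function(z, d, eta) {
  b <- lkj_cpc_shape(d, eta)
  c2 <- tanh(z)^2
  # Beta(b, b) density of (c+1)/2 on (-1,1) plus dc/dz = 1 - c^2
  sum((b - 1) * log1p(-c2) - (2 * b - 1) * log(2) - lbeta(b, b) + log1p(-c2))
}

## normalising constant of the LKJ density f(R) = det(R)^(eta-1) / c_d(eta)
lkj_log_norm <- function(d, eta) {
  k <- seq_len(d - 1)
  b <- eta + (d - 1 - k) / 2
  sum((d - k) * ((2 * b - 1) * log(2) + lbeta(b, b)))
}

#' Log density of the LKJ correlation-matrix distribution
#'
#' `f(R) = det(R)^(eta - 1) / c_d(eta)` with respect to Lebesgue measure
#' on the free (lower-triangle) elements of `R`.  `eta = 2` mildly favours
#' correlations near zero.
#'
#' @param R correlation matrix (symmetric, unit diagonal).
#' @param eta positive shape parameter.
#' @return Log density; `-Inf` (with attribute `"reason"`) if `R` is not
#'   positive definite.
#' @export
lkj_log_density <- function(R, eta) {
  d <- nrow(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    return(structure(-Inf, reason = "correlation matrix not positive definite"))
  }
  (eta - 1) * sum(log(ev)) - lkj_log_norm(d, eta)
}

## draw a CPC vector from the LKJ(eta) prior
lkj_sample_cpc <- function(d, eta) {
  b <- lkj_cpc_shape(d, eta)
  2 * stats::rbeta(length(b), b, b) - 1
}
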