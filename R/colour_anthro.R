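#' Body mass index
#'
#' Weight in kilograms divided by the square of height in metres.
#'
#' @param weight_kg,height_m positive numerics (vectorised).
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0)) {
    stop("weight and height must be positive")
  }
  weight_kg / height_m^2
}

#' Facial width-to-height ratio
#'
#' Bizygomatic width scaled by upper-lip-to-glabella height; both in the
#' same (arbitrary) units.
#'
#' @param width,height positive numerics (vectorised).
#' @return fWHR, dimensionless.
#' @export
fwhr <- function(width, height) {
  if (any(width <= 0) || any(height <= 0)) {
    stop("width and height must be positive")
  }
  width / height
}

#' Repeated-measurement quality gate
#'
#' Two repeated measurements of the same facial feature are accepted only
#' if they correlate above `threshold` (Pearson); accepted pairs are
#' averaged element-wise, otherwise an error carrying the observed r is
#' raised.
#'
#' @param measure_1,measure_2 numeric vectors, same length >= 3.
#' @param threshold acceptance threshold on Pearson r (default 0.9).
#' @return Element-wise mean, with attribute `"r"`.
#' @export
repeatability_gate <- function(measure_1, measure_2, threshold = 0.9) {
  if (length(measure_1) != length(measure_2) || length(measure_1) < 3L) {
    stop("need two equal-length vectors of length >= 3")
  }
  if (stats::sd(measure_1) <= .Machine$double.eps ||
      stats::sd(measure_2) <= .Machine$double.eps) {
    stop("zero variance in a measurement vector; correlation undefined")
  }
  r <- stats::cor(measure_1, measure_2)
  if (r <= threshold) {
    stop(sprintf(
      "repeatability failure: measurements correlate at r = %.4f <= %.2f",
      r, threshold))
  }
  structure((measure_1 + measure_2) / 2, r = r)
}

#' Two-way average-score consistency ICC(3,k)
#'
#' Interrater reliability of stimulus means from a complete raters x
#' stimuli layout: `ICC(3,k) = (MS_between_stimuli - MS_error) /
#' MS_between_stimuli`, with mean squares from the two-way (stimuli x
#' raters) ANOVA decomposition.  Stimuli with any missing rating are
#' dropped listwise.
#'
#' @param matrix_ a [rating_matrix()] (raters in rows) or plain matrix.
#' @return Scalar in (-Inf, 1]; 1 iff rater columns are identical up to
#'   rater main effects.
#' @export
icc_3k <- function(matrix_) {
  m <- t(as.matrix(matrix_))           # stimuli x raters
  m <- m[stats::complete.cases(m), , drop = FALSE]
  ns <- nrow(m); nr <- ncol(m)
  if (ns < 2L || nr < 2L) stop("ICC needs >= 2 stimuli and >= 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- nr * sum((row_m - grand)^2)          # between stimuli
  ss_cols <- ns * sum((col_m - grand)^2)          # between raters
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (ns - 1)
  ms_err <- ss_err / ((ns - 1) * (nr - 1))
  (ms_rows - ms_err) / ms_rows
}

#' Per-stimulus mean ratings
#'
#' Arithmetic mean over non-missing raters for each stimulus.
#'
#' @param matrix_ a [rating_matrix()] or plain raters x stimuli matrix.
#' @return Named numeric vector of stimulus means (1--7 scale).
#' @export
mean_ratings <- function(matrix_) {
  m <- as.matrix(matrix_)
  n_ok <- colSums(!is.na(m))
  if (any(n_ok == 0L)) {
    stop("stimulus with zero ratings: ",
         paste(colnames(m)[n_ok == 0L], collapse = ", "))
  }
  colMeans(m, na.rm = TRUE)
}

#' Horn's parallel analysis
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' mean eigenvalues of `n_random` same-shaped matrices of independent
#' standard normals; the retained factor count is the number of observed
#' eigenvalues exceeding their random counterpart.  The mean (rather than
#' a high percentile) of the random eigenvalues is used by default,
#' matching common toolkit behaviour; set `quantile` to e.g. 0.95 to
#' switch.
#'
#' @param X numeric n x p matrix of observed variables (n >= 10).
#' @param n_random number of random reference datasets.
#' @param seed integer RNG seed.
#' @param quantile `NULL` for the mean criterion, else a probability.
#' @return Integer retained factor count, with attribute
#'   `"eigenvalues"` (observed) and `"reference"` (random criterion).
#' @export
parallel_analysis <- function(X, n_random = 100L, seed = 1L, quantile = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 10L) stop("parallel analysis needs n >= 10")
  if (any(apply(X, 2, stats::sd) <= .Machine$double.eps)) {
    stop("constant column in channel matrix")
  }
  obs <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  rand <- withr_seed(seed, {
    vapply(seq_len(n_random), function(r) {
      eigen(stats::cor(matrix(stats::rnorm(n * p), n, p)),
            symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p))
  })
  ref <- if (is.null(quantile)) rowMeans(rand)
         else apply(rand, 1, stats::quantile, probs = quantile)
  retained <- 0L
  for (j in seq_len(p)) {
    if (obs[j] > ref[j]) retained <- retained + 1L else break
  }
  structure(retained, eigenvalues = obs, reference = ref)
}

## evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Single-factor extraction for collinear colour channels
#'
#' Fits a one-factor model to the standardized CIELab channels by iterated
#' principal-axis factoring, scores specimens by the regression (Thurstone)
#' method, and reports per-channel R-squared (squared correlation between
#' the factor score and the channel).  The factor sign is oriented so that
#' the loading on the first channel (L*, lightness) is positive.  With
#' three variables and one factor the model is just-identified, so the
#' extraction method barely matters.
#'
#' @param X numeric n x 3 matrix (columns L*, a*, b*).
#' @param max_iter,tol iteration control for the communality loop.
#' @return List with `loadings` (3-vector), `scores` (n-vector, mean 0,
#'   variance <= 1), `r2` (3-vector) and `communalities`.
#' @export
extract_colour_factor <- function(X, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (any(apply(X, 2, stats::sd) <= .Machine$double.eps)) {
    stop("constant column in channel matrix")
  }
  R <- stats::cor(X)
  # start from squared multiple correlations; ridge guards the exactly
  # singular (rank-one) limit
  rsolve <- function(A, b) {
    tryCatch(solve(A, b), error = function(e) solve(A + diag(1e-8, p), b))
  }
  Ri <- rsolve(R, diag(p))
  h2 <- pmin(1 - 1 / diag(Ri), 0.995)
  heywood <- FALSE
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lambda <- sqrt(max(e$values[1], 0)) * e$vectors[, 1]
    h2_new <- pmin(lambda^2, 0.995)
    if (any(lambda^2 >= 1)) {
      heywood <- TRUE
      lambda <- sign(lambda) * sqrt(h2_new)
    }
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  if (heywood) warning("Heywood case: communality clipped at 0.995")
  if (lambda[1] < 0) lambda <- -lambda
  Z <- scale(X)
  w <- rsolve(R, lambda)                # Thurstone regression weights
  scores <- drop(Z %*% w)
  r2 <- drop(stats::cor(scores, Z))^2
  list(loadings = lambda, scores = scores, r2 = r2, communalities = h2)
}

#' Decide how colour enters the path model
#'
#' The single-factor "colour" variable is used only when Horn's parallel
#' analysis retains exactly one factor AND the channels are highly
#' collinear (max pairwise |r| above `collinearity`); otherwise the three
#' CIELab channels enter the mediator layer separately.  This reproduces
#' the empirical asymmetry between heavily correlated and weakly
#' correlated channel regimes by rule rather than by fiat.
#'
#' @param X n x 3 channel matrix.
#' @param collinearity pairwise |r| threshold (default 0.8).
#' @param seed RNG seed for the parallel analysis.
#' @return `"factor"` or `"channels"`, with attribute `"retained"`.
#' @export
choose_colour_mode <- function(X, collinearity = 0.8, seed = 1L) {
  pa <- parallel_analysis(X, seed = seed)
  R <- stats::cor(X)
  maxr <- max(abs(R[upper.tri(R)]))
  mode <- if (as.integer(pa) == 1L && maxr > collinearity) "factor" else "channels"
  structure(mode, retained = as.integer(pa), max_abs_r = maxr)
}
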