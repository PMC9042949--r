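## Joint log posterior density of the path model at a constrained
## parameter point.  The sampler itself uses blocked conditionals, so this
## function exists as the single authoritative statement of the target
## (and for direct checks against closed forms).

## assemble data matrices for a manifest from a standardized data frame
path_model_matrices <- function(manifest, data) {
  med <- manifest$mediators; out <- manifest$outcomes
  need <- c("age", "bmi", med, out)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0L) {
    stop("data is missing model variable(s): ", paste(missing, collapse = ", "))
  }
  n0 <- nrow(data)
  keep <- stats::complete.cases(data[, need, drop = FALSE])
  dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  ones <- rep(1, n)
  list(
    n = n, dropped = dropped,
    age = as.numeric(data$age), bmi = as.numeric(data$bmi),
    X_bmi = cbind(ones, age = as.numeric(data$age)),
    X_med = cbind(ones, age = as.numeric(data$age), bmi = as.numeric(data$bmi)),
    M = as.matrix(data[, med, drop = FALSE]),
    X_out = cbind(ones, as.matrix(data[, c("age", "bmi", med), drop = FALSE])),
    Y = as.matrix(data[, out, drop = FALSE]))
}

## multivariate normal log likelihood of residual matrix E with covariance
## Sigma (rows independent)
mvn_resid_loglik <- function(E, Sigma) {
  n <- nrow(E); d <- ncol(Sigma)
  if (n == 0L) return(0)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  S <- crossprod(E)
  -0.5 * n * d * log(2 * pi) - n * sum(log(diag(ch))) -
    0.5 * sum(chol2inv(ch) * S)
}

#' Joint log posterior density of a path model
#'
#' Log prior plus log likelihood at one constrained parameter point:
#' normal priors on intercepts and slopes, Exponential priors on residual
#' SDs, LKJ priors on both residual correlation matrices; likelihood summed
#' over specimens from the BMI univariate-normal term, the mediator
#' multivariate-normal term and the outcome bivariate-normal term.  With a
#' zero-row dataset the likelihood is zero and the value is the joint log
#' prior.
#'
#' @param manifest a [build_model()] manifest.
#' @param point named list with elements `intercepts` (named vector),
#'   `slopes` (named vector), `sigma_bmi`, `mediator_sds`, `mediator_corr`
#'   (correlation matrix), `outcome_sds`, `outcome_corr` (scalar).
#' @param data standardized data frame (may have zero rows).
#' @return Scalar log density; `-Inf` with attribute `"reason"` for a
#'   non-positive-definite correlation input.
#' @export
log_density <- function(manifest, point, data) {
  spec <- manifest$spec
  med <- manifest$mediators; q <- length(med)
  a <- point$intercepts[manifest$intercepts]
  b <- point$slopes[manifest$slopes]
  if (any(is.na(a)) || any(is.na(b))) {
    stop("parameter point does not match the manifest's intercept/slope names")
  }
  sds <- c(point$sigma_bmi, point$mediator_sds, point$outcome_sds)
  if (any(sds <= 0)) return(structure(-Inf, reason = "non-positive sd"))
  Rm <- point$mediator_corr
  if (!isTRUE(all.equal(dim(Rm), c(q, q)))) stop("mediator_corr has wrong size")
  Ro <- matrix(c(1, point$outcome_corr, point$outcome_corr, 1), 2, 2)
  lp_m <- lkj_log_density(Rm, spec$lkj_eta)
  lp_o <- lkj_log_density(Ro, spec$lkj_eta)
  if (!is.finite(lp_m) || !is.finite(lp_o)) {
    return(structure(-Inf, reason = "correlation matrix not positive definite"))
  }
  lp <- sum(stats::dnorm(a, 0, spec$prior_intercept_sd, log = TRUE)) +
    sum(stats::dnorm(b, 0, spec$prior_slope_sd, log = TRUE)) +
    sum(stats::dexp(sds, spec$sd_rate, log = TRUE)) + lp_m + lp_o

  dm <- path_model_matrices(manifest, data)
  if (dm$n == 0L) return(lp)

  # BMI equation
  mu_b <- a["a_bmi"] + b["b_age_bmi"] * dm$age
  ll <- sum(stats::dnorm(dm$bmi, mu_b, point$sigma_bmi, log = TRUE))
  # mediator block
  Bm <- rbind(a[paste0("a_", med)],
              b[paste0("b_age_", med)],
              b[paste0("b_bmi_", med)])
  Em <- dm$M - dm$X_med %*% Bm
  Sm <- diag(point$mediator_sds, q) %*% Rm %*% diag(point$mediator_sds, q)
  ll <- ll + mvn_resid_loglik(Em, Sm)
  # outcome block
  out <- manifest$outcomes
  Bo <- rbind(a[paste0("a_", out)],
              b[paste0("b_age_", out)],
              b[paste0("b_bmi_", out)],
              matrix(b[as.vector(t(outer(med, out, function(m, o)
                paste0("b_", m, "_", o))))], q, 2, byrow = TRUE))
  Eo <- dm$Y - dm$X_out %*% Bo
  So <- diag(point$outcome_sds, 2) %*% Ro %*% diag(point$outcome_sds, 2)
  ll <- ll + mvn_resid_loglik(Eo, So)
  lp + ll
}
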