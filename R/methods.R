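#' @export
print.facepath_fit <- function(x, ...) {
  cat("Bayesian path model fit (", x$manifest$variant, " variant, ",
      x$manifest$colour_mode, " colour mode)\n", sep = "")
  cat("  n =", x$n, "specimens")
  if (x$n_dropped > 0) cat(" (", x$n_dropped, " dropped)", sep = "")
  cat("; ", nrow(x$draws), " posterior draws over ", x$chains,
      " chain(s)\n", sep = "")
  cat("  convergence:", if (x$converged) "all split-Rhat <= 1.01, ESS >= 400"
      else sprintf("NOT converged (max Rhat %.3f, min ESS %.0f)",
                   max(x$diagnostics$rhat, na.rm = TRUE),
                   min(x$diagnostics$ess, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Posterior summary of a path model fit
#'
#' Per-parameter posterior mean and central 95% compatibility interval
#' (equal-tailed 2.5%/97.5% quantiles), plus convergence diagnostics.
#' The residual dependence between the two perceived outcomes is reported
#' as the correlation parameter (the variables are standardized).
#'
#' @param object a `facepath_fit`.
#' @param pars optional character vector restricting the parameters.
#' @param prob interval mass (default 0.95).
#' @param ... unused.
#' @return data.frame with columns `parameter, mean, sd, lower, upper,
#'   rhat, ess`, class `summary.facepath_fit`.
#' @export
summary.facepath_fit <- function(object, pars = NULL, prob = 0.95, ...) {
  draws <- object$draws
  if (!is.null(pars)) {
    missing <- setdiff(pars, colnames(draws))
    if (length(missing) > 0) stop("unknown parameter(s): ",
                                  paste(missing, collapse = ", "))
    draws <- draws[, pars, drop = FALSE]
  }
  out <- summarize_draws(draws, prob = prob)
  dg <- object$diagnostics
  out$rhat <- dg$rhat[match(out$parameter, dg$parameter)]
  out$ess <- dg$ess[match(out$parameter, dg$parameter)]
  class(out) <- c("summary.facepath_fit", "data.frame")
  out
}

#' Summarize a posterior draws matrix
#'
#' @param draws numeric matrix, draws x parameters (named columns).
#' @param prob central interval mass.
#' @return data.frame `parameter, mean, sd, lower, upper`.
#' @export
summarize_draws <- function(draws, prob = 0.95) {
  draws <- as.matrix(draws)
  if (nrow(draws) == 0L) stop("no draws to summarize")
  alpha <- (1 - prob) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  data.frame(parameter = colnames(draws),
             mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             lower = qs[1, ], upper = qs[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.summary.facepath_fit <- function(x, digits = 2, ...) {
  cat("Posterior summary (mean and 95% compatibility interval):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s %s\n", x$parameter[i],
                format_ci(x$mean[i], x$lower[i], x$upper[i], digits)))
  }
  invisible(x)
}

## "0.42 (CI: 0.16, 0.64)" reporting style
format_ci <- function(mean, lower, upper, digits = 2) {
  sprintf("%.*f (CI: %.*f, %.*f)", digits, mean, digits, lower, digits, upper)
}

#' @export
coef.facepath_fit <- function(object, ...) {
  colMeans(object$draws)
}

#' @export
as.data.frame.facepath_fit <- function(x, ...) {
  as.data.frame(x$draws)
}

## posterior-mean coefficient matrix for the outcome equations
outcome_coef_matrix <- function(object) {
  m <- object$manifest
  cm <- coef(object)
  med <- m$mediators
  rbind(cm[paste0("a_", m$outcomes)],
        cm[paste0("b_age_", m$outcomes)],
        cm[paste0("b_bmi_", m$outcomes)],
        matrix(cm[as.vector(t(outer(med, m$outcomes, function(x, o)
          paste0("b_", x, "_", o))))], length(med), 2, byrow = TRUE))
}

#' Posterior-mean predictions for the perceived outcomes
#'
#' Linear predictor of the two outcome equations at the posterior-mean
#' coefficients, on the standardized scale of the fitted data.
#'
#' @param object a `facepath_fit`.
#' @param newdata optional data frame with `age`, `bmi` and the fit's
#'   mediators (standardized scales); defaults to the fitted data.
#' @param ... unused.
#' @return n x 2 matrix with columns `sextypicality`, `dominance`.
#' @export
predict.facepath_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  if (is.null(newdata) || nrow(newdata) == 0L) {
    stop("no data to predict from (prior-only fit and no `newdata`)")
  }
  med <- object$manifest$mediators
  X <- cbind(1, as.matrix(newdata[, c("age", "bmi", med), drop = FALSE]))
  out <- X %*% outcome_coef_matrix(object)
  colnames(out) <- object$manifest$outcomes
  out
}

#' @export
residuals.facepath_fit <- function(object, ...) {
  if (is.null(object$data) || nrow(object$data) == 0L) {
    stop("prior-only fit has no residuals")
  }
  Y <- as.matrix(object$data[, object$manifest$outcomes, drop = FALSE])
  Y - predict(object)
}

#' Posterior-predictive outcome simulation
#'
#' Draws outcome pairs from the fitted model's posterior predictive:
#' each simulation picks one retained posterior draw and samples the
#' bivariate outcome residual around the corresponding linear predictor.
#'
#' @param object a `facepath_fit`.
#' @param nsim number of simulated datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return List of `nsim` n x 2 outcome matrices.
#' @export
simulate.facepath_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(object$data) || nrow(object$data) == 0L) {
    stop("prior-only fit has no design to simulate over")
  }
  m <- object$manifest
  med <- m$mediators
  X <- cbind(1, as.matrix(object$data[, c("age", "bmi", med),
                                      drop = FALSE]))
  n <- nrow(X)
  idx <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  lapply(idx, function(i) {
    d <- object$draws[i, ]
    B <- rbind(d[paste0("a_", m$outcomes)],
               d[paste0("b_age_", m$outcomes)],
               d[paste0("b_bmi_", m$outcomes)],
               matrix(d[as.vector(t(outer(med, m$outcomes, function(x, o)
                 paste0("b_", x, "_", o))))], length(med), 2, byrow = TRUE))
    mu <- X %*% B
    r <- d[m$outcome_corr]; sds <- d[m$outcome_sds]
    S <- diag(sds) %*% matrix(c(1, r, r, 1), 2, 2) %*% diag(sds)
    E <- matrix(stats::rnorm(2 * n), n, 2) %*% chol(S)
    out <- mu + E
    colnames(out) <- m$outcomes
    out
  })
}

#' Marginal posterior density panels with interval bars
#'
#' Draws, for each selected parameter, the marginal posterior density with
#' the posterior mean and the 95% compatibility interval marked by a
#' horizontal bar, in the style of slope/covariance forest-density panels.
#'
#' @param x a `facepath_fit`.
#' @param pars parameters to plot; defaults to all slopes plus the outcome
#'   residual correlation.
#' @param mfrow panel layout; `NULL` chooses automatically.
#' @param ... passed to [graphics::plot()].
#' @export
plot.facepath_fit <- function(x, pars = NULL, mfrow = NULL, ...) {
  if (is.null(pars)) pars <- c(x$manifest$slopes, x$manifest$outcome_corr)
  pars <- intersect(pars, colnames(x$draws))
  np <- length(pars)
  if (np == 0L) stop("no matching parameters to plot")
  if (is.null(mfrow)) {
    nc <- ceiling(sqrt(np)); mfrow <- c(ceiling(np / nc), nc)
  }
  op <- graphics::par(mfrow = mfrow, mar = c(2.5, 2, 2, 0.5))
  on.exit(graphics::par(op))
  for (p in pars) {
    v <- x$draws[, p]
    if (stats::sd(v) <= .Machine$double.eps) {
      # degenerate spike: zero-width bar at the constant value
      graphics::plot(c(v[1], v[1]), c(0, 1), type = "l", main = p,
                     xlab = "", ylab = "", ...)
      graphics::points(v[1], 0, pch = 16)
    } else {
      d <- stats::density(v)
      graphics::plot(d, main = p, xlab = "", ylab = "", ...)
      ci <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
      graphics::segments(ci[1], 0, ci[2], 0, lwd = 3)
      graphics::points(mean(v), 0, pch = 16)
    }
    graphics::abline(v = 0, lty = 3, col = "grey50")
  }
  invisible(x)
}

#' Write density/forest figure files for a fit
#'
#' One multi-panel figure per parameter category (intercepts, slopes,
#' scales, correlations), written as PDF files; the file set maps
#' one-to-one onto the parameter manifest.  Parameters requested but
#' absent from the model are skipped with a log entry.
#'
#' @param fit a `facepath_fit`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the vector of files written.
#' @export
forest_and_density_plots <- function(fit, dir, prefix = "posterior") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  groups <- list(
    intercepts = fit$manifest$intercepts,
    slopes = fit$manifest$slopes,
    scales = c(fit$manifest$bmi_sd, fit$manifest$mediator_sds,
               fit$manifest$outcome_sds),
    correlations = c(fit$manifest$mediator_corrs, fit$manifest$outcome_corr))
  files <- character(0)
  for (g in names(groups)) {
    pars <- groups[[g]]
    absent <- setdiff(pars, colnames(fit$draws))
    if (length(absent) > 0) {
      message("skipping parameters absent from the model: ",
              paste(absent, collapse = ", "))
      pars <- setdiff(pars, absent)
    }
    if (length(pars) == 0) next
    f <- file.path(dir, paste0(prefix, "_", g, ".pdf"))
    grDevices::pdf(f, width = 9, height = 7)
    plot(fit, pars = pars)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}

#' Write posterior draws as a delimited table
#'
#' @param fit a `facepath_fit`.
#' @param path output file (one column per parameter).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path, sep = ",") {
  utils::write.table(as.data.frame(fit$draws), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
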