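## Posterior sampler for the layered path model: blocked Gibbs updates for
## all intercepts and slopes (exact multivariate-normal conditionals) and
## univariate slice sampling (Neal 2003, stepping out + shrinkage) on the
## log residual SDs and atanh canonical partial correlations of the two
## covariance blocks.  With standardized data and weakly regularising
## priors these blocks mix in a handful of sweeps, so no tuning is needed.

slice_sample_1d <- function(x0, logf, w = 0.5, max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at a zero-density point")
  logy <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  Rr <- L + w
  J <- floor(max_steps * stats::runif(1))
  K <- max_steps - 1L - J
  while (J > 0 && logf(L) > logy) { L <- L - w; J <- J - 1L }
  while (K > 0 && logf(Rr) > logy) { Rr <- Rr + w; K <- K - 1L }
  repeat {
    x1 <- stats::runif(1, L, Rr)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else Rr <- x1
  }
}

## conditional Gibbs draw of vec(B) for Z ~ MVN(X B, Sigma) rows, with
## independent normal priors (precision prior_prec per element of vec(B))
draw_coef_block <- function(XtX, XtZ, Sigma_inv, prior_prec) {
  p <- nrow(XtX); d <- nrow(Sigma_inv)
  P <- kronecker(Sigma_inv, XtX) + diag(prior_prec, p * d)
  rhs <- as.vector(XtZ %*% Sigma_inv)
  ch <- chol(P)
  mu <- backsolve(ch, forwardsolve(t(ch), rhs))
  matrix(mu + backsolve(ch, stats::rnorm(p * d)), p, d)
}

## One Gibbs pass over a covariance block.  The slice conditionals are
## made cheap by two block-specific reductions: while the log-SDs move,
## the correlation part is fixed, so tr(Sigma^-1 S) collapses to the
## quadratic form u' (Rinv*S) u in u = 1/sd (O(1) per evaluation); while
## the CPCs move, the scales are fixed, so with Ss = Cs'Cs the trace is
## ||L^-1 Cs'||^2 and a candidate CPC only alters one row of L.
update_cov_block <- function(lsd, z, S, n, bshape, sd_rate, w = 0.5) {
  d <- length(lsd)
  cpc <- tanh(z)
  L <- cpc_to_chol(cpc, d)
  # --- log-SD coordinates
  if (n > 0L) {
    W <- chol2inv(t(L)) * S
    ld_corr <- sum(log(diag(L)))
    u <- exp(-lsd)
    for (j in seq_len(d)) {
      a_j <- W[j, j]
      b_j <- 2 * sum(W[j, -j] * u[-j])
      lsd[j] <- slice_sample_1d(lsd[j], function(x) {
        uj <- exp(-x)
        -n * x - 0.5 * (a_j * uj^2 + b_j * uj) - sd_rate * exp(x) + x
      }, w = w)
      u[j] <- exp(-lsd[j])
    }
  } else {
    for (j in seq_len(d)) {
      lsd[j] <- slice_sample_1d(lsd[j], function(x) -sd_rate * exp(x) + x,
                                w = w)
    }
  }
  # --- CPC coordinates (row-wise lower triangle; position j sits in row i)
  pairs <- cpc_pairs(d)
  if (n > 0L) {
    sd <- exp(lsd)
    Ss <- S / tcrossprod(sd)
    Cs <- tryCatch(chol(Ss), error = function(e)
      chol(Ss + diag(1e-10 * (mean(diag(Ss)) + 1), d)))
    tCs <- t(Cs)
  }
  row_start <- c(0L, cumsum(seq_len(d - 1L)))  # cpc offset before row i
  for (j in seq_along(z)) {
    i <- pairs[j, 1]
    ri <- row_start[i - 1L] + seq_len(i - 1L)   # positions of row i's cpcs
    jj <- j - row_start[i - 1L]                 # column within the row
    ci <- cpc[ri]
    logf <- function(x) {
      cr <- ci; cr[jj] <- tanh(x)
      s <- sqrt(cumprod(c(1, 1 - cr^2)))
      if (any(!is.finite(s)) || s[i] <= 0) return(-Inf)
      lp <- bshape[j] * log1p(-tanh(x)^2)
      if (n == 0L) return(lp)
      Lmod <- L
      Lmod[i, seq_len(i - 1L)] <- cr * s[seq_len(i - 1L)]
      Lmod[i, i] <- s[i]
      A <- forwardsolve(Lmod, tCs)
      -n * (sum(lsd) + ld_corr - log(diag(L)[i]) + log(s[i])) -
        0.5 * sum(A * A) + lp
    }
    z[j] <- slice_sample_1d(z[j], logf, w = w)
    # commit the accepted row
    cpc[j] <- tanh(z[j])
    cr <- cpc[ri]
    s <- sqrt(cumprod(c(1, 1 - cr^2)))
    if (n > 0L) ld_corr <- ld_corr - log(diag(L)[i]) + log(s[i])
    L[i, seq_len(i - 1L)] <- cr * s[seq_len(i - 1L)]
    L[i, i] <- s[i]
  }
  list(lsd = lsd, z = z)
}

#' Fit the Bayesian path model
#'
#' Samples the joint posterior of the layered path model (see
#' [path_model_spec()]) by a blocked Gibbs/slice MCMC targeting exactly
#' the density computed by [log_density()].  Rows with any missing model
#' variable are dropped (with a message).  A zero-row dataset is allowed
#' and yields draws from the joint prior.
#'
#' @param data data frame containing `age`, `bmi`, the mediators of the
#'   chosen variant/colour mode, and the outcomes `sextypicality`,
#'   `dominance`.  Pass `NULL` for a prior-only fit.
#' @param variant,colour_mode model structure, see [path_model_spec()].
#' @param n_draws total retained posterior draws (pooled over chains).
#' @param chains number of independent chains (prior-drawn starts).
#' @param warmup discarded sweeps per chain; default half the retained
#'   sweeps per chain.
#' @param seed integer RNG seed; the fit is deterministic given it.
#' @param standardize z-score all model variables before fitting
#'   (recommended; the priors assume standardized scales).
#' @param spec optionally a ready [path_model_spec()]; overrides
#'   `variant`/`colour_mode`.
#' @return An object of class `facepath_fit` with elements `draws`
#'   (n_draws x n_parameters matrix, columns named per the manifest),
#'   `manifest`, `diagnostics` (split-Rhat and effective sample size per
#'   parameter), `converged` (all Rhat <= 1.01 and ESS >= 400), `n`,
#'   `n_dropped` and `seed`.
#' @seealso [summary.facepath_fit()], [coef.facepath_fit()],
#'   [plot.facepath_fit()]
#' @export
fit_path_model <- function(data, variant = "default",
                           colour_mode = "channels", n_draws = 10000L,
                           chains = 2L, warmup = NULL, seed = 1L,
                           standardize = TRUE, spec = NULL) {
  if (is.null(spec)) spec <- path_model_spec(variant, colour_mode,
                                             n_draws = n_draws)
  manifest <- build_model(spec)
  if (is.null(data)) {
    data <- as.data.frame(sapply(c("age", "bmi", manifest$mediators,
                                   manifest$outcomes),
                                 function(v) numeric(0), simplify = FALSE))
  }
  vars <- c("age", "bmi", manifest$mediators, manifest$outcomes)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0L) {
    stop("data is missing model variable(s): ",
         paste(missing_vars, collapse = ", "))
  }
  data <- data[, vars, drop = FALSE]
  keep <- stats::complete.cases(data)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " row(s) with missing model variables dropped")
    data <- data[keep, , drop = FALSE]
  }
  if (standardize && nrow(data) > 0L) {
    data <- standardize(data)
  }
  dm <- path_model_matrices(manifest, data)
  dm$dropped <- n_dropped
  n <- dm$n
  q <- length(manifest$mediators)
  p_out <- 3L + q

  n_draws <- as.integer(n_draws)
  chains <- as.integer(chains)
  per_chain <- ceiling(n_draws / chains)
  if (is.null(warmup)) warmup <- per_chain %/% 2L
  eta <- spec$lkj_eta; rate <- spec$sd_rate
  prec_i <- 1 / spec$prior_intercept_sd^2
  prec_s <- 1 / spec$prior_slope_sd^2

  XtX_b <- crossprod(dm$X_bmi); Xty_b <- crossprod(dm$X_bmi, dm$bmi)
  XtX_m <- crossprod(dm$X_med); XtM <- crossprod(dm$X_med, dm$M)
  XtX_o <- crossprod(dm$X_out); XtY <- crossprod(dm$X_out, dm$Y)
  prior_prec_b <- c(prec_i, prec_s)
  prior_prec_m <- rep(c(prec_i, prec_s, prec_s), q)
  prior_prec_o <- rep(c(prec_i, rep(prec_s, p_out - 1L)), 2L)

  P <- length(manifest$parameters)
  med_pairs <- cpc_pairs(q)
  bshape_m <- lkj_cpc_shape(q, eta)
  bshape_o <- lkj_cpc_shape(2, eta)
  set.seed(seed)
  all_draws <- array(NA_real_, dim = c(per_chain, chains, P))

  for (ch in seq_len(chains)) {
    # prior-drawn initial state (coefficient blocks are drawn first inside
    # the sweep, so only the scale/correlation state needs initialising)
    s_bmi <- stats::rexp(1, rate)
    lsd_m <- log(stats::rexp(q, rate))
    z_m <- atanh(lkj_sample_cpc(q, eta))
    lsd_o <- log(stats::rexp(2, rate))
    z_o <- atanh(lkj_sample_cpc(2, eta))

    for (sweep in seq_len(warmup + per_chain)) {
      # --- BMI equation coefficients and scale
      theta_b <- drop(draw_coef_block(XtX_b, Xty_b,
                                      matrix(1 / s_bmi^2, 1, 1), prior_prec_b))
      rss_b <- if (n > 0L) sum((dm$bmi - dm$X_bmi %*% theta_b)^2) else 0
      s_bmi <- exp(slice_sample_1d(log(s_bmi), function(ls) {
        s <- exp(ls)
        -n * ls - rss_b / (2 * s^2) - rate * s + ls
      }))
      # --- mediator block
      Lc_m <- cpc_to_chol(tanh(z_m), q)
      R_m <- tcrossprod(Lc_m); diag(R_m) <- 1
      Sig_m_inv <- chol2inv(chol(R_m)) / tcrossprod(exp(lsd_m))
      B_m <- draw_coef_block(XtX_m, XtM, Sig_m_inv, prior_prec_m)
      E_m <- if (n > 0L) dm$M - dm$X_med %*% B_m else matrix(0, 0, q)
      S_m <- crossprod(E_m)
      upd <- update_cov_block(lsd_m, z_m, S_m, n, bshape_m, rate)
      lsd_m <- upd$lsd; z_m <- upd$z
      # --- outcome block
      Lc_o <- cpc_to_chol(tanh(z_o), 2)
      R_o <- tcrossprod(Lc_o); diag(R_o) <- 1
      Sig_o_inv <- chol2inv(chol(R_o)) / tcrossprod(exp(lsd_o))
      B_o <- draw_coef_block(XtX_o, XtY, Sig_o_inv, prior_prec_o)
      E_o <- if (n > 0L) dm$Y - dm$X_out %*% B_o else matrix(0, 0, 2)
      S_o <- crossprod(E_o)
      upd <- update_cov_block(lsd_o, z_o, S_o, n, bshape_o, rate)
      lsd_o <- upd$lsd; z_o <- upd$z

      if (sweep > warmup) {
        R_m_cur <- cpc_to_corr(tanh(z_m), q)
        r_o_cur <- cpc_to_corr(tanh(z_o), 2)[2, 1]
        all_draws[sweep - warmup, ch, ] <- c(
          theta_b[1], B_m[1, ], B_o[1, ],              # intercepts
          theta_b[2],                                   # b_age_bmi
          B_m[2, ], B_m[3, ],                           # age->med, bmi->med
          as.vector(t(B_o[-1, , drop = FALSE])),        # per-predictor outcome slopes
          s_bmi, exp(lsd_m),
          R_m_cur[med_pairs],
          exp(lsd_o), r_o_cur)
      }
    }
  }

  draws <- matrix(all_draws, per_chain * chains, P)
  colnames(draws) <- manifest$parameters
  draws <- draws[seq_len(min(nrow(draws), n_draws)), , drop = FALSE]
  diag_tab <- mcmc_diagnostics(all_draws, manifest$parameters)
  converged <- all(diag_tab$rhat <= 1.01, na.rm = TRUE) &&
    all(diag_tab$ess >= 400, na.rm = TRUE)
  structure(list(draws = draws, manifest = manifest, spec = spec,
                 diagnostics = diag_tab, converged = converged,
                 n = n, n_dropped = dm$dropped, chains = chains,
                 warmup = warmup, seed = seed, data = data),
            class = "facepath_fit")
}

## split-Rhat and effective sample size from a (iter x chain x param) array
mcmc_diagnostics <- function(arr, par_names) {
  n <- dim(arr)[1]; m <- dim(arr)[2]; P <- dim(arr)[3]
  half <- n %/% 2L
  rhat <- ess <- rep(NA_real_, P)
  for (p in seq_len(P)) {
    # split each chain in half
    segs <- do.call(cbind, lapply(seq_len(m), function(ch) {
      cbind(arr[seq_len(half), ch, p], arr[half + seq_len(half), ch, p])
    }))
    if (stats::sd(as.vector(segs)) <= .Machine$double.eps) {
      rhat[p] <- 1; ess[p] <- n * m
      next
    }
    mns <- colMeans(segs); vars <- apply(segs, 2, stats::var)
    W <- mean(vars); B <- half * stats::var(mns)
    var_plus <- (half - 1) / half * W + B / half
    rhat[p] <- sqrt(var_plus / W)
    # combined autocorrelation, Geyer initial positive sequence
    k <- ncol(segs)
    lag_max <- min(half - 1L, 200L)
    acov <- sapply(seq_len(k), function(j) {
      a <- stats::acf(segs[, j], lag.max = lag_max, type = "covariance",
                      plot = FALSE, demean = TRUE)$acf[, 1, 1]
      a
    })
    rho <- 1 - (W - rowMeans(acov[-1, , drop = FALSE])) / var_plus
    tau <- 1
    t <- 1L
    while (t + 1L <= length(rho)) {
      pair <- rho[t] + rho[t + 1L]
      if (pair < 0) break
      tau <- tau + 2 * pair
      t <- t + 2L
    }
    ess[p] <- min(k * half / tau, k * half)
  }
  data.frame(parameter = par_names, rhat = rhat, ess = ess,
             stringsAsFactors = FALSE)
}
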