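test_that("standardization gives exact z-scores and inverts", {
  set.seed(1)
  tab <- data.frame(g = rep(c("x", "y"), each = 20),
                    a = rnorm(40, 5, 3), b = runif(40, 10, 20))
  z <- standardize(tab, c("a", "b"), by = "g")
  for (g in c("x", "y")) {
    expect_equal(mean(z$a[z$g == g]), 0, tolerance = 1e-12)
    expect_equal(sd(z$b[z$g == g]), 1, tolerance = 1e-12)
  }
  back <- unstandardize(z)
  expect_equal(back$a, tab$a, tolerance = 1e-12)
  expect_equal(back$b, tab$b, tolerance = 1e-12)
  tab$c <- 3
  expect_error(standardize(tab, "c"), "constant")
})

test_that("the manifest reproduces the model's parameter counts", {
  counts <- function(variant, mode) unlist(build_model(variant, mode)$counts)
  expect_equal(counts("default", "channels"),
               c(intercepts = 9, slopes = 29, mediator_variances = 6,
                 mediator_covariances = 15, outcome_variances = 2,
                 outcome_covariances = 1))
  expect_equal(counts("extended", "channels"),
               c(intercepts = 11, slopes = 37, mediator_variances = 8,
                 mediator_covariances = 28, outcome_variances = 2,
                 outcome_covariances = 1))
  # partial variants, cross-checked by combinatorial enumeration:
  # q mediators -> 1 + q + 2 intercepts, 1 + 2q + 2(q + 2) slopes, C(q,2) corrs
  for (v in c("shape_dominance_only", "shape_sextypicality_only")) {
    q <- 7
    expect_equal(unname(counts(v, "channels")),
                 c(1 + q + 2, 1 + 2 * q + 2 * (q + 2), q, choose(q, 2), 2, 1))
  }
  # factor colour mode collapses three channels into one mediator
  expect_equal(unname(counts("default", "factor")),
               c(1 + 4 + 2, 1 + 2 * 4 + 2 * 6, 4, choose(4, 2), 2, 1))
  m <- build_model("default", "channels")
  expect_false(anyDuplicated(m$parameters) > 0)
  expect_length(m$parameters,
                9 + 29 + 1 + 6 + 15 + 2 + 1)   # + the BMI residual SD
  expect_error(build_model("nonsense"), "arg")
})

null_point <- function(manifest) {
  q <- length(manifest$mediators)
  list(intercepts = setNames(rep(0, length(manifest$intercepts)),
                             manifest$intercepts),
       slopes = setNames(rep(0, length(manifest$slopes)), manifest$slopes),
       sigma_bmi = 1, mediator_sds = rep(1, q), mediator_corr = diag(q),
       outcome_sds = c(1, 1), outcome_corr = 0)
}

test_that("log density at the null point equals the closed-form prior sum", {
  manifest <- build_model("default", "channels")
  empty <- data.frame(age = numeric(0), bmi = numeric(0), L = numeric(0),
                      a = numeric(0), b = numeric(0), fwhr = numeric(0),
                      sshd = numeric(0), dist = numeric(0),
                      sextypicality = numeric(0), dominance = numeric(0))
  ld <- log_density(manifest, null_point(manifest), empty)
  # closed forms, written out independently: 9 intercepts N(0, 0.2),
  # 29 slopes N(0, 0.5), 9 sds Exp(1) at 1, LKJ(2) at identity for d = 6
  # and d = 2 (log det = 0, so only the normalising constants remain)
  lkj_norm <- function(d, eta) {
    k <- 1:(d - 1); b <- eta + (d - 1 - k) / 2
    sum((d - k) * ((2 * b - 1) * log(2) + lbeta(b, b)))
  }
  expected <- 9 * dnorm(0, 0, 0.2, log = TRUE) +
    29 * dnorm(0, 0, 0.5, log = TRUE) + 9 * dexp(1, 1, log = TRUE) -
    lkj_norm(6, 2) - lkj_norm(2, 2)
  expect_equal(ld, expected, tolerance = 1e-12)
  # non-positive-definite correlation input is flagged, not crashed
  bad <- null_point(manifest)
  bad$mediator_corr <- matrix(0.99, 6, 6) - diag(0.99 * 0:5 / 5) * 0
  diag(bad$mediator_corr) <- 1
  bad$mediator_corr[1, 2] <- bad$mediator_corr[2, 1] <- -0.99
  ld_bad <- log_density(manifest, bad, empty)
  expect_identical(as.numeric(ld_bad), -Inf)
  expect_match(attr(ld_bad, "reason"), "positive definite")
})

test_that("log density matches an independently assembled computation", {
  # single specimen, factor colour mode (4 mediators), everything written
  # out with explicit normal/MVN algebra
  manifest <- build_model("default", "factor")
  set.seed(2)
  row <- data.frame(age = 0.7, bmi = -0.3, colour = 0.5, fwhr = 1.1,
                    sshd = -0.8, dist = 0.2, sextypicality = 0.9,
                    dominance = -0.4)
  pt <- null_point(manifest)
  pt$intercepts[] <- seq(-0.2, 0.2, length.out = 7)
  pt$slopes[] <- seq(-0.4, 0.4, length.out = 21)
  pt$sigma_bmi <- 0.8
  pt$mediator_sds <- c(0.9, 1.1, 0.7, 1.3)
  R <- diag(4); R[1, 2] <- R[2, 1] <- 0.3; R[3, 4] <- R[4, 3] <- -0.2
  pt$mediator_corr <- R
  pt$outcome_sds <- c(0.85, 1.05)
  pt$outcome_corr <- 0.45
  ld <- log_density(manifest, pt, row)

  # independent oracle
  dmvn <- function(x, mu, S) {
    -length(x) / 2 * log(2 * pi) - 0.5 * determinant(S)$modulus[1] -
      0.5 * drop(t(x - mu) %*% solve(S) %*% (x - mu))
  }
  lkj_norm <- function(d, eta) {
    k <- 1:(d - 1); b <- eta + (d - 1 - k) / 2
    sum((d - k) * ((2 * b - 1) * log(2) + lbeta(b, b)))
  }
  a <- pt$intercepts; b <- pt$slopes
  prior <- sum(dnorm(a, 0, 0.2, log = TRUE)) +
    sum(dnorm(b, 0, 0.5, log = TRUE)) +
    sum(dexp(c(pt$sigma_bmi, pt$mediator_sds, pt$outcome_sds), 1, log = TRUE)) +
    (2 - 1) * determinant(R)$modulus[1] - lkj_norm(4, 2) +
    (2 - 1) * log(1 - 0.45^2) - lkj_norm(2, 2)
  med <- c("colour", "fwhr", "sshd", "dist")
  mu_m <- sapply(med, function(m) {
    a[paste0("a_", m)] + b[paste0("b_age_", m)] * row$age +
      b[paste0("b_bmi_", m)] * row$bmi
  })
  S_m <- diag(pt$mediator_sds) %*% R %*% diag(pt$mediator_sds)
  x_m <- unlist(row[med])
  mu_o <- sapply(c("sextypicality", "dominance"), function(o) {
    a[paste0("a_", o)] + b[paste0("b_age_", o)] * row$age +
      b[paste0("b_bmi_", o)] * row$bmi +
      sum(sapply(med, function(m) b[paste0("b_", m, "_", o)] * row[[m]]))
  })
  Ro <- matrix(c(1, 0.45, 0.45, 1), 2)
  S_o <- diag(pt$outcome_sds) %*% Ro %*% diag(pt$outcome_sds)
  lik <- dnorm(row$bmi, a["a_bmi"] + b["b_age_bmi"] * row$age, 0.8,
               log = TRUE) +
    dmvn(x_m, mu_m, S_m) +
    dmvn(unlist(row[c("sextypicality", "dominance")]), mu_o, S_o)
  expect_equal(ld, unname(prior + lik), tolerance = 1e-10)
})

test_that("density falls when any slope leaves its generative value", {
  truth <- study_preset("czech_women")
  set.seed(3)
  dat <- simulate_path_data(truth, 600)
  manifest <- build_model("default", "channels")
  pt <- null_point(manifest)
  # parameter point at the generative values
  pt$slopes["b_age_bmi"] <- truth$bmi_on_age_slope
  for (m in truth$mediators) {
    pt$slopes[paste0("b_age_", m)] <- truth$mediator_slopes["age", m]
    pt$slopes[paste0("b_bmi_", m)] <- truth$mediator_slopes["bmi", m]
  }
  for (o in c("sextypicality", "dominance")) {
    pt$slopes[paste0("b_age_", o)] <- truth$outcome_slopes["age", o]
    pt$slopes[paste0("b_bmi_", o)] <- truth$outcome_slopes["bmi", o]
    for (m in truth$mediators) {
      pt$slopes[paste0("b_", m, "_", o)] <- truth$outcome_slopes[m, o]
    }
  }
  pt$mediator_corr <- truth$mediator_residual_corr
  pt$outcome_corr <- truth$outcome_residual_corr
  ld0 <- log_density(manifest, pt, dat)
  for (s in c("b_age_bmi", "b_sshd_sextypicality", "b_bmi_fwhr",
              "b_age_dominance")) {
    for (shift in c(-1.5, 1.5)) {
      pt2 <- pt
      pt2$slopes[s] <- pt2$slopes[s] + shift
      expect_lt(log_density(manifest, pt2, dat), ld0)
    }
  }
})

test_that("posterior summaries follow the draws' quantiles", {
  set.seed(4)
  draws <- cbind(z = rnorm(20000), k = rep(2.5, 20000))
  s <- summarize_draws(draws)
  expect_equal(s$lower[1], qnorm(0.025), tolerance = 0.05)
  expect_equal(s$upper[1], qnorm(0.975), tolerance = 0.05)
  expect_equal(s$mean[2], 2.5)
  expect_equal(s$upper[2] - s$lower[2], 0)   # constant draws: zero width
})

test_that("the sampled BMI-equation posterior matches numerical integration", {
  set.seed(5)
  n <- 60
  age <- rnorm(n)
  bmi_v <- 0.25 * age + rnorm(n, 0, 0.9)
  dat <- data.frame(age = age, bmi = bmi_v)
  for (v in c("L", "a", "b", "fwhr", "sshd", "dist",
              "sextypicality", "dominance")) dat[[v]] <- rnorm(n)
  fit <- fit_path_model(dat, n_draws = 4000, chains = 2, warmup = 1000,
                        seed = 6, standardize = FALSE)
  # independent oracle: the (a_bmi, b_age_bmi, sigma_bmi) posterior block
  # factorises from the rest; integrate it on a dense grid
  Sx <- sum(age); Sxx <- sum(age^2); Sy <- sum(bmi_v)
  Sxy <- sum(age * bmi_v); Syy <- sum(bmi_v^2)
  ols <- coef(lm(bmi_v ~ age)); sig_hat <- summary(lm(bmi_v ~ age))$sigma
  a_grid <- seq(ols[1] - 0.8, ols[1] + 0.8, length.out = 81)
  b_grid <- seq(ols[2] - 0.8, ols[2] + 0.8, length.out = 81)
  s_grid <- seq(max(sig_hat / 2.5, 0.05), sig_hat * 2.5, length.out = 61)
  lp <- array(0, c(81, 81, 61))
  for (i in seq_along(a_grid)) for (k in seq_along(s_grid)) {
    a <- a_grid[i]; s <- s_grid[k]
    rss <- Syy - 2 * a * Sy - 2 * b_grid * Sxy + 2 * a * b_grid * Sx +
      n * a^2 + b_grid^2 * Sxx
    lp[i, , k] <- -n * log(s) - rss / (2 * s^2) +
      dnorm(a, 0, 0.2, log = TRUE) + dnorm(b_grid, 0, 0.5, log = TRUE) +
      dexp(s, 1, log = TRUE)
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  e_b <- sum(aperm(w, c(2, 1, 3)) * b_grid)
  e_a <- sum(w * a_grid)
  dg <- fit$diagnostics
  mc_se <- function(p) sd(fit$draws[, p]) / sqrt(dg$ess[dg$parameter == p])
  expect_lt(abs(mean(fit$draws[, "b_age_bmi"]) - e_b),
            3 * mc_se("b_age_bmi") + 1e-3)
  expect_lt(abs(mean(fit$draws[, "a_bmi"]) - e_a), 3 * mc_se("a_bmi") + 1e-3)
})

test_that("posterior slope uncertainty contracts with sample size", {
  truth <- study_preset("czech_women")
  sds <- sapply(c(50, 200, 800), function(n) {
    dat <- simulate_path_data(truth, n, seed = 100 + n)
    fit <- fit_path_model(dat, n_draws = 600, chains = 2, warmup = 200,
                          seed = 7)
    mean(apply(fit$draws[, fit$manifest$slopes], 2, sd))
  })
  expect_true(all(diff(sds) < 0))
})

test_that("specimen order does not affect the posterior", {
  truth <- study_preset("czech_women")
  dat <- simulate_path_data(truth, 150, seed = 8)
  fit1 <- fit_path_model(dat, n_draws = 800, chains = 2, warmup = 300,
                         seed = 9)
  fit2 <- fit_path_model(dat[sample(nrow(dat)), ], n_draws = 800,
                         chains = 2, warmup = 300, seed = 9)
  m1 <- coef(fit1); m2 <- coef(fit2)
  se <- sapply(colnames(fit1$draws), function(p) {
    sqrt(sd(fit1$draws[, p])^2 / fit1$diagnostics$ess[
      fit1$diagnostics$parameter == p] +
      sd(fit2$draws[, p])^2 / fit2$diagnostics$ess[
        fit2$diagnostics$parameter == p])
  })
  expect_true(all(abs(m1 - m2) < 3.5 * se + 1e-4))
})

test_that("prior-only fits expose the priors through every margin", {
  fit <- fit_path_model(NULL, n_draws = 2000, chains = 2, seed = 10)
  expect_equal(fit$n, 0L)
  expect_equal(mean(fit$draws[, "b_age_sshd"]), 0, tolerance = 0.05)
  expect_equal(sd(fit$draws[, "b_age_sshd"]), 0.5, tolerance = 0.05)
  expect_equal(mean(fit$draws[, "sigma_dist"]), 1, tolerance = 0.07)
  expect_equal(mean(fit$draws[, "rho_L_b"]), 0, tolerance = 0.05)
})

test_that("missing rows are dropped with a message, not imputed", {
  truth <- study_preset("czech_women")
  dat <- simulate_path_data(truth, 60, seed = 11)
  dat$sshd[c(3, 9)] <- NA
  expect_message(
    fit <- fit_path_model(dat, n_draws = 200, chains = 1, warmup = 100,
                          seed = 12),
    "2 row")
  expect_equal(fit$n, 58L)
})
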