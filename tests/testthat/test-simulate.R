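test_that("ground truth validates its correlation inputs", {
  expect_error(ground_truth(mediator_residual_corr = matrix(0.99, 6, 6)),
               "unit diagonal|positive definite")
  bad <- diag(6); bad[1, 2] <- 0.5   # asymmetric
  expect_error(ground_truth(mediator_residual_corr = bad), "symmetric")
  nonpd <- matrix(0.99, 3, 3); diag(nonpd) <- 1
  nonpd[1, 2] <- nonpd[2, 1] <- -0.99
  expect_error(ground_truth(mediators = c("fwhr", "sshd", "dist"),
                            mediator_slopes = matrix(0.1, 2, 3),
                            mediator_residual_corr = nonpd,
                            outcome_slopes = matrix(0.1, 5, 2)),
               "positive definite")
  expect_error(ground_truth(outcome_residual_corr = 1.2), "\\(-1, 1\\)")
  expect_error(ground_truth(n_raters = 1), "n_raters")
})

test_that("zero-noise studies are fully degenerate", {
  truth <- tiny_truth(sshd_within_sd = 0, idiosyncratic_sd = 0,
                      curve_jitter_sd = 0, rater_noise_sd = 0,
                      dist_gain = 0)
  st <- simulate_study(truth, c(5, 5), seed = 21)
  # every rater's rating equals the rounded, clamped latent value
  an <- truth$anchors$sextypicality
  latent <- an[1] + an[2] * st$latent$sextypicality
  expected <- pmin(pmax(round(latent), 1), 7)
  for (r in seq_len(nrow(st$ratings_sextypicality))) {
    expect_equal(unname(st$ratings_sextypicality[r, ]), expected)
  }
  # specimens within a sex share one shape: aligned distances vanish
  al <- gpa(st$landmarks, tol = 1e-10, max_iter = 100)
  sex <- st$specimens$sex[match(al$ids, st$specimens$id)]
  for (s in c("female", "male")) {
    idx <- which(sex == s)
    for (i in idx[-1]) {
      expect_lt(procrustes_distance(al$aligned[idx[1], , ],
                                    al$aligned[i, , ]), 1e-8)
    }
  }
})

test_that("noiseless zero-latent landmarks are similarity copies of the template", {
  truth <- tiny_truth(idiosyncratic_sd = 0, curve_jitter_sd = 0)
  cfgs <- simulate_landmarks(truth, rep(0, 4), seed = 22)
  for (cf in cfgs) {
    expect_lt(opa_align(truth$template$points, cf$points)$distance, 1e-10)
  }
  al <- gpa(cfgs)
  expect_lt(procrustes_distance(al$aligned[1, , ], al$aligned[4, , ]), 1e-10)
})

test_that("latent outcome residual correlation is reproduced at scale", {
  truth <- tiny_truth(outcome_residual_corr = 0.6)
  dat <- simulate_path_data(truth, 5000, seed = 23)
  res_s <- residuals(lm(sextypicality ~ age + bmi + L + a + b + fwhr +
                          sshd + dist, dat))
  res_d <- residuals(lm(dominance ~ age + bmi + L + a + b + fwhr +
                          sshd + dist, dat))
  expect_equal(cor(res_s, res_d), 0.6, tolerance = 0.05)
})

test_that("generated moments converge to the ground truth", {
  truth <- study_preset("czech_women")
  dat <- simulate_path_data(truth, 2000, seed = 24)
  n <- nrow(dat)
  # every variable standardized to unit total variance (3 MC SEs)
  for (v in names(dat)) {
    expect_lt(abs(mean(dat[[v]])), 3 / sqrt(n) * 1.1)
    expect_lt(abs(sd(dat[[v]]) - 1), 3 / sqrt(2 * n) * 1.3)
  }
  expect_equal(cor(dat$age, dat$bmi), truth$bmi_on_age_slope,
               tolerance = 3 / sqrt(n) * 1.5)
  expect_equal(unname(coef(lm(fwhr ~ age + bmi, dat))[3]),
               truth$mediator_slopes["bmi", "fwhr"], tolerance = 0.07)
})

test_that("identical seeds give byte-identical studies, different seeds differ", {
  truth <- tiny_truth()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  write_study(simulate_study(truth, c(6, 6), seed = 33), d1)
  write_study(simulate_study(truth, c(6, 6), seed = 33), d2)
  write_study(simulate_study(truth, c(6, 6), seed = 34), d3)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  expect_false(identical(unname(tools::md5sum(file.path(d1, "landmarks.tps"))),
                         unname(tools::md5sum(file.path(d3, "landmarks.tps")))))
})

test_that("rating matrices reach perfect reliability as rater noise vanishes", {
  base <- function(noise) {
    st <- simulate_study(tiny_truth(rater_noise_sd = noise), c(10, 10),
                         seed = 25)
    icc_3k(st$ratings_dominance)
  }
  expect_equal(base(0), 1)
  expect_gt(base(0.4), base(1.5))
})

test_that("study presets reproduce the published calibration anchors", {
  truth <- study_preset("czech_women")
  expect_identical(attr(truth, "n_default"), c(106L, 89L))
  st <- simulate_study(truth, attr(truth, "n_default"), seed = 26)
  sp <- st$specimens[st$specimens$sex == "female", ]
  # age and rating moments within 20% of the published values
  expect_equal(mean(sp$age), 23.09, tolerance = 0.2 * 23.09 / 23.09)
  expect_lt(abs(sd(sp$age) - 4.12) / 4.12, 0.2)
  mr <- mean_ratings(st$ratings_sextypicality)
  expect_lt(abs(mean(mr) - 4.00) / 4.00, 0.2)
  expect_lt(abs(sd(mr) - 0.84) / 0.84, 0.2)
  bmi_obs <- bmi(sp$weight, sp$height)
  expect_lt(abs(mean(bmi_obs) - 21.8) / 21.8, 0.2)
  # recovered per-sex SShD score SDs land in the published 0.01-0.02 band
  al <- gpa(st$landmarks, scheme = st$scheme, slide = TRUE)
  sex <- st$specimens$sex[match(al$ids, st$specimens$id)]
  ss <- sshd_scores(al, sex)
  for (s in c("female", "male")) {
    expect_gt(sd(ss[sex == s]), 0.01)
    expect_lt(sd(ss[sex == s]), 0.02)
  }
  # women more female-like (negative), men positive
  expect_lt(mean(ss[sex == "female"]), 0)
  expect_gt(mean(ss[sex == "male"]), 0)
})

test_that("recovered SShD scores track the injected latents", {
  truth <- study_preset("czech_women")
  st <- simulate_study(truth, c(30, 30), seed = 27)
  al <- gpa(st$landmarks, scheme = st$scheme, slide = TRUE)
  ss <- sshd_scores(al, st$specimens$sex[match(al$ids, st$specimens$id)])
  expect_gt(cor(ss[st$focal_ids], st$latent$sshd_latent), 0.9)
})

test_that("factor-mode presets produce collinear channels driven by one factor", {
  truth <- study_preset("cmr_women")
  st <- simulate_study(truth, c(50, 49), seed = 28)
  chan <- as.matrix(st$specimens[st$specimens$sex == "female",
                                 c("L", "a", "b")])
  R <- cor(chan)
  expect_gt(max(abs(R[upper.tri(R)])), 0.8)
  expect_equal(as.character(choose_colour_mode(chan, seed = 5)), "factor")
  fa <- extract_colour_factor(chan)
  expect_gt(cor(fa$scores, st$latent$colour), 0.85)
})

test_that("extended presets carry the shape-trait mediators", {
  truth <- study_preset("czech_women", extended = TRUE)
  expect_setequal(truth$mediators,
                  c("L", "a", "b", "fwhr", "sshd", "dist",
                    "shape_dominance", "shape_sextypicality"))
  expect_equal(truth$mediator_residual_corr["sshd", "shape_sextypicality"],
               -0.87)
  dat <- simulate_path_data(truth, 3000, seed = 29)
  res <- sapply(c("sshd", "shape_sextypicality"), function(v)
    residuals(lm(stats::reformulate(c("age", "bmi"), v), dat)))
  expect_equal(cor(res[, 1], res[, 2]), -0.87, tolerance = 0.03)
})
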