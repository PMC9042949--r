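# build an aligned_sample by hand (bypassing GPA) so projection oracles
# can be checked against explicit arithmetic
manual_aligned <- function(X_flat, ids = NULL) {
  n <- nrow(X_flat); k <- ncol(X_flat) / 2
  arr <- array(0, dim = c(n, k, 2))
  for (i in seq_len(n)) arr[i, , ] <- matrix(X_flat[i, ], k, 2)
  structure(list(aligned = arr, consensus = matrix(colMeans(X_flat), k, 2),
                 centroid_sizes = rep(1, n), iterations = 1L,
                 converged = TRUE,
                 ids = ids %||% sprintf("s%02d", seq_len(n)),
                 slide = FALSE, slide_criterion = NA, objective = numeric(0)),
            class = "aligned_sample")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("SShD scores are midpoint-centred projections on the sex axis", {
  # 3-landmark toy: male and female mean shapes written out by hand
  f_mean <- c(0, 1, -1, 0, 0, 0)     # flattened (x1,x2,x3,y1,y2,y3)
  m_mean <- c(0, 1.2, -1.2, 0.2, 0, 0)
  set.seed(5)
  X <- rbind(f_mean, f_mean + 0.01, m_mean, m_mean - 0.01,
             f_mean, m_mean)
  sex <- c("female", "female", "male", "male", "female", "male")
  al <- manual_aligned(X)
  sc <- sshd_scores(al, sex)
  # hand-computed oracle: axis, midpoint, dot products done explicitly
  fm <- colMeans(X[sex == "female", ]); mm <- colMeans(X[sex == "male", ])
  axis_hand <- (mm - fm) / sqrt(sum((mm - fm)^2))
  mid <- (fm + mm) / 2
  expected <- as.numeric((X - rep(mid, each = 6)) %*% axis_hand)
  expect_equal(unname(sc), expected, tolerance = 1e-12)
  # a specimen exactly at a sex mean scores +/- half the inter-mean distance
  half <- sqrt(sum((mm - fm)^2)) / 2
  sc2 <- sshd_scores(manual_aligned(rbind(X, mm, fm)),
                     c(sex, "male", "female"))
  expect_equal(unname(sc2[7]), half, tolerance = 1e-10)
  expect_equal(unname(sc2[8]), -half, tolerance = 1e-10)
  # lower = more female-like (sign contract)
  expect_lt(mean(sc[sex == "female"]), mean(sc[sex == "male"]))
})

test_that("SShD is linear along the dimorphism axis", {
  set.seed(6)
  X <- matrix(rnorm(12 * 8, sd = 0.1), 12, 8) +
    rep(c(0, 1, 0, -1, 0.5, 0.5, -0.5, -0.5), each = 12)
  sex <- rep(c("female", "male"), each = 6)
  X[sex == "male", 1] <- X[sex == "male", 1] + 0.5
  al <- manual_aligned(X)
  sc <- sshd_scores(al, sex)
  fm <- colMeans(X[sex == "female", ]); mm <- colMeans(X[sex == "male", ])
  d <- (mm - fm) / sqrt(sum((mm - fm)^2))
  delta <- 0.037
  X2 <- X; X2[3, ] <- X2[3, ] + delta * d
  sc2 <- sshd_scores(manual_aligned(X2), sex)
  # moving female specimen 3 by delta*d moves the female mean by delta*d/6
  # and the midpoint by delta*d/12, all parallel to d, so the axis is
  # unchanged and the score moves by exactly delta * (1 - 1/12)
  expect_equal(unname(sc2[3] - sc[3]), delta * (1 - 1 / 12),
               tolerance = 1e-10)
  expect_error(sshd_scores(al, rep("male", 12)), "both sexes|male/female")
})

test_that("distinctiveness is the Procrustes distance from the consensus", {
  set.seed(8)
  X <- matrix(rnorm(5 * 6), 5, 6)
  al <- manual_aligned(X)
  d <- distinctiveness(al)
  expected <- sqrt(rowSums(sweep(X, 2, colMeans(X))^2))
  expect_equal(unname(d), unname(expected))
  # appending the mean of the first rows yields a specimen that equals the
  # consensus of the extended sample exactly, hence distinctiveness 0
  X5 <- rbind(X, colMeans(X))  # row 6 = mean of rows 1..5 = mean of all 6
  al2 <- manual_aligned(X5)
  expect_lt(unname(distinctiveness(al2)[6]), 1e-12)
})

test_that("larger noise strictly increases expected distinctiveness", {
  set.seed(9)
  n <- 20; reps <- 100
  base <- matrix(rnorm(8), 1, 8)
  last_dist <- function(noise_sd) {
    mean(vapply(seq_len(reps), function(r) {
      X <- rbind(base[rep(1, n - 1), ] +
                   matrix(rnorm((n - 1) * 8, 0, 0.05), n - 1, 8),
                 base + rnorm(8, 0, noise_sd))
      unname(distinctiveness(manual_aligned(X))[n])
    }, numeric(1)))
  }
  expect_gt(last_dist(0.25), last_dist(0.05))
})

test_that("shape-trait scores match an explicit normal-equations fit", {
  set.seed(10)
  X <- matrix(rnorm(5 * 6), 5, 6)    # n = 5, 3 landmarks
  trait <- c(-1.2, -0.5, 0, 0.7, 1.0)
  al <- manual_aligned(X)
  sc <- shape_trait_scores(al, trait)
  # oracle: per-coordinate least squares via stats::lm, then projection
  Xc <- sweep(X, 2, colMeans(X))
  b_hand <- apply(Xc, 2, function(col) unname(coef(lm(col ~ trait))[2]))
  expected <- as.numeric(Xc %*% b_hand)
  expect_equal(unname(sc), expected, tolerance = 1e-10)
  expect_equal(mean(sc), 0, tolerance = 1e-12)
  expect_error(shape_trait_scores(al, rep(1, 5)), "constant")
})

test_that("trait scores vanish when the trait is independent of shape", {
  set.seed(11)
  n <- 2000
  X <- matrix(rnorm(n * 6, sd = 0.05), n, 6)
  trait <- rnorm(n)
  sc <- shape_trait_scores(manual_aligned(X), trait)
  # slopes are O(1/sqrt(n)); scores collapse toward zero
  expect_lt(stats::sd(sc), 0.05 * 0.05 * 10)
  expect_equal(mean(sc), 0, tolerance = 1e-12)
})

test_that("all three scores are invariant to raw-data similarity transforms", {
  truth <- tiny_truth()
  st <- simulate_study(truth, c(12, 12), seed = 13)
  sex <- st$specimens$sex[match(vapply(st$landmarks, function(x) x$id,
                                       character(1)), st$specimens$id)]
  run_scores <- function(configs) {
    al <- gpa(configs, tol = 1e-12, max_iter = 200)
    trait <- sin(seq_along(configs))          # fixed pseudo-trait
    list(sshd = sshd_scores(al, sex), dist = distinctiveness(al),
         trait = shape_trait_scores(al, trait))
  }
  base <- run_scores(st$landmarks)
  set.seed(99)
  moved <- lapply(st$landmarks, function(cf) {
    landmark_config(similarity_transform(cf$points, runif(1, 0, 2 * pi),
                                         exp(runif(1, -0.6, 0.6)),
                                         rnorm(2, 0, 5)), id = cf$id)
  })
  new <- run_scores(moved)
  expect_lt(max(abs(new$sshd - base$sshd)), 1e-8)
  expect_lt(max(abs(new$dist - base$dist)), 1e-8)
  expect_lt(max(abs(new$trait - base$trait)), 1e-8)
})

test_that("recovered trait scores track the injected shape component", {
  # shape carries a known component along the dimorphism axis; the trait
  # is that component plus noise -- scores must recover the ordering
  truth <- tiny_truth(idiosyncratic_sd = 0.002, curve_jitter_sd = 0)
  n <- 200
  set.seed(14)
  lat <- rnorm(n, 0, 0.015)
  configs <- simulate_landmarks(truth, lat, seed = 15)
  al <- gpa(configs)
  trait <- as.numeric(scale(lat + rnorm(n, 0, 0.003)))
  sc <- shape_trait_scores(al, trait)
  expect_gt(cor(sc, lat), 0.9)
})

test_that("score tables merge per-sex trait scores by specimen id", {
  st <- simulate_study(tiny_truth(), c(8, 8), seed = 16)
  al <- gpa(st$landmarks)
  sex <- st$specimens$sex[match(al$ids, st$specimens$id)]
  traits <- list(dominance = rnorm(16))
  tab <- shape_score_table(al, sex, traits)
  expect_setequal(names(tab), c("id", "sshd", "dist", "shape_dominance"))
  expect_equal(tab$id, al$ids)
  # trait scores are centred within each sex subset
  expect_equal(mean(tab$shape_dominance[sex == "female"]), 0,
               tolerance = 1e-10)
  expect_equal(mean(tab$shape_dominance[sex == "male"]), 0,
               tolerance = 1e-10)
})
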