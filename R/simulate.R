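## Synthetic-study generator.  Every downstream stage (TPS ingestion, GPA,
## shape scores, reliability, colour handling, the path model fit) can be
## exercised on studies generated here from a fully known ground truth.

#' The packaged 72-point schematic face template
#'
#' A synthetic frontal-face landmark scheme: 36 fixed anatomical landmarks
#' plus 36 semi-landmarks on four curves (jaw/face outline, left and right
#' brow, upper lip).  The geometry is a schematic stand-in built in code --
#' all downstream mathematics is scheme-agnostic, only the declared
#' fixed/semi roles and curve memberships matter.  Centred, unit centroid
#' size.
#'
#' @return List with `points` (72 x 2 matrix) and `scheme`
#'   (a [landmark_scheme()]).
#' @export
face_template <- function() {
  mirror <- function(p) cbind(-p[, 1], p[, 2])
  fixed <- rbind(
    c(0, 0.55), c(0, 0.45), c(0, -0.05), c(0, -0.18),        # glabella, nasion, nose tip, subnasale
    c(-0.18, -0.10), c(0.18, -0.10),                          # alae
    c(-0.08, -0.15), c(0.08, -0.15),                          # nostrils
    c(-0.22, 0.30), c(0.22, 0.30),                            # inner eye corners
    c(-0.52, 0.33), c(0.52, 0.33),                            # outer eye corners
    c(-0.37, 0.32), c(0.37, 0.32),                            # pupils
    c(-0.37, 0.40), c(0.37, 0.40),                            # upper eyelids
    c(-0.37, 0.26), c(0.37, 0.26),                            # lower eyelids
    c(-0.20, 0.55), c(0.20, 0.55),                            # brow inner ends
    c(-0.58, 0.52), c(0.58, 0.52),                            # brow outer ends
    c(-0.85, 0.10), c(0.85, 0.10),                            # zygia
    c(-0.62, -0.60), c(0.62, -0.60),                          # gonia
    c(-0.30, -0.42), c(0.30, -0.42),                          # mouth corners
    c(0, -0.35), c(0, -0.52),                                 # upper/lower lip mid
    c(0, -1.00), c(0, -0.85),                                 # chin tip, pogonion
    c(-0.72, 0.55), c(0.72, 0.55),                            # temples
    c(0, 0.95), c(0, -0.44))                                  # forehead mid, stomion
  # jaw/face outline: 16 points, left zygion around the chin to right zygion
  t_jaw <- seq(0.05, 0.95, length.out = 16)
  jaw <- cbind(-0.88 * cos(pi * t_jaw),
               0.10 - 1.10 * sin(pi * t_jaw)^1.3)
  # brows: 6 points each, arcs above the eyes
  t_br <- seq(0.1, 0.9, length.out = 6)
  brow_l <- cbind(-0.58 + 0.38 * t_br, 0.545 + 0.065 * sin(pi * t_br))
  brow_r <- mirror(brow_l)[6:1, , drop = FALSE]
  # upper lip: 8 points, left corner to right corner
  t_lip <- seq(0.08, 0.92, length.out = 8)
  lip <- cbind(-0.30 + 0.60 * t_lip,
               -0.42 + 0.09 * sin(pi * t_lip) + 0.01 * cos(3 * pi * t_lip))
  pts <- rbind(fixed, jaw, brow_l, brow_r, lip)
  pts <- centre_config(pts)
  pts <- pts / sqrt(sum(pts^2))
  scheme <- landmark_scheme(
    roles = c(rep("fixed", 36), rep("semi", 36)),
    curve_id = c(rep(0L, 36), rep(1L, 16), rep(2L, 6), rep(3L, 6), rep(4L, 8)))
  list(points = pts, scheme = scheme)
}

#' The template's sexual dimorphism axis
#'
#' A deterministic male-ward displacement field on the template (wider
#' jaw and zygia, lower brows, thinner lips, longer chin, slightly
#' narrower eyes), centred and normalised to a unit 144-vector in shape
#' space.  Adding a positive multiple of this axis to the template makes
#' the shape more male-like.
#'
#' @param template a [face_template()] (defaults to the packaged one).
#' @return Unit numeric vector of length 144 (column-major x then y).
#' @export
dimorphism_axis <- function(template = face_template()) {
  pts <- template$points
  d <- matrix(0, nrow(pts), 2)
  jaw <- 37:52; brow <- c(19:22, 53:64); lip <- c(29, 65:72)
  d[jaw, 1] <- 0.06 * sign(pts[jaw, 1]) * abs(pts[jaw, 1])
  d[jaw, 2] <- -0.02 * pmax(-pts[jaw, 2], 0)
  d[c(23, 24, 25, 26), 1] <- 0.05 * sign(pts[c(23, 24, 25, 26), 1])
  d[brow, 2] <- -0.025
  d[lip, 2] <- 0.012
  d[30, 2] <- 0.02
  d[c(31, 36), 2] <- -0.04
  d[c(15, 16), 2] <- -0.008
  d[c(17, 18), 2] <- 0.008
  v <- as.vector(centre_config(d))
  v / sqrt(sum(v^2))
}

#' Ground truth for a synthetic study
#'
#' Collects every generative quantity of a study: the landmark geometry
#' (template, dimorphism axis, separation of the sex mean shapes, shape
#' noise), the covariate model (age, BMI), the standardized path model
#' (mediator slopes, mediator residual correlation, outcome slopes,
#' outcome residual correlation), the raw-scale anchors used to dress
#' standardized variables in realistic units, and the rating model.
#'
#' @param mediators character vector of mediator names.  Recognised names
#'   with raw-scale counterparts: `L`, `a`, `b`, `colour`, `fwhr`, `sshd`,
#'   `dist`; other names (e.g. `shape_dominance`) stay latent-only.
#' @param mediator_slopes 2 x q matrix, rows age and BMI, standardized.
#' @param mediator_residual_corr q x q positive-definite correlation matrix.
#' @param outcome_slopes (2+q) x 2 matrix, rows (age, bmi, mediators),
#'   columns (sex-typicality, dominance), standardized.
#' @param outcome_residual_corr scalar in (-1, 1).
#' @param bmi_on_age_slope standardized age -> BMI slope.
#' @param sshd_separation distance between sex mean shapes along the
#'   dimorphism axis (Procrustes units).
#' @param sshd_within_sd within-sex SD of the latent shape position along
#'   the axis.
#' @param idiosyncratic_sd per-coordinate shape noise SD.
#' @param dist_gain relative modulation of the shape-noise SD by the
#'   standardized `dist` mediator (links measured distinctiveness to the
#'   generative variable).
#' @param curve_jitter_sd tangential digitising jitter SD on semi-landmarks.
#' @param colour_mode `"channels"` or `"factor"` (single latent factor
#'   driving the three channels).
#' @param colour_factor_loadings 3-vector of loadings (L*, a*, b*) used in
#'   factor mode.
#' @param anchors named list of `c(mean, sd)` raw-scale anchors for
#'   `age`, `bmi`, `L`, `a`, `b`, `fwhr`, `sextypicality`, `dominance`.
#' @param opposite_anchors anchors for the non-focal sex (landmarks and
#'   covariates only; no ratings are generated for it).
#' @param focal_sex `"female"` or `"male"`.
#' @param n_raters raters per rating matrix (>= 2).
#' @param rater_noise_sd residual rater noise SD (rating-scale units).
#' @param rater_effect_sd SD of rater main effects (default 0: the rating
#'   model is residual-noise-only).
#' @param template a [face_template()].
#' @param axis dimorphism axis (unit 144-vector).
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(mediators = c("L", "a", "b", "fwhr", "sshd", "dist"),
                         mediator_slopes = NULL,
                         mediator_residual_corr = NULL,
                         outcome_slopes = NULL,
                         outcome_residual_corr = 0.4,
                         bmi_on_age_slope = 0.2,
                         sshd_separation = 0.04,
                         sshd_within_sd = 0.015,
                         idiosyncratic_sd = 0.0045,
                         dist_gain = 0.25,
                         curve_jitter_sd = 0.003,
                         colour_mode = c("channels", "factor"),
                         colour_factor_loadings = c(0.75, 0.95, 0.95),
                         anchors = NULL, opposite_anchors = NULL,
                         focal_sex = c("female", "male"),
                         n_raters = 100L, rater_noise_sd = 1.0,
                         rater_effect_sd = 0,
                         template = face_template(),
                         axis = NULL) {
  colour_mode <- match.arg(colour_mode)
  focal_sex <- match.arg(focal_sex)
  q <- length(mediators)
  if (is.null(mediator_slopes)) {
    mediator_slopes <- matrix(0.1, 2, q,
                              dimnames = list(c("age", "bmi"), mediators))
  }
  if (is.null(mediator_residual_corr)) {
    mediator_residual_corr <- diag(q) * 0.9 + 0.1
  }
  if (is.null(outcome_slopes)) {
    outcome_slopes <- matrix(0.15, 2 + q, 2,
                             dimnames = list(c("age", "bmi", mediators),
                                             c("sextypicality", "dominance")))
  }
  default_anchors <- list(age = c(23, 4), bmi = c(22, 3), L = c(60, 3.5),
                          a = c(18, 2.5), b = c(13, 2), fwhr = c(1.9, 0.12),
                          sextypicality = c(4.0, 0.8), dominance = c(3.9, 0.65))
  if (is.null(anchors)) anchors <- default_anchors
  anchors <- utils::modifyList(default_anchors, anchors)
  if (is.null(opposite_anchors)) opposite_anchors <- anchors
  opposite_anchors <- utils::modifyList(anchors, opposite_anchors)
  if (is.null(axis)) axis <- dimorphism_axis(template)

  check_corr <- function(R, what) {
    if (!isSymmetric(unname(R), tol = 1e-8)) {
      stop(what, " must be symmetric")
    }
    if (any(abs(diag(R) - 1) > 1e-12)) stop(what, " must have unit diagonal")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop(what, " is not positive definite (min eigenvalue ",
           format(min(ev)), ")")
    }
  }
  check_corr(mediator_residual_corr, "mediator_residual_corr")
  if (abs(outcome_residual_corr) >= 1) {
    stop("outcome_residual_corr must lie in (-1, 1)")
  }
  stopifnot(sshd_within_sd >= 0, idiosyncratic_sd >= 0, curve_jitter_sd >= 0,
            rater_noise_sd >= 0, rater_effect_sd >= 0, n_raters >= 2,
            abs(sum(axis^2) - 1) < 1e-8,
            nrow(mediator_slopes) == 2, ncol(mediator_slopes) == q,
            nrow(outcome_slopes) == 2 + q, ncol(outcome_slopes) == 2)
  if (colour_mode == "factor" && !("colour" %in% mediators)) {
    stop("factor colour_mode requires a 'colour' mediator")
  }
  structure(list(mediators = mediators, mediator_slopes = mediator_slopes,
                 mediator_residual_corr = mediator_residual_corr,
                 outcome_slopes = outcome_slopes,
                 outcome_residual_corr = outcome_residual_corr,
                 bmi_on_age_slope = bmi_on_age_slope,
                 sshd_separation = sshd_separation,
                 sshd_within_sd = sshd_within_sd,
                 idiosyncratic_sd = idiosyncratic_sd,
                 dist_gain = dist_gain,
                 curve_jitter_sd = curve_jitter_sd,
                 colour_mode = colour_mode,
                 colour_factor_loadings = colour_factor_loadings,
                 anchors = anchors, opposite_anchors = opposite_anchors,
                 focal_sex = focal_sex, n_raters = as.integer(n_raters),
                 rater_noise_sd = rater_noise_sd,
                 rater_effect_sd = rater_effect_sd,
                 template = template, axis = axis),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic-study ground truth: focal", x$focal_sex, "sample,",
      length(x$mediators), "mediators (", paste(x$mediators, collapse = ", "),
      "),", x$colour_mode, "colour mode\n")
  invisible(x)
}

## implied covariance matrix of (age, bmi, mediators) when every variable
## has unit total variance; also returns the residual sds that achieve it
implied_predictor_cov <- function(truth) {
  q <- length(truth$mediators)
  rho <- truth$bmi_on_age_slope
  C_ab <- matrix(c(1, rho, rho, 1), 2, 2)
  B <- truth$mediator_slopes                       # 2 x q
  ve <- colSums(B * (C_ab %*% B))                  # explained variance per mediator
  if (any(ve >= 0.95)) {
    stop("mediator slopes explain >= 95% variance; cannot scale to unit total")
  }
  res_sd <- sqrt(1 - ve)
  S_res <- diag(res_sd, q) %*% truth$mediator_residual_corr %*% diag(res_sd, q)
  C_am <- C_ab %*% B                               # cov((age,bmi), M)
  C_mm <- t(B) %*% C_ab %*% B + S_res
  C <- rbind(cbind(C_ab, C_am), cbind(t(C_am), C_mm))
  dimnames(C) <- rep(list(c("age", "bmi", truth$mediators)), 2)
  list(cov = C, mediator_residual_sd = res_sd)
}

#' Generate standardized path-model data
#'
#' Draws n specimens directly from the ground truth's standardized linear
#' path model: age ~ N(0,1); BMI from age; mediators from (age, BMI) with
#' the specified residual correlation; the two latent outcomes from all
#' predictors with the specified residual correlation.  Residual SDs are
#' chosen so every variable has unit total variance, keeping "standardized
#' slope" meaningful.  This is the generator used to validate the sampler
#' itself (no landmarks, no raters).
#'
#' @param truth a [ground_truth()].
#' @param n number of specimens.
#' @param seed RNG seed (optional; inherits the ambient stream if NULL).
#' @return data.frame with columns `age`, `bmi`, the mediators,
#'   `sextypicality`, `dominance` (all standardized scales).
#' @export
simulate_path_data <- function(truth, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- length(truth$mediators)
  ipc <- implied_predictor_cov(truth)
  age <- stats::rnorm(n)
  rho <- truth$bmi_on_age_slope
  bmi_v <- rho * age + stats::rnorm(n, 0, sqrt(max(1 - rho^2, 1e-12)))
  ch_m <- chol(truth$mediator_residual_corr)
  E <- (matrix(stats::rnorm(n * q), n, q) %*% ch_m) *
    rep(ipc$mediator_residual_sd, each = n)
  M <- cbind(age, bmi_v) %*% truth$mediator_slopes + E
  X <- cbind(age, bmi = bmi_v, M)
  bo <- truth$outcome_slopes
  ve_o <- colSums(bo * (ipc$cov %*% bo))
  if (any(ve_o >= 0.95)) {
    stop("outcome slopes explain >= 95% variance; cannot scale to unit total")
  }
  sd_o <- sqrt(1 - ve_o)
  r <- truth$outcome_residual_corr
  Eo <- matrix(stats::rnorm(n * 2), n, 2) %*% chol(matrix(c(1, r, r, 1), 2, 2))
  Yl <- X %*% bo + Eo * rep(sd_o, each = n)
  out <- data.frame(age = age, bmi = bmi_v)
  for (j in seq_len(q)) out[[truth$mediators[j]]] <- M[, j]
  out$sextypicality <- Yl[, 1]
  out$dominance <- Yl[, 2]
  out
}

#' Generate raw landmark configurations
#'
#' Builds one configuration per latent shape position: template +
#' `latent * axis` + isotropic per-coordinate noise + tangential jitter on
#' semi-landmarks, then a random similarity transform (rotation uniform on
#' [0, 2pi), scale log-uniform on [0.5, 2], translation) so that the
#' superimposition step is genuinely exercised.
#'
#' @param truth a [ground_truth()].
#' @param sshd_latent numeric vector of per-specimen positions along the
#'   dimorphism axis (Procrustes units).
#' @param ids specimen identifiers.
#' @param noise_scale optional per-specimen multiplier on
#'   `idiosyncratic_sd` (used to tie measured distinctiveness to the
#'   generative `dist` variable).
#' @param seed RNG seed (optional).
#' @return List of [landmark_config()] objects in raw digitising space.
#' @export
simulate_landmarks <- function(truth, sshd_latent, ids = NULL,
                               noise_scale = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tmpl <- truth$template
  pts0 <- tmpl$points
  if (centroid_size(pts0) <= .Machine$double.eps) {
    stop("zero-area template")
  }
  k <- nrow(pts0)
  n <- length(sshd_latent)
  if (is.null(ids)) ids <- sprintf("spec%03d", seq_len(n))
  if (is.null(noise_scale)) noise_scale <- rep(1, n)
  semi <- which(tmpl$scheme$role == "semi")
  # template-curve tangents for jitter
  tang <- matrix(0, length(semi), 2)
  for (s in seq_along(semi)) {
    j <- semi[s]; cid <- tmpl$scheme$curve_id[j]
    prev <- if (j > 1 && tmpl$scheme$curve_id[j - 1] == cid) j - 1L else j
    nxt <- if (j < k && tmpl$scheme$curve_id[j + 1] == cid) j + 1L else j
    v <- pts0[nxt, ] - pts0[prev, ]
    tang[s, ] <- v / sqrt(sum(v^2))
  }
  lapply(seq_len(n), function(i) {
    shape <- pts0 + matrix(sshd_latent[i] * truth$axis, k, 2)
    shape <- shape + matrix(stats::rnorm(2 * k, 0,
                                         truth$idiosyncratic_sd * noise_scale[i]),
                            k, 2)
    if (truth$curve_jitter_sd > 0) {
      shape[semi, ] <- shape[semi, ] +
        tang * stats::rnorm(length(semi), 0, truth$curve_jitter_sd)
    }
    theta <- stats::runif(1, 0, 2 * pi)
    sc <- exp(stats::runif(1, log(0.5), log(2)))
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    shape <- sc * (shape %*% R) +
      matrix(stats::runif(2, -2, 2), k, 2, byrow = TRUE)
    landmark_config(shape, id = ids[i])
  })
}

#' Generate a complete synthetic study
#'
#' Produces everything the analysis pipeline ingests: raw TPS-style
#' landmark configurations for both sexes, a specimen covariate table,
#' two rater-by-stimulus rating matrices (sex-typicality and dominance,
#' focal sex only), and the persisted ground-truth record with every
#' latent per-specimen value.
#'
#' The focal sample is generated from the standardized path model
#' ([simulate_path_data()]) and dressed in raw units via the anchors;
#' landmarks place each specimen at `sex centre + sshd_within_sd * z_sshd`
#' along the dimorphism axis (female centre at -separation/2, male at
#' +separation/2).  Per-rater ratings are the latent rating (anchor mean +
#' anchor SD * latent outcome) plus rater noise, rounded and clamped to
#' the 1--7 scale.
#'
#' @param truth a [ground_truth()].
#' @param n_per_sex specimens per sex: one number or `c(focal, opposite)`.
#' @param seed integer seed; identical seeds give byte-identical studies.
#' @return Object of class `synthetic_study`: list with `landmarks`,
#'   `scheme`, `specimens`, `ratings_sextypicality`, `ratings_dominance`,
#'   `truth` (the input), `latent` (per-specimen generative record) and
#'   `focal_ids`.
#' @export
simulate_study <- function(truth, n_per_sex, seed = 1L) {
  set.seed(seed)
  n_per_sex <- rep(as.integer(n_per_sex), length.out = 2L)
  nf <- n_per_sex[1]; no <- n_per_sex[2]
  if (nf < 3L || no < 3L) stop("need n_per_sex >= 3")
  fs <- truth$focal_sex
  os <- if (fs == "female") "male" else "female"
  sex_centre <- function(s) {
    if (s == "male") truth$sshd_separation / 2 else -truth$sshd_separation / 2
  }
  focal_ids <- sprintf("%s%03d", substr(fs, 1, 1), seq_len(nf))
  opp_ids <- sprintf("%s%03d", substr(os, 1, 1), seq_len(no))

  # --- focal sample: standardized path-model draw
  pd <- simulate_path_data(truth, nf)
  # --- raw covariates via anchors
  an <- truth$anchors
  raw <- data.frame(id = focal_ids, sex = fs,
                    age = an$age[1] + an$age[2] * pd$age,
                    stringsAsFactors = FALSE)
  bmi_raw <- an$bmi[1] + an$bmi[2] * pd$bmi
  height_m <- stats::rnorm(nf, if (fs == "female") 1.67 else 1.79, 0.06)
  raw$weight <- round(bmi_raw * height_m^2, 1)
  raw$height <- round(height_m, 3)
  if (truth$colour_mode == "factor") {
    lo <- truth$colour_factor_loadings
    chan_z <- sapply(1:3, function(j) {
      lo[j] * pd$colour + stats::rnorm(nf, 0, sqrt(max(1 - lo[j]^2, 1e-12)))
    })
  } else {
    chan_z <- as.matrix(pd[, c("L", "a", "b")])
  }
  raw$L <- an$L[1] + an$L[2] * chan_z[, 1]
  raw$a <- an$a[1] + an$a[2] * chan_z[, 2]
  raw$b <- an$b[1] + an$b[2] * chan_z[, 3]
  fwhr_raw <- an$fwhr[1] + an$fwhr[2] * pd$fwhr
  fh <- stats::rnorm(nf, 260, 15)                  # facial height, px
  fw <- fwhr_raw * fh
  raw$width1 <- round(fw + stats::rnorm(nf, 0, 1.5), 2)
  raw$width2 <- round(fw + stats::rnorm(nf, 0, 1.5), 2)
  raw$height1 <- round(fh + stats::rnorm(nf, 0, 1.0), 2)
  raw$height2 <- round(fh + stats::rnorm(nf, 0, 1.0), 2)

  # --- opposite sample covariates (anchors only; no ratings)
  ano <- truth$opposite_anchors
  opp_age_z <- stats::rnorm(no)
  opp_bmi_z <- truth$bmi_on_age_slope * opp_age_z +
    stats::rnorm(no, 0, sqrt(max(1 - truth$bmi_on_age_slope^2, 1e-12)))
  opp_height <- stats::rnorm(no, if (os == "female") 1.67 else 1.79, 0.06)
  opp_fh <- stats::rnorm(no, 260, 15)
  opp_fwhr <- ano$fwhr[1] + ano$fwhr[2] * stats::rnorm(no)
  opp <- data.frame(id = opp_ids, sex = os,
                    age = ano$age[1] + ano$age[2] * opp_age_z,
                    weight = round((ano$bmi[1] + ano$bmi[2] * opp_bmi_z) *
                                     opp_height^2, 1),
                    height = round(opp_height, 3),
                    L = ano$L[1] + ano$L[2] * stats::rnorm(no),
                    a = ano$a[1] + ano$a[2] * stats::rnorm(no),
                    b = ano$b[1] + ano$b[2] * stats::rnorm(no),
                    stringsAsFactors = FALSE)
  opp$width1 <- round(opp_fwhr * opp_fh + stats::rnorm(no, 0, 1.5), 2)
  opp$width2 <- round(opp_fwhr * opp_fh + stats::rnorm(no, 0, 1.5), 2)
  opp$height1 <- round(opp_fh + stats::rnorm(no, 0, 1.0), 2)
  opp$height2 <- round(opp_fh + stats::rnorm(no, 0, 1.0), 2)

  specimens <- rbind(raw, opp)
  specimens$age <- round(specimens$age, 2)
  for (cl in c("L", "a", "b")) specimens[[cl]] <- round(specimens[[cl]], 2)

  # --- landmarks (both sexes)
  sshd_lat_f <- sex_centre(fs) + truth$sshd_within_sd * pd$sshd
  sshd_lat_o <- sex_centre(os) + truth$sshd_within_sd * stats::rnorm(no)
  nsc_f <- pmax(1 + truth$dist_gain * pd$dist, 0.2)
  landmarks <- c(
    simulate_landmarks(truth, sshd_lat_f, ids = focal_ids, noise_scale = nsc_f),
    simulate_landmarks(truth, sshd_lat_o, ids = opp_ids))

  # --- ratings (focal stimuli only)
  make_ratings <- function(latent_z, anchor) {
    lat <- anchor[1] + anchor[2] * latent_z
    k <- truth$n_raters
    re <- stats::rnorm(k, 0, truth$rater_effect_sd)
    m <- matrix(0, k, nf, dimnames = list(sprintf("R%03d", seq_len(k)),
                                          focal_ids))
    for (r in seq_len(k)) {
      v <- lat + re[r] + stats::rnorm(nf, 0, truth$rater_noise_sd)
      m[r, ] <- pmin(pmax(round(v), 1), 7)
    }
    rating_matrix(m)
  }
  ratings_st <- make_ratings(pd$sextypicality, an$sextypicality)
  ratings_do <- make_ratings(pd$dominance, an$dominance)

  latent <- cbind(id = focal_ids, pd, sshd_latent = sshd_lat_f)
  structure(list(landmarks = landmarks, scheme = truth$template$scheme,
                 specimens = specimens,
                 ratings_sextypicality = ratings_st,
                 ratings_dominance = ratings_do,
                 truth = truth, latent = latent,
                 focal_ids = focal_ids, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", nrow(x$specimens), "specimens (",
      length(x$focal_ids), "focal", x$truth$focal_sex, "),",
      x$truth$n_raters, "raters per scale; seed", x$seed, "\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the complete plain-text bundle: `landmarks.tps`, `scheme.txt`,
#' `specimens.csv`, `ratings_sextypicality.csv`, `ratings_dominance.csv`
#' and a structured `truth.txt` record (generative parameters and the
#' per-specimen latent values).  Byte-identical for identical seeds.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tps(study$landmarks, file.path(dir, "landmarks.tps"))
  write_scheme(study$scheme, file.path(dir, "scheme.txt"))
  write_specimen_table(study$specimens, file.path(dir, "specimens.csv"))
  write_ratings(study$ratings_sextypicality,
                file.path(dir, "ratings_sextypicality.csv"))
  write_ratings(study$ratings_dominance,
                file.path(dir, "ratings_dominance.csv"))
  tr <- study$truth
  con <- file(file.path(dir, "truth.txt"), "w")
  writeLines(c(
    sprintf("focal_sex=%s", tr$focal_sex),
    sprintf("colour_mode=%s", tr$colour_mode),
    sprintf("mediators=%s", paste(tr$mediators, collapse = ",")),
    sprintf("outcome_residual_corr=%.17g", tr$outcome_residual_corr),
    sprintf("sshd_separation=%.17g", tr$sshd_separation),
    sprintf("seed=%d", study$seed),
    "latent:"), con)
  close(con)
  suppressWarnings(utils::write.table(
    study$latent, file.path(dir, "truth.txt"), sep = ",", append = TRUE,
    row.names = FALSE, quote = FALSE))
  invisible(dir)
}

#' Calibrated study presets
#'
#' Ground truths calibrated once to the published study conditions of the
#' four samples (Czech/Cameroonian x women/men): sample moments of age,
#' BMI, fWHR, CIELab channels, SShD and perceived scales, the reported
#' outcome residual correlations, the reported non-zero outcome slopes,
#' and the channel regime (heavily collinear single-factor colour for the
#' Cameroonian samples, separate channels for the Czech samples).
#'
#' @param name one of `"czech_women"`, `"czech_men"`, `"cmr_women"`,
#'   `"cmr_men"`.
#' @param extended add the two shape-trait mediators (`shape_dominance`,
#'   `shape_sextypicality`) with their reported residual correlations.
#' @return A [ground_truth()]; attribute `"n_default"` carries the
#'   published per-sex sample sizes `c(focal, opposite)`.
#' @export
study_preset <- function(name = c("czech_women", "czech_men",
                                  "cmr_women", "cmr_men"),
                         extended = FALSE) {
  name <- match.arg(name)
  cz <- grepl("czech", name)
  fem <- grepl("women", name)
  # Table-1-style anchors per sample
  A <- list(
    czech_women = list(age = c(23.09, 4.12), bmi = c(21.80, 2.89),
                       fwhr = c(1.93, 0.12), L = c(61.38, 3.46),
                       a = c(17.39, 2.50), b = c(13.12, 2.14),
                       sextypicality = c(4.00, 0.84), dominance = c(3.81, 0.66)),
    czech_men = list(age = c(23.38, 4.25), bmi = c(22.99, 2.36),
                     fwhr = c(1.88, 0.11), L = c(58.77, 2.74),
                     a = c(19.15, 2.66), b = c(13.72, 1.57),
                     sextypicality = c(4.17, 0.85), dominance = c(3.94, 0.71)),
    cmr_women = list(age = c(21.24, 1.89), bmi = c(24.30, 4.17),
                     fwhr = c(2.16, 0.17), L = c(38.36, 6.45),
                     a = c(21.09, 3.18), b = c(18.13, 4.45),
                     sextypicality = c(4.88, 0.58), dominance = c(3.90, 0.49)),
    cmr_men = list(age = c(22.00, 2.24), bmi = c(23.15, 2.33),
                   fwhr = c(2.09, 0.17), L = c(32.91, 6.24),
                   a = c(17.44, 3.41), b = c(13.33, 4.33),
                   sextypicality = c(5.62, 0.57), dominance = c(4.11, 0.51)))
  ns <- list(czech_women = c(106L, 89L), czech_men = c(89L, 106L),
             cmr_women = c(50L, 49L), cmr_men = c(49L, 50L))
  opp_name <- c(czech_women = "czech_men", czech_men = "czech_women",
                cmr_women = "cmr_men", cmr_men = "cmr_women")[name]
  colour_mode <- if (cz) "channels" else "factor"
  med <- if (cz) c("L", "a", "b", "fwhr", "sshd", "dist")
         else c("colour", "fwhr", "sshd", "dist")
  q <- length(med)
  # age/BMI -> mediator slopes: weak, realistic defaults
  ms <- matrix(0, 2, q, dimnames = list(c("age", "bmi"), med))
  ms["bmi", "fwhr"] <- 0.35
  ms["age", "sshd"] <- 0.10
  ms["bmi", "sshd"] <- 0.10
  ms["age", "dist"] <- 0.15
  if (cz) { ms["age", "L"] <- -0.15; ms["bmi", "a"] <- 0.15 }
  else ms["age", "colour"] <- -0.15
  # mediator residual correlations: modest, plus channel collinearity for CZ
  mc <- diag(q)
  rownames(mc) <- colnames(mc) <- med
  if (cz) {
    mc["L", "a"] <- mc["a", "L"] <- -0.45
    mc["L", "b"] <- mc["b", "L"] <- 0.25
    mc["a", "b"] <- mc["b", "a"] <- 0.35
  }
  mc["sshd", "dist"] <- mc["dist", "sshd"] <- 0.15
  # outcome slopes: reported non-zero coefficients per sample
  os <- matrix(0, 2 + q, 2,
               dimnames = list(c("age", "bmi", med),
                               c("sextypicality", "dominance")))
  rr <- switch(name,
    czech_women = { os["sshd", "sextypicality"] <- -0.24
                    os["dist", "sextypicality"] <- -0.26
                    os["age", "dominance"] <- 0.30
                    0.31 },
    czech_men = { os["age", "sextypicality"] <- 0.24
                  os["age", "dominance"] <- 0.23
                  os["bmi", "dominance"] <- 0.30
                  os["b", "sextypicality"] <- 0.18
                  os["b", "dominance"] <- 0.16
                  os["sshd", "sextypicality"] <- 0.15
                  os["sshd", "dominance"] <- 0.08
                  0.77 },
    cmr_women = { os["colour", "sextypicality"] <- 0.52
                  os["sshd", "sextypicality"] <- -0.08
                  os["sshd", "dominance"] <- 0.24
                  os["bmi", "dominance"] <- 0.24
                  -0.24 },
    cmr_men = { os["colour", "sextypicality"] <- -0.29
                os["sshd", "sextypicality"] <- 0.29
                os["sshd", "dominance"] <- 0.29
                os["age", "sextypicality"] <- 0.31
                0.42 })
  loadings <- if (fem) c(sqrt(0.77), sqrt(0.90), sqrt(0.999))
              else c(sqrt(0.55), sqrt(0.999), sqrt(0.97))
  truth_args <- list(
    mediators = med, mediator_slopes = ms, mediator_residual_corr = mc,
    outcome_slopes = os, outcome_residual_corr = rr,
    bmi_on_age_slope = 0.2,
    sshd_separation = if (cz) 0.04 else 0.02,
    colour_mode = colour_mode, colour_factor_loadings = loadings,
    anchors = A[[name]], opposite_anchors = A[[opp_name]],
    focal_sex = if (fem) "female" else "male")
  if (extended) {
    med2 <- c(med, "shape_dominance", "shape_sextypicality")
    q2 <- length(med2)
    ms2 <- cbind(ms, shape_dominance = c(0.05, 0.05),
                 shape_sextypicality = c(0.05, 0.05))
    mc2 <- diag(q2); rownames(mc2) <- colnames(mc2) <- med2
    mc2[rownames(mc), colnames(mc)] <- mc
    # reported residual correlations among the shape-derived predictors
    shp <- switch(name,
      czech_women = c(sshd_shdom = 0.0, sshd_shst = -0.87, shdom_shst = 0.14),
      czech_men = c(sshd_shdom = 0.30, sshd_shst = 0.41, shdom_shst = 0.58),
      cmr_women = c(sshd_shdom = 0.20, sshd_shst = 0.34, shdom_shst = 0.47),
      cmr_men = c(sshd_shdom = 0.40, sshd_shst = 0.69, shdom_shst = 0.58))
    mc2["sshd", "shape_dominance"] <- mc2["shape_dominance", "sshd"] <- shp[1]
    mc2["sshd", "shape_sextypicality"] <-
      mc2["shape_sextypicality", "sshd"] <- shp[2]
    mc2["shape_dominance", "shape_sextypicality"] <-
      mc2["shape_sextypicality", "shape_dominance"] <- shp[3]
    os2 <- rbind(os, shape_dominance = c(0.05, 0.30),
                 shape_sextypicality = c(0.30, 0.05))
    truth_args$mediators <- med2
    truth_args$mediator_slopes <- ms2
    truth_args$mediator_residual_corr <- mc2
    truth_args$outcome_slopes <- os2
  }
  out <- do.call(ground_truth, truth_args)
  attr(out, "n_default") <- ns[[name]]
  attr(out, "preset") <- name
  out
}
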