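#' Variance inflation factor
#'
#' `1 / (1 - R^2)` where `R^2` comes from the ordinary least-squares
#' regression of the target predictor on the remaining predictors.  A
#' collinearity diagnostic: the usual rule of thumb treats VIF > 5 with
#' caution.
#'
#' @param predictors data frame or matrix of predictors (n > number of
#'   predictors, >= 2 columns).
#' @param target column name (or index) of the predictor under scrutiny.
#' @return Scalar >= 1; `Inf` with a warning under perfect collinearity.
#' @export
vif <- function(predictors, target) {
  X <- as.data.frame(predictors)
  if (ncol(X) < 2L) stop("VIF needs >= 2 predictors")
  if (nrow(X) <= ncol(X)) stop("need n > number of predictors")
  if (is.numeric(target)) target <- names(X)[target]
  if (!target %in% names(X)) stop("unknown predictor: ", target)
  y <- X[[target]]
  Z <- X[setdiff(names(X), target)]
  fit <- stats::lm(y ~ ., data = Z)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  if (r2 >= 1 - 1e-12) {
    warning("perfect collinearity: VIF is infinite for ", target)
    return(Inf)
  }
  1 / (1 - r2)
}

#' All VIFs of a predictor set
#' @rdname vif
#' @export
vif_table <- function(predictors) {
  X <- as.data.frame(predictors)
  vapply(names(X), function(v) vif(X, v), numeric(1))
}

#' Run the full analysis pipeline on a study
#'
#' Executes every stage in order on a synthetic study or a directory of
#' study files: landmark ingestion, pooled two-sex Procrustes
#' superimposition with sliding semi-landmarks, shape scores (SShD, DIST,
#' shape-trait scores for the extended variant), the fWHR repeatability
#' gate, interrater reliability and rating means, the colour-mode decision
#' (parallel analysis + collinearity rule), within-sample standardization,
#' the Bayesian path-model fit on the focal sample, posterior summaries
#' and (optionally) figure files.  Any stage failure aborts with a
#' stage-named diagnostic.
#'
#' @param study a [simulate_study()] result, or a directory path written
#'   by [write_study()].
#' @param focal_sex sex of the rated sample (`"female"`/`"male"`;
#'   defaults to the study's own record, or `"female"` for directories
#'   without one).
#' @param variant model variant, see [path_model_spec()].
#' @param n_draws,chains,warmup passed to [fit_path_model()].
#' @param seed RNG seed governing every stochastic stage.
#' @param slide slide semi-landmarks during GPA.
#' @param out optional output directory for tables, figures and the run
#'   report.
#' @return Object of class `facepath_pipeline`: list with `fit`,
#'   `summary`, `aligned`, `scores`, `model_data`, `icc`, `colour_mode`,
#'   `vif`, `stages` (per-stage log) and `seed`.
#' @export
run_pipeline <- function(study, focal_sex = NULL, variant = "default",
                         n_draws = 2000L, chains = 2L, warmup = NULL,
                         seed = 1L, slide = TRUE, out = NULL) {
  stages <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_stage <- function(msg) stages <<- c(stages, msg)

  # --- ingest
  if (is.character(study)) {
    dirn <- study
    study <- stage("ingest", list(
      landmarks = read_tps(file.path(dirn, "landmarks.tps")),
      scheme = read_scheme(file.path(dirn, "scheme.txt")),
      specimens = read_specimen_table(file.path(dirn, "specimens.csv")),
      ratings_sextypicality =
        read_ratings(file.path(dirn, "ratings_sextypicality.csv")),
      ratings_dominance =
        read_ratings(file.path(dirn, "ratings_dominance.csv"))))
    log_stage(paste("ingest: read study from", dirn))
  }
  spec_tab <- study$specimens
  if (is.null(focal_sex)) {
    focal_sex <- if (!is.null(study$truth)) study$truth$focal_sex else "female"
  }

  # --- superimposition (pooled two-sex)
  aligned <- stage("gpa", gpa(study$landmarks, scheme = study$scheme,
                              slide = slide))
  log_stage(sprintf("gpa: %d configurations, %d iterations, %s",
                    dim(aligned$aligned)[1], aligned$iterations,
                    if (aligned$converged) "converged" else "not converged"))

  # --- ratings (needed before shape-trait scores)
  icc <- stage("reliability", c(
    sextypicality = icc_3k(study$ratings_sextypicality),
    dominance = icc_3k(study$ratings_dominance)))
  mr_st <- mean_ratings(study$ratings_sextypicality)
  mr_do <- mean_ratings(study$ratings_dominance)
  log_stage(sprintf("reliability: ICC(3,k) sextypicality %.3f, dominance %.3f",
                    icc[1], icc[2]))

  # --- shape scores
  sex <- spec_tab$sex[match(aligned$ids, spec_tab$id)]
  traits <- NULL
  if (variant != "default") {
    tr_st <- tr_do <- rep(NA_real_, length(aligned$ids))
    idx <- match(names(mr_st), aligned$ids)
    tr_st[idx] <- as.vector(scale(mr_st))
    tr_do[match(names(mr_do), aligned$ids)] <- as.vector(scale(mr_do))
    traits <- list(sextypicality = tr_st, dominance = tr_do)
  }
  scores <- stage("scores", shape_score_table(aligned, sex, traits))
  log_stage(sprintf("scores: SShD sex means %.4f (female) / %.4f (male)",
                    mean(scores$sshd[sex == "female"]),
                    mean(scores$sshd[sex == "male"])))

  # --- focal specimen table with measurements
  focal <- spec_tab[spec_tab$sex == focal_sex, , drop = FALSE]
  fw <- stage("fwhr_gate",
              repeatability_gate(focal$width1, focal$width2))
  fh <- stage("fwhr_gate",
              repeatability_gate(focal$height1, focal$height2))
  focal$fwhr <- fwhr(fw, fh)
  if (!("bmi" %in% names(focal))) focal$bmi <- bmi(focal$weight, focal$height)
  focal <- merge(focal, scores, by = "id", sort = FALSE)
  focal$sextypicality <- mr_st[focal$id]
  focal$dominance <- mr_do[focal$id]
  focal <- focal[!is.na(focal$sextypicality) & !is.na(focal$dominance), ,
                 drop = FALSE]

  # --- colour decision
  chan <- as.matrix(focal[, c("L", "a", "b")])
  cmode <- stage("colour", choose_colour_mode(chan, seed = seed))
  if (cmode == "factor") {
    fa <- extract_colour_factor(chan)
    focal$colour <- fa$scores
    log_stage(sprintf(
      "colour: single factor retained (r2 = %.3f/%.3f/%.3f), 'colour' variable created",
      fa$r2[1], fa$r2[2], fa$r2[3]))
  } else {
    log_stage("colour: channels kept separate (no dominant single factor)")
  }

  # --- model data (standardized within the focal sample)
  med <- mediator_names(variant, as.character(cmode))
  model_vars <- c("age", "bmi", med, "sextypicality", "dominance")
  missing_vars <- setdiff(model_vars, names(focal))
  if (length(missing_vars) > 0) {
    stop("pipeline stage 'standardize' failed: focal table lacks ",
         paste(missing_vars, collapse = ", "))
  }
  model_data <- stage("standardize",
                      standardize(focal[, model_vars, drop = FALSE]))
  vifs <- stage("vif", vif_table(model_data[, med, drop = FALSE]))

  # --- fit
  fit <- stage("fit", fit_path_model(model_data, variant = variant,
                                     colour_mode = as.character(cmode),
                                     n_draws = n_draws, chains = chains,
                                     warmup = warmup, seed = seed,
                                     standardize = FALSE))
  log_stage(sprintf("fit: %s variant, %d draws, %s", variant, nrow(fit$draws),
                    if (fit$converged) "converged" else "NOT converged"))
  summ <- summary(fit)

  run <- structure(list(fit = fit, summary = summ, aligned = aligned,
                        scores = scores, model_data = model_data,
                        focal_table = focal, icc = icc,
                        colour_mode = as.character(cmode), vif = vifs,
                        stages = stages, focal_sex = focal_sex,
                        variant = variant, seed = seed),
                   class = "facepath_pipeline")
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(summ, file.path(out, "posterior_summary.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    utils::write.table(scores, file.path(out, "shape_scores.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    write_draws(fit, file.path(out, "draws.csv"))
    forest_and_density_plots(fit, out)
    writeLines(c(sprintf("facepath pipeline run (seed %d)", seed), stages,
                 sprintf("vif: %s",
                         paste(sprintf("%s=%.2f", names(vifs), vifs),
                               collapse = " "))),
               file.path(out, "run_report.txt"))
  }
  run
}

#' @export
print.facepath_pipeline <- function(x, ...) {
  cat("facepath pipeline run (", x$variant, " variant, focal ", x$focal_sex,
      ", colour mode ", x$colour_mode, ")\n", sep = "")
  for (s in x$stages) cat("  -", s, "\n")
  invisible(x)
}
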