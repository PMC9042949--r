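#' Specify a layered path model
#'
#' The model is a directed three-layer system on standardized variables:
#' age is exogenous; BMI is regressed on age; a correlated block of
#' facial "mediators" (skin colour -- either the three CIELab channels or
#' one latent colour factor -- plus fWHR, SShD and DIST, optionally the
#' two shape-trait scores) is regressed on age and BMI with a joint
#' multivariate-normal residual; and the two perceived outcomes
#' (sex-typicality and dominance) are regressed on age, BMI and all
#' mediators with a bivariate-normal residual whose correlation captures
#' the non-directed outcome association.
#'
#' Priors: Normal(0, 0.2) intercepts, Normal(0, 0.5) slopes, LKJ(2) on
#' both residual correlation matrices, Exponential(1) on all residual
#' standard deviations.
#'
#' @param variant `"default"`, `"extended"` (adds shape dominance and
#'   shape sex-typicality to the mediator block), `"shape_dominance_only"`
#'   or `"shape_sextypicality_only"` (each adds exactly one).
#' @param colour_mode `"channels"` (L*, a*, b* enter separately) or
#'   `"factor"` (single latent colour score).
#' @param prior_intercept_sd,prior_slope_sd,lkj_eta,sd_rate prior
#'   hyperparameters.
#' @param n_draws posterior draws retained after warm-up.
#' @return An object of class `path_model_spec`.
#' @export
path_model_spec <- function(variant = c("default", "extended",
                                        "shape_dominance_only",
                                        "shape_sextypicality_only"),
                            colour_mode = c("channels", "factor"),
                            prior_intercept_sd = 0.2, prior_slope_sd = 0.5,
                            lkj_eta = 2, sd_rate = 1, n_draws = 10000L) {
  variant <- match.arg(variant)
  colour_mode <- match.arg(colour_mode)
  stopifnot(prior_intercept_sd > 0, prior_slope_sd > 0, lkj_eta > 0,
            sd_rate > 0, n_draws >= 1)
  structure(list(variant = variant, colour_mode = colour_mode,
                 prior_intercept_sd = prior_intercept_sd,
                 prior_slope_sd = prior_slope_sd,
                 lkj_eta = lkj_eta, sd_rate = sd_rate,
                 n_draws = as.integer(n_draws)),
            class = "path_model_spec")
}

#' @export
print.path_model_spec <- function(x, ...) {
  cat("Path model spec: variant =", x$variant, ", colour_mode =",
      x$colour_mode, "\n")
  invisible(x)
}

mediator_names <- function(variant, colour_mode) {
  base <- if (colour_mode == "channels") c("L", "a", "b") else "colour"
  base <- c(base, "fwhr", "sshd", "dist")
  switch(variant,
         default = base,
         extended = c(base, "shape_dominance", "shape_sextypicality"),
         shape_dominance_only = c(base, "shape_dominance"),
         shape_sextypicality_only = c(base, "shape_sextypicality"),
         stop("unknown variant: ", variant))
}

outcome_names <- function() c("sextypicality", "dominance")

#' Enumerate the parameters of a path model
#'
#' Produces the full parameter manifest implied by a [path_model_spec()]:
#' an intercept for every variable except age; one slope from age to BMI;
#' slopes from age and BMI to each mediator; slopes from age, BMI and
#' every mediator to each outcome; a residual SD per mediator plus a
#' correlation entry per mediator pair; and the two outcome residual SDs
#' with their single correlation.  The BMI equation's residual SD is
#' carried separately (`bmi_sd`) -- the likelihood needs it, but it sits
#' outside the mediator/outcome blocks whose counts characterise the
#' model structure.
#'
#' @param spec a [path_model_spec()] (or a variant name).
#' @param colour_mode used when `spec` is given as a variant name.
#' @return An object of class `path_manifest`: named character vectors of
#'   parameter names per category plus a `counts` list.
#' @export
build_model <- function(spec, colour_mode = "channels") {
  if (is.character(spec)) spec <- path_model_spec(spec, colour_mode)
  med <- mediator_names(spec$variant, spec$colour_mode)
  out <- outcome_names()
  q <- length(med)
  intercepts <- paste0("a_", c("bmi", med, out))
  slopes <- c("b_age_bmi",
              as.vector(t(outer(c("age", "bmi"), med,
                                function(p, m) paste0("b_", p, "_", m)))),
              as.vector(t(outer(c("age", "bmi", med), out,
                                function(p, o) paste0("b_", p, "_", o)))))
  med_pairs <- cpc_pairs(q)
  manifest <- list(
    variant = spec$variant, colour_mode = spec$colour_mode,
    mediators = med, outcomes = out,
    intercepts = intercepts,
    slopes = slopes,
    bmi_sd = "sigma_bmi",
    mediator_sds = paste0("sigma_", med),
    mediator_corrs = paste0("rho_", med[med_pairs[, 2]], "_",
                            med[med_pairs[, 1]]),
    outcome_sds = paste0("sigma_", out),
    outcome_corr = paste0("rho_", out[1], "_", out[2]),
    spec = spec)
  manifest$counts <- list(
    intercepts = length(intercepts),
    slopes = length(slopes),
    mediator_variances = as.integer(q),
    mediator_covariances = as.integer(q * (q - 1L) / 2L),
    outcome_variances = 2L,
    outcome_covariances = 1L)
  manifest$parameters <- c(manifest$intercepts, manifest$slopes,
                           manifest$bmi_sd, manifest$mediator_sds,
                           manifest$mediator_corrs, manifest$outcome_sds,
                           manifest$outcome_corr)
  if (anyDuplicated(manifest$parameters)) stop("duplicate parameter names")
  class(manifest) <- "path_manifest"
  manifest
}

#' @export
print.path_manifest <- function(x, ...) {
  cat("Path model parameter manifest (", x$variant, ", ", x$colour_mode,
      " colour mode)\n", sep = "")
  cat("  mediators:", paste(x$mediators, collapse = ", "), "\n")
  with(x$counts, cat(sprintf(
    "  %d intercepts, %d slopes, %d + %d mediator (co)variances, %d + %d outcome (co)variances\n",
    intercepts, slopes, mediator_variances, mediator_covariances,
    outcome_variances, outcome_covariances)))
  invisible(x)
}

#' Standardize variables within a sample
#'
#' Z-scores each requested column (optionally within groups, e.g. the
#' sex-by-population samples in which ratings were collected), recording
#' the centring/scaling constants so the transform can be inverted.
#'
#' @param table data frame.
#' @param variables columns to standardize (default: all numeric).
#' @param by optional grouping column name.
#' @return The table with standardized columns and a `"standardization"`
#'   attribute; invert with [unstandardize()].
#' @export
standardize <- function(table, variables = NULL, by = NULL) {
  if (is.null(variables)) {
    variables <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  groups <- if (is.null(by)) rep("all", nrow(table)) else as.character(table[[by]])
  params <- list()
  for (v in variables) {
    for (g in unique(groups)) {
      idx <- which(groups == g)
      mu <- mean(table[[v]][idx]); sdv <- stats::sd(table[[v]][idx])
      if (!is.finite(sdv) || sdv <= .Machine$double.eps) {
        stop("variable '", v, "' is constant within sample '", g,
             "'; cannot standardize")
      }
      table[[v]][idx] <- (table[[v]][idx] - mu) / sdv
      params[[paste(v, g, sep = "|")]] <- c(mean = mu, sd = sdv)
    }
  }
  attr(table, "standardization") <- list(params = params,
                                         variables = variables, by = by)
  table
}

#' @rdname standardize
#' @param ztable a table produced by [standardize()].
#' @export
unstandardize <- function(ztable) {
  st <- attr(ztable, "standardization")
  if (is.null(st)) stop("table carries no standardization attribute")
  groups <- if (is.null(st$by)) rep("all", nrow(ztable))
            else as.character(ztable[[st$by]])
  for (v in st$variables) {
    for (g in unique(groups)) {
      idx <- which(groups == g)
      p <- st$params[[paste(v, g, sep = "|")]]
      ztable[[v]][idx] <- ztable[[v]][idx] * p["sd"] + p["mean"]
    }
  }
  attr(ztable, "standardization") <- NULL
  ztable
}
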