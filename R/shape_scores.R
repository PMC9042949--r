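## Perception-relevant shape statistics computed from an aligned sample:
## sexual shape dimorphism (SShD), morphological distinctiveness (DIST) and
## per-face shape-trait regression scores.

flatten_aligned <- function(aligned) {
  n <- dim(aligned$aligned)[1]
  k <- dim(aligned$aligned)[2]
  out <- matrix(0, n, 2 * k)
  for (i in seq_len(n)) out[i, ] <- as.vector(aligned$aligned[i, , ])
  rownames(out) <- aligned$ids
  out
}

#' Sexual shape dimorphism scores
#'
#' Projects every configuration of a pooled two-sex aligned sample onto the
#' unit vector connecting the female and male mean shapes, centred at the
#' midpoint between the two means.  Lower values indicate more female-like
#' facial shape, higher values more male-like shape: a specimen exactly at
#' the male mean scores +half the inter-mean distance, one at the female
#' mean the negative of that.
#'
#' @param aligned an `aligned_sample` from [gpa()] run on the pooled
#'   two-sex sample.
#' @param sex character vector (`"male"`/`"female"`), one per specimen.
#' @return Named numeric vector of SShD scores (Procrustes units).
#' @export
sshd_scores <- function(aligned, sex) {
  X <- flatten_aligned(aligned)
  sex <- tolower(as.character(sex))
  if (length(sex) != nrow(X)) stop("`sex` length does not match sample size")
  if (!all(sex %in% c("male", "female"))) stop("sex must be male/female")
  if (sum(sex == "male") < 2L || sum(sex == "female") < 2L) {
    stop("both sexes need >= 2 specimens to define the dimorphism axis")
  }
  m <- colMeans(X[sex == "male", , drop = FALSE])
  f <- colMeans(X[sex == "female", , drop = FALSE])
  d <- m - f
  nd <- sqrt(sum(d^2))
  if (nd <= .Machine$double.eps) stop("sex mean shapes coincide; axis undefined")
  d <- d / nd
  mid <- (m + f) / 2
  scores <- drop(sweep(X, 2, mid) %*% d)
  names(scores) <- rownames(X)
  scores
}

#' Morphological distinctiveness (DIST)
#'
#' Procrustes distance of each aligned configuration from the sample
#' consensus; the larger the value, the less average the face.
#'
#' @param aligned an `aligned_sample`.
#' @return Named non-negative numeric vector.
#' @export
distinctiveness <- function(aligned) {
  X <- flatten_aligned(aligned)
  cvec <- as.vector(aligned$consensus)
  scores <- sqrt(rowSums(sweep(X, 2, cvec)^2))
  names(scores) <- rownames(X)
  scores
}

#' Per-face shape-trait regression scores
#'
#' Regresses every aligned coordinate on a perceived trait (one
#' least-squares slope per coordinate) and scores each face by the dot
#' product of its consensus-centred coordinates with the raw coefficient
#' vector.  The score is the shape-explained component of the trait:
#' separate calls produce "shape dominance" and "shape sex-typicality".
#' Scores are centred by construction (the consensus is the sample mean),
#' and the coefficient vector is deliberately left un-normalised, which
#' gives the characteristically small raw-unit score spread; all variables
#' are standardized before entering the path model, so the scaling washes
#' out downstream.
#'
#' @param aligned an `aligned_sample` (typically the per-sex subset in
#'   which the ratings were collected).
#' @param trait numeric vector of per-specimen standardized ratings.
#' @return Named numeric vector of scores (mean 0 within the sample).
#' @export
shape_trait_scores <- function(aligned, trait) {
  X <- flatten_aligned(aligned)
  if (length(trait) != nrow(X)) stop("`trait` length does not match sample size")
  if (any(!is.finite(trait))) stop("trait contains non-finite values")
  if (stats::sd(trait) <= .Machine$double.eps) {
    stop("trait is constant; regression undefined")
  }
  if (nrow(X) <= 2L) stop("need n > 2 specimens")
  Xc <- sweep(X, 2, as.vector(aligned$consensus))
  tc <- trait - mean(trait)
  b <- drop(crossprod(Xc, tc)) / sum(tc^2)   # per-coordinate LS slope
  scores <- drop(Xc %*% b)
  names(scores) <- rownames(X)
  scores
}

#' Score table for a sample
#'
#' Convenience wrapper assembling SShD, DIST and (optionally) shape-trait
#' scores into one data frame keyed by specimen id, mergeable into a
#' specimen table.
#'
#' @param aligned pooled two-sex `aligned_sample`.
#' @param sex per-specimen sex labels.
#' @param traits optional named list of per-specimen standardized ratings;
#'   each entry adds a `shape_<name>` column computed within sex.
#' @return data.frame with columns `id`, `sshd`, `dist` and one
#'   `shape_<name>` column per trait.
#' @export
shape_score_table <- function(aligned, sex, traits = NULL) {
  out <- data.frame(id = aligned$ids,
                    sshd = unname(sshd_scores(aligned, sex)),
                    dist = unname(distinctiveness(aligned)),
                    stringsAsFactors = FALSE)
  if (!is.null(traits)) {
    sex <- tolower(as.character(sex))
    for (nm in names(traits)) {
      col <- rep(NA_real_, nrow(out))
      tr <- traits[[nm]]
      for (s in unique(sex)) {
        idx <- which(sex == s)
        if (all(is.na(tr[idx]))) next
        sub <- subset_aligned(aligned, idx)
        col[idx] <- shape_trait_scores(sub, tr[idx])
      }
      out[[paste0("shape_", nm)]] <- col
    }
  }
  out
}

## restrict an aligned sample to a subset of specimens; the consensus is
## recomputed as the subset mean so trait scores stay centred
subset_aligned <- function(aligned, idx) {
  X <- aligned$aligned[idx, , , drop = FALSE]
  structure(list(aligned = X, consensus = apply(X, c(2, 3), mean),
                 centroid_sizes = aligned$centroid_sizes[idx],
                 iterations = aligned$iterations, converged = aligned$converged,
                 ids = aligned$ids[idx], slide = aligned$slide,
                 slide_criterion = aligned$slide_criterion,
                 objective = numeric(0)),
            class = "aligned_sample")
}
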