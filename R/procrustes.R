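## Generalized Procrustes superimposition with sliding semi-landmarks.
## Shapes are k x 2 coordinate matrices; the aligned frame uses centred,
## unit-centroid-size configurations (full Procrustes, no reflection).

centre_config <- function(X) sweep(X, 2, colMeans(X))

centroid_size <- function(X) {
  Xc <- centre_config(X)
  sqrt(sum(Xc^2))
}

#' Procrustes distance between two superimposed configurations
#'
#' Root summed squared coordinate difference.  Both configurations must
#' already live in a common aligned frame (same landmark count and
#' superimposition); no further fitting is done here.
#'
#' @param shape_a,shape_b k x 2 coordinate matrices.
#' @return Non-negative scalar; zero iff the shapes are identical.
#' @export
procrustes_distance <- function(shape_a, shape_b) {
  shape_a <- as.matrix(shape_a); shape_b <- as.matrix(shape_b)
  if (!all(dim(shape_a) == dim(shape_b))) {
    stop("frame mismatch: configurations have different dimensions")
  }
  sqrt(sum((shape_a - shape_b)^2))
}

## optimal rotation-only fit of unit-size centred target onto reference
## direction; returns 2x2 rotation with det +1 (reflection excluded)
optimal_rotation <- function(reference, target) {
  M <- crossprod(target, reference)          # 2 x 2
  sv <- svd(M)
  R <- sv$u %*% diag(c(1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  R
}

#' Ordinary (pairwise) Procrustes alignment
#'
#' Centres both configurations, scales them to unit centroid size, then
#' rotates the target (rotation only -- reflections are never allowed,
#' faces have a consistent orientation) to minimise the summed squared
#' distance to the reference.
#'
#' @param reference,target k x 2 coordinate matrices.
#' @return A list with `aligned` (the fitted target), `reference` (centred,
#'   unit-size), `rotation` (2 x 2), and `distance` (the minimised root
#'   summed squared distance).
#' @export
opa_align <- function(reference, target) {
  reference <- as.matrix(reference); target <- as.matrix(target)
  if (!all(dim(reference) == dim(target))) {
    stop("frame mismatch: configurations have different landmark counts")
  }
  sr <- centroid_size(reference); st <- centroid_size(target)
  if (sr <= .Machine$double.eps || st <= .Machine$double.eps) {
    stop("degenerate configuration: all points coincident")
  }
  A <- centre_config(reference) / sr
  B <- centre_config(target) / st
  R <- optimal_rotation(A, B)
  fitted <- B %*% R
  list(aligned = fitted, reference = A, rotation = R,
       distance = procrustes_distance(A, fitted))
}

## thin-plate-spline bending energy matrix of a 2-D reference (k x k)
bending_energy_matrix <- function(ref) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(d2 > 0, d2 * log(d2), 0)
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- solve(L)
  Li[seq_len(k), seq_len(k), drop = FALSE]
}

## slide semi-landmarks of one configuration toward the consensus.
## criterion "procrustes": per-point projection of the residual on the
## tangent; "bending": joint minimisation of the TPS bending energy of the
## deformation from the consensus.  Displacements are capped at half the
## distance to the nearer curve neighbour to prevent curve inversion.
slide_semilandmarks <- function(X, consensus, scheme,
                                criterion = c("procrustes", "bending"),
                                B = NULL) {
  criterion <- match.arg(criterion)
  semi <- which(scheme$role == "semi")
  if (length(semi) == 0L) return(X)
  tangents <- matrix(0, length(semi), 2)
  caps <- numeric(length(semi))
  for (s in seq_along(semi)) {
    j <- semi[s]
    cid <- scheme$curve_id[j]
    prev <- if (j > 1L && scheme$curve_id[j - 1L] == cid) j - 1L else j
    nxt  <- if (j < nrow(scheme) && scheme$curve_id[j + 1L] == cid) j + 1L else j
    v <- X[nxt, ] - X[prev, ]
    nv <- sqrt(sum(v^2))
    tangents[s, ] <- if (nv > 0) v / nv else c(0, 0)
    dn <- min(if (prev != j) sqrt(sum((X[j, ] - X[prev, ])^2)) else Inf,
              if (nxt != j)  sqrt(sum((X[j, ] - X[nxt, ])^2))  else Inf)
    caps[s] <- dn / 2
  }
  resid <- consensus - X
  if (criterion == "procrustes") {
    s_opt <- rowSums(resid[semi, , drop = FALSE] * tangents)
  } else {
    if (is.null(B)) B <- bending_energy_matrix(consensus)
    m <- length(semi)
    # U_d: k x m placement of tangent components
    Ux <- matrix(0, nrow(X), m); Uy <- matrix(0, nrow(X), m)
    Ux[cbind(semi, seq_len(m))] <- tangents[, 1]
    Uy[cbind(semi, seq_len(m))] <- tangents[, 2]
    A <- crossprod(Ux, B %*% Ux) + crossprod(Uy, B %*% Uy)
    b <- -(crossprod(Ux, B %*% (X[, 1] - consensus[, 1])) +
           crossprod(Uy, B %*% (X[, 2] - consensus[, 2])))
    s_opt <- tryCatch(drop(solve(A + diag(1e-10, m), b)),
                      error = function(e) rep(0, m))
  }
  s_opt <- pmin(pmax(s_opt, -caps), caps)
  X[semi, ] <- X[semi, ] + s_opt * tangents
  X
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes a set of configurations: every configuration is
#' centred, scaled to unit centroid size and rotated onto the current
#' consensus; the consensus is then recomputed as the mean of the aligned
#' set and the loop repeats until the consensus stabilises (root mean
#' square change below `tol`) or `max_iter` outer iterations are reached.
#' With `slide = TRUE`, each outer iteration additionally slides every
#' semi-landmark along its local curve tangent to the position that
#' minimises the specimen's squared Procrustes distance to the consensus
#' (`slide_criterion = "procrustes"`, the default) or the bending energy of
#' the thin-plate-spline deformation from the consensus
#' (`slide_criterion = "bending"`).
#'
#' @param configs list of [landmark_config()] objects or k x 2 matrices.
#' @param scheme a [landmark_scheme()]; required when `slide = TRUE`.
#' @param slide logical, slide semi-landmarks?
#' @param slide_criterion sliding criterion, see above.
#' @param tol consensus RMS-change convergence tolerance.
#' @param slide_tol relative per-iteration decrease of the total squared
#'   distance to the consensus below which a sliding superimposition is
#'   declared converged.  Distance-minimising sliding lets semi-landmarks
#'   creep along their curves indefinitely at ever-smaller gains, so the
#'   objective (not the consensus) is the meaningful stopping criterion
#'   when `slide = TRUE`.
#' @param max_iter maximum number of outer iterations.
#' @param slide_iters number of initial outer iterations in which
#'   semi-landmarks are slid; later iterations refine the superimposition
#'   with the slid positions held fixed.  Sliding gains virtually all of
#'   its improvement in the first few passes, and unbounded re-sliding
#'   lets semi-landmarks drift along their curves (especially under the
#'   bending-energy criterion, whose null directions barely resist smooth
#'   tangential redistribution).
#' @param project_tangent logical; if `TRUE`, aligned shapes are
#'   orthogonally projected onto the tangent space at the consensus after
#'   convergence.  At facial-variation magnitudes this changes downstream
#'   scores negligibly; default `FALSE`.
#' @return An object of class `aligned_sample`: list with `aligned`
#'   (n x k x 2 array), `consensus` (k x 2, the arithmetic mean of the
#'   aligned set), `centroid_sizes`, `iterations`, `converged`, `ids`, and
#'   the objective history (total squared distance to the mean after each
#'   outer iteration).
#' @export
gpa <- function(configs, scheme = NULL, slide = FALSE,
                slide_criterion = c("procrustes", "bending"),
                tol = 1e-6, slide_tol = 1e-3, max_iter = 20L,
                slide_iters = 5L, project_tangent = FALSE) {
  slide_criterion <- match.arg(slide_criterion)
  if (length(configs) < 2L) stop("GPA needs >= 2 configurations")
  mats <- lapply(configs, function(cf) {
    if (inherits(cf, "landmark_config")) cf$points else as.matrix(cf)
  })
  ids <- vapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    if (inherits(cf, "landmark_config") && nzchar(cf$id)) cf$id
    else as.character(i)
  }, character(1))
  k <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, integer(1)) != k)) {
    stop("inconsistent landmark counts across configurations")
  }
  if (slide) {
    if (is.null(scheme)) stop("`scheme` is required when slide = TRUE")
    if (nrow(scheme) != k) stop("scheme size does not match landmark count")
  }
  n <- length(mats)
  sizes <- vapply(mats, centroid_size, numeric(1))
  if (any(sizes <= .Machine$double.eps)) {
    stop("degenerate configuration: zero centroid size")
  }
  X <- array(0, dim = c(n, k, 2))
  for (i in seq_len(n)) X[i, , ] <- centre_config(mats[[i]]) / sizes[i]

  # initial consensus: all rotated onto the first configuration
  cons <- X[1, , ]
  for (i in seq_len(n)) X[i, , ] <- X[i, , ] %*% optimal_rotation(cons, X[i, , ])
  cons <- apply(X, c(2, 3), mean)

  obj_hist <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    ref <- cons / sqrt(sum(cons^2))   # unit-size consensus for alignment
    do_slide <- slide && iter <= slide_iters
    B_bend <- if (do_slide && slide_criterion == "bending")
      bending_energy_matrix(ref) else NULL
    for (i in seq_len(n)) {
      Xi <- X[i, , ]
      if (do_slide) {
        Xi <- slide_semilandmarks(Xi, ref, scheme, slide_criterion, B = B_bend)
        Xi <- centre_config(Xi)
        Xi <- Xi / sqrt(sum(Xi^2))
      }
      X[i, , ] <- Xi %*% optimal_rotation(ref, Xi)
    }
    new_cons <- apply(X, c(2, 3), mean)
    obj_hist <- c(obj_hist,
                  sum(vapply(seq_len(n),
                             function(i) sum((X[i, , ] - new_cons)^2),
                             numeric(1))))
    delta <- sqrt(mean((new_cons / sqrt(sum(new_cons^2)) - ref)^2))
    cons <- new_cons
    if (delta < tol) { converged <- TRUE; break }
    if (do_slide && iter >= 2L) {
      m <- length(obj_hist)
      rel <- (obj_hist[m - 1L] - obj_hist[m]) / obj_hist[m - 1L]
      if (abs(rel) < slide_tol) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    warning("GPA did not converge in ", max_iter, " iterations")
  }
  if (project_tangent) {
    chat <- as.vector(cons) / sqrt(sum(cons^2))
    for (i in seq_len(n)) {
      xi <- as.vector(X[i, , ])
      X[i, , ] <- xi - sum(xi * chat) * chat + chat * sqrt(sum(cons^2))
    }
    cons <- apply(X, c(2, 3), mean)
  }
  structure(list(aligned = X, consensus = cons, centroid_sizes = sizes,
                 iterations = iter, converged = converged, ids = ids,
                 slide = slide, slide_criterion = if (slide) slide_criterion else NA,
                 objective = obj_hist),
            class = "aligned_sample")
}

#' @export
print.aligned_sample <- function(x, ...) {
  cat("Procrustes-aligned sample: ", dim(x$aligned)[1], " configurations, ",
      dim(x$aligned)[2], " landmarks; ", x$iterations, " iterations (",
      if (x$converged) "converged" else "NOT converged", ")",
      if (isTRUE(x$slide)) paste0("; semi-landmarks slid (", x$slide_criterion, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Serialise / load an aligned sample as plain text
#'
#' A simple structured-text bundle: a header, the consensus, centroid
#' sizes, and the aligned coordinates of every configuration.
#'
#' @param x an `aligned_sample`.
#' @param path file path.
#' @return `read_aligned_sample` returns an `aligned_sample`.
#' @export
write_aligned_sample <- function(x, path) {
  n <- dim(x$aligned)[1]; k <- dim(x$aligned)[2]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("aligned_sample n=%d k=%d iterations=%d converged=%d",
                     n, k, x$iterations, as.integer(x$converged)), con)
  writeLines("consensus", con)
  writeLines(sprintf("%.17g %.17g", x$consensus[, 1], x$consensus[, 2]), con)
  writeLines("centroid_sizes", con)
  writeLines(sprintf("%s %.17g", x$ids, x$centroid_sizes), con)
  for (i in seq_len(n)) {
    writeLines(sprintf("config %s", x$ids[i]), con)
    writeLines(sprintf("%.17g %.17g", x$aligned[i, , 1], x$aligned[i, , 2]), con)
  }
  invisible(path)
}

#' @rdname write_aligned_sample
#' @export
read_aligned_sample <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  get <- function(key) as.integer(sub(paste0(key, "="), "",
                                      grep(paste0("^", key, "="), hdr, value = TRUE)))
  n <- get("n"); k <- get("k")
  pos <- 2L
  stopifnot(lines[pos] == "consensus")
  cons <- do.call(rbind, lapply(lines[pos + seq_len(k)], function(ln)
    as.numeric(strsplit(ln, " ")[[1]])))
  pos <- pos + k + 1L
  stopifnot(lines[pos] == "centroid_sizes")
  sz <- do.call(rbind, lapply(lines[pos + seq_len(n)], function(ln)
    strsplit(ln, " ")[[1]]))
  ids <- sz[, 1]; sizes <- as.numeric(sz[, 2])
  pos <- pos + n + 1L
  X <- array(0, dim = c(n, k, 2))
  for (i in seq_len(n)) {
    stopifnot(startsWith(lines[pos], "config "))
    block <- do.call(rbind, lapply(lines[pos + seq_len(k)], function(ln)
      as.numeric(strsplit(ln, " ")[[1]])))
    X[i, , ] <- block
    pos <- pos + k + 1L
  }
  structure(list(aligned = X, consensus = cons, centroid_sizes = sizes,
                 iterations = get("iterations"),
                 converged = as.logical(get("converged")), ids = ids,
                 slide = NA, slide_criterion = NA, objective = numeric(0)),
            class = "aligned_sample")
}
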