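#' Landmark digitising scheme
#'
#' A scheme declares, for each landmark index, whether it is a fixed
#' (anatomical) landmark or a semi-landmark, and for semi-landmarks which
#' curve it belongs to.  TPS files carry no role information, so the scheme
#' travels as a sidecar next to the landmark file (one line per landmark:
#' `index role curve_id`, with `curve_id = 0` for fixed landmarks).
#' Semi-landmarks of a curve must occupy consecutive indices so that curve
#' tangents can be taken from neighbouring points.
#'
#' @param roles character vector, one of `"fixed"`/`"semi"` per landmark.
#' @param curve_id integer vector, curve membership per landmark
#'   (0 for fixed landmarks, >= 1 for semi-landmarks).
#' @return An object of class `landmark_scheme`: a data frame with columns
#'   `index`, `role`, `curve_id`.
#' @seealso [default_scheme()] for the packaged 72-point face scheme.
#' @export
landmark_scheme <- function(roles, curve_id) {
  if (length(roles) != length(curve_id)) {
    stop("`roles` and `curve_id` must have the same length")
  }
  roles <- match.arg(roles, c("fixed", "semi"), several.ok = TRUE)
  if (any(roles == "semi" & curve_id < 1)) {
    stop("semi-landmarks must carry a curve_id >= 1")
  }
  if (any(roles == "fixed" & curve_id != 0)) {
    stop("fixed landmarks must carry curve_id 0")
  }
  # curve members must be consecutive so that tangents are well defined
  for (cid in unique(curve_id[curve_id > 0])) {
    idx <- which(curve_id == cid)
    if (length(idx) < 2L) stop("curve ", cid, " has fewer than 2 semi-landmarks")
    if (any(diff(idx) != 1L)) stop("curve ", cid, " members are not consecutive")
  }
  out <- data.frame(index = seq_along(roles), role = roles,
                    curve_id = as.integer(curve_id))
  class(out) <- c("landmark_scheme", "data.frame")
  out
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme:", nrow(x), "landmarks (",
      sum(x$role == "fixed"), "fixed,", sum(x$role == "semi"),
      "semi on", length(unique(x$curve_id[x$curve_id > 0])), "curves )\n")
  invisible(x)
}

#' Write / read a scheme sidecar file
#'
#' Plain text, one line per landmark: `index role curve_id`.
#'
#' @param scheme a [landmark_scheme()].
#' @param path file path.
#' @return `read_scheme` returns a `landmark_scheme`; `write_scheme` returns
#'   `path` invisibly.
#' @export
write_scheme <- function(scheme, path) {
  writeLines(sprintf("%d %s %d", scheme$index, scheme$role, scheme$curve_id),
             path)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  tab <- utils::read.table(path, col.names = c("index", "role", "curve_id"),
                           colClasses = c("integer", "character", "integer"))
  if (any(tab$index != seq_len(nrow(tab)))) {
    stop("scheme file indices must run 1..n in order: ", path)
  }
  landmark_scheme(tab$role, tab$curve_id)
}

#' A single digitised landmark configuration
#'
#' @param points numeric k x 2 matrix of digitised coordinates.
#' @param id specimen identifier.
#' @param scale optional physical scale factor (tpsDig2 `SCALE=`); when
#'   present the stored coordinates are already multiplied by it.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(points, id = "", scale = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("`points` must be a k x 2 matrix")
  if (any(!is.finite(points))) stop("non-finite coordinates in configuration ", id)
  structure(list(id = as.character(id), points = unname(points), scale = scale),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration '", x$id, "': ", nrow(x$points), " points\n",
      sep = "")
  invisible(x)
}

#' Read a TPS landmark file (tpsDig2 dialect)
#'
#' Parses records of the form `LM=<k>` followed by `k` lines of `x y`
#' coordinates (space or tab separated), with optional `IMAGE=`, `ID=` and
#' `SCALE=` lines.  When a `SCALE=` line is present the coordinates are
#' multiplied by it.  Record order is preserved and no record is silently
#' dropped: the number of configurations returned equals the number of
#' `LM=` records, or an error is raised naming the offending record.
#'
#' @param path path to a TPS file.
#' @return A list of [landmark_config()] objects (empty list, with a
#'   warning, for an empty file).
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty TPS file: ", path)
    return(list())
  }
  starts <- grep("^LM=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) stop("no LM= records in TPS file: ", path)
  if (starts[1] != 1L) stop("TPS file does not start with an LM= record: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  configs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- suppressWarnings(as.integer(sub("^LM=\\s*", "", block[1],
                                         ignore.case = TRUE)))
    if (is.na(k) || k < 1L) stop("bad LM= count in record ", r, " of ", path)
    body <- block[-1]
    is_meta <- grepl("^[A-Za-z]+=", body)
    coord_lines <- body[!is_meta]
    if (length(coord_lines) != k) {
      stop("record ", r, " of ", path, ": LM=", k, " but ",
           length(coord_lines), " coordinate lines")
    }
    xy <- t(vapply(coord_lines, function(ln) {
      parts <- strsplit(ln, "[ \t]+")[[1]]
      if (length(parts) != 2L) stop("record ", r, " of ", path,
                                    ": malformed coordinate line '", ln, "'")
      suppressWarnings(as.numeric(parts))
    }, numeric(2), USE.NAMES = FALSE))
    if (any(!is.finite(xy))) stop("record ", r, " of ", path,
                                  ": non-numeric coordinate")
    meta <- body[is_meta]
    get_meta <- function(key) {
      hit <- grep(paste0("^", key, "="), meta, ignore.case = TRUE, value = TRUE)
      if (length(hit) == 0L) NULL else sub(paste0("^", key, "=\\s*"), "",
                                           hit[1], ignore.case = TRUE)
    }
    id <- get_meta("ID")
    if (is.null(id)) id <- get_meta("IMAGE")
    if (is.null(id)) id <- as.character(r)
    scale <- get_meta("SCALE")
    scale <- if (is.null(scale)) NULL else as.numeric(scale)
    if (!is.null(scale)) xy <- xy * scale
    configs[[r]] <- landmark_config(xy, id = id, scale = scale)
  }
  configs
}

#' Write landmark configurations as a TPS file
#'
#' Emits the dialect read by [read_tps()]: `LM=<k>`, `k` coordinate lines
#' at full precision, then `ID=`.  All configurations must share the same
#' landmark count.
#'
#' @param configs list of [landmark_config()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  if (length(configs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ks <- vapply(configs, function(cf) nrow(cf$points), integer(1))
  if (length(unique(ks)) != 1L) {
    stop("heterogeneous landmark counts: ", paste(unique(ks), collapse = ", "))
  }
  out <- unlist(lapply(configs, function(cf) {
    c(sprintf("LM=%d", nrow(cf$points)),
      sprintf("%.17g %.17g", cf$points[, 1], cf$points[, 2]),
      sprintf("ID=%s", cf$id))
  }))
  writeLines(out, path)
  invisible(path)
}
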