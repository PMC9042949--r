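#' Read a specimen covariate table
#'
#' The ingestion schema matches what the study generator writes: one row per
#' photographed face with identifier, sex, age, body measurements, CIELab
#' skin colour and the two repeated width/height measurements used for the
#' facial width-to-height ratio.  Either `weight` + `height` (body) or a
#' precomputed `bmi` column must be present.
#'
#' @param path delimited text file; comma-separated by default, tabs accepted.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab.
#' @return A validated `data.frame` with at least the columns
#'   `id, sex, age, L, a, b, width1, width2, height1, height2` and one of
#'   `bmi` or `weight`+`height`.
#' @export
read_specimen_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("specimen table not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_specimen_table(tab)
}

#' @rdname read_specimen_table
#' @param table a data frame to validate in place of a file.
#' @export
validate_specimen_table <- function(table) {
  required <- c("id", "sex", "age", "L", "a", "b",
                "width1", "width2", "height1", "height2")
  missing <- setdiff(required, names(table))
  if (!("bmi" %in% names(table)) &&
      !all(c("weight", "height") %in% names(table))) {
    missing <- c(missing, "bmi (or weight+height)")
  }
  if (length(missing) > 0L) {
    stop("specimen table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  table$id <- as.character(table$id)
  table$sex <- tolower(as.character(table$sex))
  bad_sex <- setdiff(unique(table$sex), c("male", "female"))
  if (length(bad_sex) > 0L) {
    stop("sex must be 'male' or 'female'; found: ",
         paste(bad_sex, collapse = ", "))
  }
  num_cols <- intersect(c("age", "weight", "height", "bmi", "L", "a", "b",
                          "width1", "width2", "height1", "height2"),
                        names(table))
  for (cl in num_cols) table[[cl]] <- as.numeric(table[[cl]])
  if (anyDuplicated(table$id)) stop("duplicate specimen ids in table")
  table
}

#' Write a specimen table
#' @param table validated specimen data frame.
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(table, path, sep = ",") {
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a rater-by-stimulus rating matrix
#'
#' Rows are raters, columns are stimulus ids, cells are integer ratings on
#' the 1--7 scale (blank/NA allowed for missing).  The first column must be
#' `rater_id`.
#'
#' @param path delimited text file (comma default, tab accepted).
#' @param sep separator; `NULL` auto-detects.
#' @return An object of class `rating_matrix`: an integer matrix with
#'   raters as rownames and stimulus ids as colnames.
#' @export
read_ratings <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("rating file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(tab)[1], "rater_id")) {
    stop("rating file must have 'rater_id' as its first column: ", path)
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab$rater_id)
  rating_matrix(m)
}

#' Construct / validate a rating matrix
#'
#' @param values numeric matrix, raters x stimuli, entries in 1..7 or NA.
#' @return `rating_matrix` object.
#' @export
rating_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("rating matrix needs >= 2 raters")
  obs <- values[!is.na(values)]
  if (any(obs != round(obs)) || any(obs < 1 | obs > 7)) {
    stop("ratings must be integers in [1, 7]")
  }
  rated_by <- colSums(!is.na(values))
  if (any(rated_by < 2L)) {
    stop("every stimulus must be rated by >= 2 raters; offending: ",
         paste(colnames(values)[rated_by < 2L], collapse = ", "))
  }
  structure(values, class = c("rating_matrix", class(values)))
}

#' Write a rating matrix
#' @param m a [rating_matrix()].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(m, path, sep = ",") {
  df <- data.frame(rater_id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
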