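#' Construct a dose-response expression study
#'
#' A `dose_response_study` bundles a probeset-by-sample matrix of normalized
#' log2 intensities with the per-sample dose labels (mg/kg/d) for a single
#' test molecule. The design must contain a control group (dose 0) and at
#' least two distinct positive dose levels, each dose group with at least two
#' replicates.
#'
#' @param matrix numeric matrix, probesets in rows (rownames = probeset ids),
#'   samples in columns, values = normalized log2 intensities.
#' @param doses numeric vector of per-sample doses in mg/kg/d, one per column.
#' @param molecule_id character label for the test molecule.
#' @param samples optional character vector of sample labels; defaults to the
#'   matrix column names.
#' @return An object of class `dose_response_study`: a list with elements
#'   `molecule_id`, `doses`, `samples`, `matrix`, `probeset_ids`.
#' @export
#' @examples
#' m <- matrix(rnorm(3 * 9, 8), 3, 9,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:9)))
#' dose_response_study(m, rep(c(0, 10, 100), each = 3), "demo")
dose_response_study <- function(matrix, doses, molecule_id = "molecule",
                                samples = colnames(matrix)) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  if (is.null(rownames(matrix)))
    stop("`matrix` must carry probeset ids as rownames")
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(matrix)))
  doses <- as.numeric(doses)
  if (length(doses) != ncol(matrix))
    stop("length(doses) must equal ncol(matrix)")
  if (length(samples) != ncol(matrix))
    stop("length(samples) must equal ncol(matrix)")
  study <- structure(
    list(molecule_id = as.character(molecule_id)[1],
         doses = doses,
         samples = as.character(samples),
         matrix = matrix,
         probeset_ids = rownames(matrix)),
    class = "dose_response_study")
  validate_study(study)
  study
}

#' Validate a dose-response study
#'
#' Checks the invariants of the container: exactly one control dose (0),
#' at least two distinct positive dose levels, every dose group with two or
#' more samples, unique probeset ids, and all-finite expression values.
#'
#' @param study a `dose_response_study`.
#' @return `study`, invisibly; stops with a validation error otherwise.
#' @export
validate_study <- function(study) {
  doses <- study$doses
  if (anyNA(doses)) stop("doses contain missing values")
  lev <- sort(unique(doses))
  if (sum(lev == 0) != 1 || !any(doses == 0))
    stop("study must contain exactly one control dose level equal to 0")
  if (sum(lev > 0) < 2)
    stop("study must contain at least 2 distinct positive dose levels")
  if (any(lev < 0)) stop("negative doses are not allowed")
  cnt <- table(doses)
  if (any(cnt < 2))
    stop("every dose group must contain at least 2 samples")
  if (anyDuplicated(study$probeset_ids))
    stop("duplicate probeset id: ",
         study$probeset_ids[anyDuplicated(study$probeset_ids)])
  if (!all(is.finite(study$matrix)))
    stop("expression matrix contains non-finite values")
  invisible(study)
}

#' @export
print.dose_response_study <- function(x, ...) {
  lev <- sort(unique(x$doses))
  cat("Dose-response study:", x$molecule_id, "\n")
  cat(sprintf("  %d probesets x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("  dose levels (mg/kg/d):", paste(lev, collapse = ", "), "\n")
  cat("  replicates per group:",
      paste(as.integer(table(x$doses)[as.character(lev)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a dose-response expression study from a tab-delimited file
#'
#' The dialect follows the import convention of dose-response modeling tools
#' for expression data: row 1 is a header whose first cell is an arbitrary
#' label followed by sample labels; row 2 starts with the literal token
#' `Dose` followed by the numeric dose of each sample; rows 3+ hold one
#' probeset per row (id, then one log2 intensity per sample).
#'
#' @param path path to a tab-delimited text file.
#' @param molecule_id molecule label to attach; defaults to the file name
#'   without extension.
#' @return a validated [dose_response_study()].
#' @export
read_expression_study <- function(path, molecule_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3)
    stop("format error: expected a header row, a Dose row and data rows")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  dose_row <- strsplit(lines[[2]], "\t", fixed = TRUE)[[1]]
  if (!identical(dose_row[[1]], "Dose"))
    stop("format error: second row must start with the literal 'Dose'")
  if (length(dose_row) - 1L != length(samples))
    stop("format error: Dose row has ", length(dose_row) - 1L,
         " values for ", length(samples), " samples")
  doses <- suppressWarnings(as.numeric(dose_row[-1]))
  if (anyNA(doses)) {
    bad <- which(is.na(doses))[1]
    stop(sprintf(
      "format error: non-numeric dose '%s' in column %d (sample '%s')",
      dose_row[-1][bad], bad, samples[bad]))
  }
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  ids <- vapply(body, `[[`, character(1), 1L)
  vals <- lapply(body, function(f) suppressWarnings(as.numeric(f[-1])))
  nv <- lengths(vals)
  if (any(nv != length(samples)))
    stop("format error: probeset '", ids[which(nv != length(samples))[1]],
         "' has a wrong number of values")
  mat <- do.call(rbind, vals)
  if (anyNA(mat))
    stop("format error: non-numeric expression value for probeset '",
         ids[which(rowSums(is.na(mat)) > 0)[1]], "'")
  rownames(mat) <- ids
  colnames(mat) <- samples
  if (is.null(molecule_id))
    molecule_id <- sub("\\.[^.]*$", "", basename(path))
  dose_response_study(mat, doses, molecule_id, samples)
}

#' Write a dose-response expression study
#'
#' Canonical writer for the dialect read by [read_expression_study()]:
#' read/write round-trips preserve doses, sample order and probeset order.
#'
#' @param study a `dose_response_study`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_study <- function(study, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("Array", study$samples), collapse = "\t"), con)
  writeLines(paste(c("Dose", format(study$doses, trim = TRUE,
                                    scientific = FALSE)),
                   collapse = "\t"), con)
  body <- apply(study$matrix, 1, function(v)
    paste(format(v, trim = TRUE, digits = 15), collapse = "\t"))
  writeLines(paste(study$probeset_ids, body, sep = "\t"), con)
  invisible(path)
}

# Per-group sample index in increasing dose order; first group is control.
group_index <- function(doses) {
  lev <- sort(unique(doses))
  list(levels = lev, idx = lapply(lev, function(l) which(doses == l)),
       n = vapply(lev, function(l) sum(doses == l), integer(1)))
}

# Group means for one probeset's values.
group_means <- function(values, doses) {
  gi <- group_index(doses)
  vapply(gi$idx, function(i) mean(values[i]), numeric(1))
}
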