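#' Construct a modality matrix
#'
#' A modality matrix is the basic subjects-by-variables container fed to the
#' parallel decomposition: one row per subject, one column per variable
#' (within-mask voxel for the FA modality, SNP for the genetic modality).
#' It is an ordinary numeric matrix carrying subject IDs as row names,
#' variable IDs as column names, and a modality tag.
#'
#' @param values numeric matrix, subjects in rows.
#' @param subjects character vector of subject IDs (defaults to existing row
#'   names or `S1..Sn`).
#' @param variables character vector of variable IDs.
#' @param modality tag, e.g. `"fa"` or `"snp"`.
#' @return a `modality_matrix` (numeric matrix subclass).
#' @export
modality_matrix <- function(values, subjects = NULL, variables = NULL,
                            modality = "generic") {
  values <- as.matrix(values)
  assert_that(is.numeric(values), "modality matrix must be numeric")
  assert_that(!anyNA(values), "modality matrix must not contain missing values")
  if (is.null(subjects)) {
    subjects <- rownames(values)
    if (is.null(subjects)) subjects <- sprintf("S%03d", seq_len(nrow(values)))
  }
  if (is.null(variables)) {
    variables <- colnames(values)
    if (is.null(variables)) variables <- sprintf("V%d", seq_len(ncol(values)))
  }
  assert_that(length(subjects) == nrow(values) &&
                length(variables) == ncol(values),
              "ID lengths must match matrix dimensions")
  dimnames(values) <- list(subjects, variables)
  structure(values, modality = modality,
            class = c("modality_matrix", class(values)))
}

#' @export
print.modality_matrix <- function(x, ...) {
  cat(sprintf("<modality_matrix '%s': %d subjects x %d variables>\n",
              attr(x, "modality"), nrow(x), ncol(x)))
  invisible(x)
}

# Strip the class for plain matrix algebra.
mm_values <- function(x) {
  y <- unclass(x)
  attr(y, "modality") <- NULL
  y
}

#' Read a delimited modality matrix
#'
#' Tab-separated text with a header row of variable IDs and a first column of
#' subject IDs.
#'
#' @param path file path.
#' @param modality modality tag for the result.
#' @return a [modality_matrix()].
#' @export
read_modality_matrix <- function(path, modality = "generic") {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  row.names = 1L)
  modality_matrix(as.matrix(d), modality = modality)
}

#' Write a modality matrix to tab-separated text
#'
#' @param x a [modality_matrix()] or plain matrix.
#' @param path output file path.
#' @export
write_modality_matrix <- function(x, path) {
  d <- data.frame(id = rownames(x), as.data.frame(unclass(x)),
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
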