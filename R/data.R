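#' Construct a mediation dataset
#'
#' Bundles the outcome, exposure, mediator and optional covariates into a
#' validated container used by the model-fitting functions. Column types are
#' declared, never inferred: a column declared `"binary"` must contain only
#' 0/1 values, and no missing values are allowed anywhere (resolve missingness
#' before analysis, e.g. by complete-case restriction or missing-indicator
#' coding).
#'
#' @param y Numeric outcome vector.
#' @param x Numeric exposure vector (binary 0/1 or continuous).
#' @param m Numeric mediator vector.
#' @param w Optional covariate matrix or data frame (`n` rows); columns must
#'   be numeric (expand categorical covariates to dummies beforehand).
#' @param y_type,m_type Declared type of the outcome / mediator:
#'   `"continuous"` or `"binary"`.
#' @return An object of class `mediation_data`: a list with elements `y`,
#'   `x`, `m`, `w` (numeric matrix, possibly zero columns), `y_type`,
#'   `m_type`, `n`.
#' @examples
#' d <- mediation_data(y = rnorm(50), x = rbinom(50, 1, 0.5),
#'                     m = rnorm(50), y_type = "continuous",
#'                     m_type = "continuous")
#' d$n
#' @export
mediation_data <- function(y, x, m, w = NULL,
                           y_type = c("continuous", "binary"),
                           m_type = c("continuous", "binary")) {
  y_type <- match.arg(y_type)
  m_type <- match.arg(m_type)
  y <- as.numeric(y); x <- as.numeric(x); m <- as.numeric(m)
  n <- length(y)
  if (n == 0L)
    pm_validation_error("empty dataset: no observations")
  if (length(x) != n || length(m) != n)
    pm_validation_error("y, x and m must have equal length")
  if (is.null(w)) {
    w <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    w <- as.matrix(w)
    storage.mode(w) <- "double"
    if (nrow(w) != n)
      pm_validation_error("covariate matrix w must have one row per subject")
    if (is.null(colnames(w)))
      colnames(w) <- paste0("w", seq_len(ncol(w)))
  }
  if (anyNA(y) || anyNA(x) || anyNA(m) || anyNA(w))
    pm_validation_error(
      "missing values detected; resolve missingness before fitting")
  check_binary <- function(v, what) {
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad))
      pm_validation_error(sprintf(
        "column declared binary (%s) contains non-0/1 value %g at row %d",
        what, v[bad[1]], bad[1]))
  }
  if (y_type == "binary") check_binary(y, "outcome")
  if (m_type == "binary") check_binary(m, "mediator")
  # identifiability precondition: n at least the larger model's parameter count
  p_larger <- 3L + ncol(w)
  if (n < p_larger)
    pm_validation_error(sprintf(
      "n = %d is smaller than the %d parameters of the outcome model", n, p_larger))
  structure(list(y = y, x = x, m = m, w = w,
                 y_type = y_type, m_type = m_type, n = n),
            class = "mediation_data")
}

#' @export
print.mediation_data <- function(x, ...) {
  cat(sprintf("<mediation_data> n = %d, outcome: %s, mediator: %s, covariates: %d\n",
              x$n, x$y_type, x$m_type, ncol(x$w)))
  invisible(x)
}

#' Read a delimited text table into a mediation dataset
#'
#' Reads a header-ed delimited file (comma by default, tab accepted) and maps
#' declared columns onto the outcome/exposure/mediator/covariate roles.
#' Column roles and types are declared by the caller, never inferred from the
#' data.
#'
#' @param path Path to a delimited text file with a header row.
#' @param outcome,exposure,mediator Column names for each role.
#' @param covariates Character vector of covariate column names (may be
#'   empty). Covariates used by only one of the two models are selected at
#'   fitting time; the dataset carries their union.
#' @param binary_outcome,binary_mediator Logical type declarations.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return A [mediation_data] object.
#' @export
read_mediation_data <- function(path, outcome, exposure, mediator,
                                covariates = character(0),
                                binary_outcome = FALSE,
                                binary_mediator = FALSE,
                                sep = ",") {
  if (!file.exists(path))
    pm_validation_error(sprintf("data file not found: %s", path))
  if (file.size(path) == 0L)
    pm_validation_error(sprintf("data file is empty: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L)
    pm_validation_error(sprintf("data file has a header but no rows: %s", path))
  wanted <- c(outcome, exposure, mediator, covariates)
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols))
    pm_validation_error(sprintf("declared column(s) not present in %s: %s",
                                path, paste(missing_cols, collapse = ", ")))
  for (cl in wanted) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !anyNA(v)) {
        bad <- which(is.na(vn))[1]
        pm_validation_error(sprintf(
          "non-numeric cell in column '%s' at row %d: '%s'", cl, bad, v[bad]))
      }
      df[[cl]] <- vn
    }
  }
  w <- if (length(covariates)) as.matrix(df[covariates]) else NULL
  mediation_data(
    y = df[[outcome]], x = df[[exposure]], m = df[[mediator]], w = w,
    y_type = if (binary_outcome) "binary" else "continuous",
    m_type = if (binary_mediator) "binary" else "continuous")
}
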