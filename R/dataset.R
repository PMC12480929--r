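#' Regression dataset container
#'
#' Holds the design matrix (covariates in problem order, no intercept column)
#' and the response. Invariants: no missing values, more observations than
#' coefficients (n > p + 1), and a binary response must contain both classes.
#'
#' @param X numeric matrix or data frame of covariates (n x p).
#' @param y response vector: 0/1 for logistic problems, real for linear.
#' @param variable_names optional covariate names; defaults to `colnames(X)`.
#' @return an object of class `regression_dataset`.
#' @export
regression_dataset <- function(X, y, variable_names = colnames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) pe_stop("regression_dataset: length(y) != nrow(X)")
  if (anyNA(X) || anyNA(y)) pe_stop("regression_dataset: missing values are not allowed")
  if (p > 0) {
    if (is.null(variable_names)) variable_names <- paste0("x", seq_len(p))
    variable_names <- as.character(variable_names)
    if (length(variable_names) != p || anyDuplicated(variable_names)) {
      pe_stop("regression_dataset: variable names must be unique and match ncol(X)")
    }
    colnames(X) <- variable_names
  } else {
    variable_names <- character()
  }
  if (n <= p + 1) {
    pe_stop("regression_dataset: need n > p + 1 (got n = %d, p = %d)", n, p)
  }
  if (all(y %in% c(0, 1)) && length(unique(y)) < 2L) {
    pe_stop("regression_dataset: binary response must contain both classes")
  }
  structure(list(X = X, y = y, variable_names = variable_names),
            class = "regression_dataset")
}

#' @export
print.regression_dataset <- function(x, ...) {
  cat(sprintf("<regression_dataset> %d obs x %d covariate(s): %s\n",
              nrow(x$X), ncol(x$X), paste(x$variable_names, collapse = ", ")))
  invisible(x)
}

#' Read a regression dataset from delimited text
#'
#' @param path delimited text file with a header row (comma separated by
#'   default; pass `sep = "\t"` for tab).
#' @param response name of the response column.
#' @param sep field separator.
#' @param positive_level for a two-level text/factor response, the level coded
#'   as 1.
#' @return a [regression_dataset()].
#' @export
read_regression_data <- function(path, response, sep = ",", positive_level = NULL) {
  if (!file.exists(path)) pe_stop("dataset file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!response %in% names(df)) {
    pe_stop("response column '%s' not found in %s", response, path)
  }
  y <- df[[response]]
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    lev <- sort(unique(y))
    if (length(lev) != 2L) {
      pe_stop("text response must have exactly two levels (found %d)", length(lev))
    }
    if (is.null(positive_level)) {
      pe_stop("text response needs an explicit 'positive_level' (one of: %s)",
              paste(lev, collapse = ", "))
    }
    if (!positive_level %in% lev) {
      pe_stop("positive_level '%s' is not a level of the response", positive_level)
    }
    y <- as.numeric(y == positive_level)
  }
  Xdf <- df[setdiff(names(df), response)]
  if (!all(vapply(Xdf, is.numeric, logical(1)))) {
    bad <- names(Xdf)[!vapply(Xdf, is.numeric, logical(1))]
    pe_stop("non-numeric covariate column(s): %s", paste(bad, collapse = ", "))
  }
  regression_dataset(as.matrix(Xdf), y, variable_names = names(Xdf))
}

#' Write a regression dataset to delimited text
#'
#' @param data a [regression_dataset()].
#' @param path output file.
#' @param response name used for the response column.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_regression_data <- function(data, path, response = "y", sep = ",") {
  stopifnot(inherits(data, "regression_dataset"))
  df <- as.data.frame(data$X, check.names = FALSE)
  df[[response]] <- data$y
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# design matrix with intercept column first
design_with_intercept <- function(data) {
  cbind(`(Intercept)` = 1, data$X)
}
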