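#' Bundle a count response with component design matrices
#'
#' A `zic_data` object holds the ingredients of a two-part zero-inflated
#' count regression: a nonnegative integer response `y`, a design matrix for
#' the count component (log link) and a design matrix for the zero component
#' (logit link). Both designs carry a leading intercept column; pass
#' covariate matrices without an intercept and one is prepended.
#'
#' @param y Nonnegative integer response vector.
#' @param X_count Numeric matrix of count-component covariates (no intercept
#'   column), `n x p`. May be `NULL` for an intercept-only count model.
#' @param X_zero Numeric matrix of zero-component covariates (no intercept
#'   column), `n x q`. Defaults to intercept-only, the usual choice when the
#'   zero-inflation level is not covariate-dependent.
#' @return An object of class `zic_data` with elements `y`, `X_count`,
#'   `X_zero` (both with a leading `"(Intercept)"` column of ones).
#' @export
zic_data <- function(y, X_count = NULL, X_zero = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n == 0L) stop("empty response")
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y)))
    stop("y must be finite nonnegative integers")
  X_count <- .with_intercept(X_count, n, "x")
  X_zero <- .with_intercept(X_zero, n, "z")
  structure(list(y = y, X_count = X_count, X_zero = X_zero), class = "zic_data")
}

.with_intercept <- function(X, n, prefix) {
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
  }
  if (nrow(X) != n) stop("design matrix must have length(y) rows")
  if (ncol(X) && any(!is.finite(X))) stop("non-finite entries in design matrix")
  if (is.null(colnames(X)) && ncol(X))
    colnames(X) <- paste0(prefix, seq_len(ncol(X)))
  cbind("(Intercept)" = rep(1, n), X)
}

#' @export
print.zic_data <- function(x, ...) {
  cat(sprintf(
    "zic_data: n = %d, count covariates = %d, zero covariates = %d, zero fraction = %.3f\n",
    length(x$y), ncol(x$X_count) - 1L, ncol(x$X_zero) - 1L, mean(x$y == 0)))
  invisible(x)
}

#' Read a delimited phenotype/covariate table into a `zic_data` object
#'
#' @param file Path to a delimited text file with a header row.
#' @param response Name of the count-response column.
#' @param count_cols Character vector of column names entering the count
#'   component. Default: all non-response columns.
#' @param zero_cols Character vector of column names entering the zero
#'   component. Default: none (intercept-only zero model).
#' @param sep Field separator, default comma.
#' @return A `zic_data` object.
#' @export
read_zic_csv <- function(file, response, count_cols = NULL, zero_cols = character(),
                         sep = ",") {
  tab <- utils::read.table(file, header = TRUE, sep = sep, check.names = FALSE)
  if (!response %in% names(tab)) stop("response column not found: ", response)
  if (is.null(count_cols)) count_cols <- setdiff(names(tab), response)
  missing <- setdiff(c(count_cols, zero_cols), names(tab))
  if (length(missing)) stop("columns not found: ", paste(missing, collapse = ", "))
  Xc <- if (length(count_cols)) as.matrix(tab[count_cols]) else NULL
  Xz <- if (length(zero_cols)) as.matrix(tab[zero_cols]) else NULL
  zic_data(tab[[response]], Xc, Xz)
}
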