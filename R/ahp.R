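#' Pairwise comparison matrices
#'
#' Validates (and optionally repairs) a positive reciprocal matrix of
#' relative importances in the AHP sense: unit diagonal, all entries
#' positive, and `a[j, i] == 1 / a[i, j]`. Entries are conventionally
#' drawn from the Saaty 1-9 scale and its reciprocals; values beyond
#' that range (above 9 or below 1/9) trigger a warning, not an error.
#' Intermediate continuous ratios are accepted silently, since ratio
#' matrices built from numeric weight vectors are legitimate inputs.
#'
#' @param x square numeric matrix (or something coercible to one).
#'   Row/column names, when present, are kept and become the names of the
#'   derived weight vector.
#' @param symmetrize if `TRUE`, replace each pair by the geometric mean
#'   `sqrt(a[i, j] / a[j, i])` and its reciprocal before validation,
#'   which repairs small asymmetries in hand-entered matrices. Off by
#'   default.
#' @param tol reciprocity tolerance (relative), default `1e-9`.
#' @return The matrix with class `pairwise_matrix`.
#' @export
#' @examples
#' m <- pairwise_matrix(rbind(c(1, 2, 4), c(1/2, 1, 2), c(1/4, 1/2, 1)))
#' derive_weights(m)     # 4/7, 2/7, 1/7: perfectly consistent
pairwise_matrix <- function(x, symmetrize = FALSE, tol = 1e-9) {
  m <- as.matrix(x)
  if (!is.numeric(m) || nrow(m) != ncol(m) || nrow(m) < 1L)
    stop("a pairwise comparison matrix must be square and numeric",
         call. = FALSE)
  if (anyNA(m) || any(!is.finite(m)) || any(m <= 0))
    stop("all entries of a pairwise comparison matrix must be finite ",
         "and > 0", call. = FALSE)
  n <- nrow(m)
  if (symmetrize) {
    g <- sqrt(m / t(m))
    m <- g
    diag(m) <- 1
  }
  if (any(abs(diag(m) - 1) > tol))
    stop("diagonal entries must equal 1", call. = FALSE)
  rel <- abs(m * t(m) - 1)
  if (any(rel > tol * pmax(1, m * t(m))))
    stop("matrix is not reciprocal: a[j,i] must equal 1/a[i,j] ",
         "(within ", format(tol), "); use symmetrize = TRUE to repair ",
         "small asymmetries", call. = FALSE)
  if (any(m > 9 + 1e-9 | m < 1 / 9 - 1e-9))
    warning("entries outside the Saaty scale range [1/9, 9]; ",
            "weights are still computed", call. = FALSE)
  class(m) <- c("pairwise_matrix", class(m))
  m
}

# Power iteration for the Perron (dominant) eigenpair of a positive
# matrix. Deterministic: starts from the uniform vector; converges
# geometrically for any positive matrix.
.power_iterate <- function(m, tol = 1e-12, max_iter = 10000L) {
  n <- nrow(m)
  if (n == 1L)
    return(list(w = stats::setNames(1, rownames(m)), lambda = m[1, 1],
                iterations = 0L))
  w <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    v <- as.numeric(m %*% w)
    v <- v / sum(v)
    if (max(abs(v - w)) < tol) {
      lambda <- sum(m %*% v)  # v sums to 1, so sum(Av) = Rayleigh value
      return(list(w = stats::setNames(v, rownames(m)), lambda = lambda,
                  iterations = it))
    }
    w <- v
  }
  stop("power iteration failed to converge in ", max_iter,
       " iterations for a ", n, "x", n, " matrix", call. = FALSE)
}

#' Derive criterion weights from a pairwise comparison matrix
#'
#' Computes the principal right eigenvector of the comparison matrix,
#' normalized to sum 1 — the classical AHP weight vector. For a perfectly
#' consistent matrix (`a[i, j] = w[i] / w[j]`) this recovers `w` exactly;
#' by the Perron-Frobenius theorem all components are strictly positive
#' for any positive matrix.
#'
#' @param m a [pairwise_matrix] (or a plain matrix, validated on entry).
#' @param tol convergence tolerance of the power iteration on the
#'   eigenvector (sup norm), default `1e-12`.
#' @param max_iter iteration cap, default 10000.
#' @return Named numeric vector of weights summing to 1.
#' @seealso [lambda_max()], [consistency_report()]
#' @export
derive_weights <- function(m, tol = 1e-12, max_iter = 10000L) {
  if (!inherits(m, "pairwise_matrix")) m <- pairwise_matrix(m)
  .power_iterate(m, tol = tol, max_iter = max_iter)$w
}

#' Principal eigenvalue of a comparison matrix
#'
#' The dominant eigenvalue \eqn{\lambda_{max}} of a positive reciprocal
#' matrix is always at least the order `n`, with equality exactly when
#' the matrix is consistent; the excess drives the consistency index.
#'
#' @inheritParams derive_weights
#' @return The dominant eigenvalue (a scalar).
#' @export
lambda_max <- function(m, tol = 1e-12, max_iter = 10000L) {
  if (!inherits(m, "pairwise_matrix")) m <- pairwise_matrix(m)
  .power_iterate(m, tol = tol, max_iter = max_iter)$lambda
}

#' Consistency index CI
#'
#' `CI = (lambda_max - n) / (n - 1)` for order `n >= 2`; a 1x1 matrix is
#' trivially consistent, so `CI = 0` by convention.
#'
#' @param lambda_max dominant eigenvalue of the matrix.
#' @param n matrix order (number of criteria compared).
#' @return The consistency index (non-negative scalar).
#' @export
consistency_index <- function(lambda_max, n) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("`n` must be a single integer >= 1", call. = FALSE)
  if (lambda_max < n - 1e-9)
    stop("lambda_max (", format(lambda_max), ") cannot be below the ",
         "matrix order n = ", n, call. = FALSE)
  if (n == 1) return(0)
  (lambda_max - n) / (n - 1)
}

#' Saaty's average random consistency index table
#'
#' Expected CI of randomly filled reciprocal matrices, for orders 1-9
#' (the largest sibling group in the bundled model has nine criteria).
#' Used as the denominator of the consistency ratio.
#'
#' @return Named numeric vector `RI[n]` for `n = 1..9`.
#' @export
saaty_ri <- function() {
  stats::setNames(c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45),
                  as.character(1:9))
}

#' Consistency ratio CR and verdict
#'
#' `CR = CI / RI(n)`. Judgments are conventionally acceptable when
#' `CR < 0.1`. For `n <= 2` the random index is zero and a reciprocal
#' matrix is automatically consistent, so `CR` is reported as 0 and the
#' verdict depends on `CI` alone.
#'
#' @param ci consistency index, see [consistency_index()].
#' @param n matrix order.
#' @param ri_table random-index lookup table indexed by order; defaults
#'   to [saaty_ri()]. Supply a longer vector for matrices above order 9.
#' @return List with elements `RI`, `CR` and logical `consistent`.
#' @export
consistency_ratio <- function(ci, n, ri_table = saaty_ri()) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("`n` must be a single integer >= 1", call. = FALSE)
  if (n > length(ri_table))
    stop("no random index for order n = ", n, "; the table covers ",
         "orders 1-", length(ri_table),
         ". Supply `ri_table` with an RI value for this order.",
         call. = FALSE)
  ri <- as.numeric(ri_table[[n]])
  if (ri > 0) {
    cr <- ci / ri
    list(RI = ri, CR = cr, consistent = cr < 0.1)
  } else {
    list(RI = ri, CR = 0, consistent = ci <= 1e-9)
  }
}

#' Full consistency diagnostics for a comparison matrix
#'
#' Convenience wrapper computing the dominant eigenvalue, CI, RI, CR and
#' the acceptability verdict in one call.
#'
#' @inheritParams derive_weights
#' @inheritParams consistency_ratio
#' @return An object of class `consistency_report`: list with
#'   `lambda_max`, `n`, `CI`, `RI`, `CR`, `consistent` and the derived
#'   `weights`.
#' @export
#' @examples
#' m <- pairwise_matrix(rbind(c(1, 3, 5), c(1/3, 1, 2), c(1/5, 1/2, 1)))
#' consistency_report(m)
consistency_report <- function(m, ri_table = saaty_ri(), tol = 1e-12,
                               max_iter = 10000L) {
  if (!inherits(m, "pairwise_matrix")) m <- pairwise_matrix(m)
  n <- nrow(m)
  pe <- .power_iterate(m, tol = tol, max_iter = max_iter)
  ci <- consistency_index(max(pe$lambda, n), n)
  cr <- consistency_ratio(ci, n, ri_table)
  structure(
    list(lambda_max = pe$lambda, n = n, CI = ci, RI = cr$RI, CR = cr$CR,
         consistent = cr$consistent, weights = pe$w),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, digits = 4, ...) {
  cat("<consistency_report> n =", x$n, "\n")
  cat(sprintf("  lambda_max = %.*f   CI = %.*f   RI = %.*f   CR = %.*f\n",
              digits, x$lambda_max, digits, x$CI, digits, x$RI,
              digits, x$CR))
  cat("  verdict:", if (x$consistent) "consistent (CR < 0.1)"
      else "NOT consistent (CR >= 0.1)", "\n")
  cat("  weights:", paste(sprintf("%.*f", digits, x$weights),
                          collapse = " "), "\n")
  invisible(x)
}

#' Read / write pairwise comparison matrices as delimited tables
#'
#' The on-disk format is a square delimited table whose header row gives
#' the criterion ids; the delimiter is taken from the file extension
#' (`.csv` comma, anything else tab) unless given explicitly.
#'
#' @param path file path.
#' @param sep field delimiter, `NULL` to infer from the extension.
#' @param ... passed on to [pairwise_matrix()] (e.g. `symmetrize`).
#' @return `read_pairwise_matrix()` returns a [pairwise_matrix];
#'   `write_pairwise_matrix()` returns `path` invisibly.
#' @export
read_pairwise_matrix <- function(path, sep = NULL, ...) {
  if (!file.exists(path))
    stop("matrix file not found: ", path, call. = FALSE)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, strip.white = TRUE)
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("matrix file '", path, "' contains non-numeric entries",
         call. = FALSE)
  if (nrow(m) != ncol(m))
    stop("matrix file '", path, "' is not square: ", nrow(m), " rows x ",
         ncol(m), " columns", call. = FALSE)
  rownames(m) <- colnames(m)
  pairwise_matrix(m, ...)
}

#' @rdname read_pairwise_matrix
#' @param m a [pairwise_matrix] (or plain square matrix).
#' @export
write_pairwise_matrix <- function(m, path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(unclass(m)), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
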