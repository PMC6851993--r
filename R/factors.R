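# Raw varimax criterion: sum over factors of the variance of squared
# loadings within the column.
.varimax_criterion <- function(L) {
  p <- nrow(L)
  sum(colSums(L^4) - colSums(L^2)^2 / p)
}

# Normalize a loading matrix for reporting: columns ordered by explained
# variance (descending), sign chosen so the largest-|loading| item in
# each column is positive.
.normalize_loadings <- function(L) {
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  colnames(L) <- sprintf("F%d", seq_len(ncol(L)))
  L
}

#' Principal-component factor extraction
#'
#' Extracts `k` factors from pooled item-level rating-scale rows using
#' the principal component method: loadings are the eigenvectors of the
#' Pearson correlation matrix scaled by the square roots of their
#' eigenvalues, keeping the top `k` eigenvalues.  Rows with any missing
#' item are dropped.  The combined explained variance is the sum of the
#' retained eigenvalues divided by the number of items.  The number of
#' factors `k` is a configuration input, conventionally chosen from the
#' elbow of the scree plot (see [scree_eigenvalues()]); it is not
#' automated.
#'
#' @param item_table Numeric matrix or data frame, pooled visits x items.
#' @param k Number of factors, `1 <= k <=` number of items.
#' @param rotation `"varimax"` (default) or `"none"`.
#' @return An object of class `factor_solution`: `loadings` (items x k,
#'   sign/order normalized), `explained_variance` (per factor),
#'   `combined_explained_variance`, `eigenvalues` (full spectrum),
#'   `rotation`, `item_ids`, `k`, `n_rows`.
#' @seealso [varimax_rotate()], [score_factors()]
#' @export
extract_factors <- function(item_table, k,
                            rotation = c("varimax", "none")) {
  rotation <- match.arg(rotation)
  X <- as.matrix(item_table)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  p <- ncol(X)
  if (k < 1 || k > p) stop("k must be between 1 and the number of items")
  if (nrow(X) < k + 1) stop("need at least k + 1 complete rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(X)[which(sds == 0)]
    if (is.null(nm)) nm <- which(sds == 0)
    stop("constant item(s) with zero variance: ",
         paste(nm, collapse = ", "))
  }
  R <- stats::cor(X)
  eg <- eigen(R, symmetric = TRUE)
  L <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
  rownames(L) <- colnames(X)
  if (rotation == "varimax" && k >= 2) L <- varimax_rotate(L)
  L <- .normalize_loadings(L)
  structure(list(loadings = L,
                 explained_variance = colSums(L^2) / p,
                 combined_explained_variance =
                   sum(eg$values[seq_len(k)]) / p,
                 eigenvalues = eg$values,
                 rotation = rotation,
                 item_ids = rownames(L), k = k, n_rows = nrow(X)),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Factor solution: %d factors on %d items (%s rotation), %d rows\n",
    x$k, length(x$item_ids), x$rotation, x$n_rows))
  cat(sprintf("Combined explained variance: %.1f%%\n",
              100 * x$combined_explained_variance))
  print(round(x$loadings, digits))
  invisible(x)
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the (raw) varimax criterion — the
#' summed within-column variance of squared loadings — to push each item
#' toward a single dominant factor.  Communalities (row sums of squared
#' loadings) are preserved exactly by orthogonality.  Columns of the
#' result are ordered by explained variance and signed so the
#' largest-|loading| item is positive.  `k = 1` returns the input.
#'
#' @param loadings Items x k numeric matrix, finite.
#' @return Rotated loading matrix with the same dimensions.
#' @export
varimax_rotate <- function(loadings) {
  L <- as.matrix(loadings)
  if (any(!is.finite(L))) stop("loadings must be finite")
  if (ncol(L) < 2) return(L)
  rot <- stats::varimax(L, normalize = FALSE, eps = 1e-10)
  .normalize_loadings(L %*% rot$rotmat)
}

#' Loading-weighted factor score
#'
#' A factor subscore is the sum of the raw item scores weighted by the
#' item's loading on that factor.  With unit loadings this reduces to the
#' plain subtotal.
#'
#' @param item_scores Numeric vector of raw item scores aligned with
#'   `solution$item_ids`, or a rows x items matrix.
#' @param solution A [factor_solution()][extract_factors()].
#' @param factor_index Column of the loading matrix to score.
#' @return Numeric score (one per row when a matrix is given).
#' @export
score_factors <- function(item_scores, solution, factor_index = 1) {
  stopifnot(inherits(solution, "factor_solution"))
  w <- solution$loadings[, factor_index]
  if (is.matrix(item_scores) || is.data.frame(item_scores)) {
    X <- as.matrix(item_scores)
    if (ncol(X) != length(w))
      stop("item columns do not align with the factor solution")
    if (!is.null(colnames(X)) && !is.null(solution$item_ids) &&
        !identical(colnames(X), solution$item_ids))
      stop("item names do not align with the factor solution")
    return(drop(X %*% w))
  }
  if (length(item_scores) != length(w))
    stop("item scores do not align with the factor solution")
  sum(w * item_scores)
}

#' Eigenvalue spectrum for scree inspection
#'
#' Full ordered eigenvalues of the pooled item correlation matrix, for
#' choosing the number of factors from the scree elbow.  Eigenvalues sum
#' to the number of items.
#'
#' @inheritParams extract_factors
#' @return Numeric vector of eigenvalues, decreasing.
#' @export
scree_eigenvalues <- function(item_table) {
  X <- as.matrix(item_table)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant item(s) with zero variance: ",
         paste(which(sds == 0), collapse = ", "))
  eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
}

#' Write a factor solution to CSV
#'
#' Items x factors loading table with a final row of per-factor explained
#' variance fractions.
#'
#' @param solution A [factor_solution()][extract_factors()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_factor_solution <- function(solution, path) {
  stopifnot(inherits(solution, "factor_solution"))
  tab <- as.data.frame(solution$loadings)
  tab <- rbind(tab, as.list(solution$explained_variance))
  tab <- cbind(item = c(solution$item_ids, "explained_variance"), tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
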