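#' Matricize a purchase tensor for standard PCA
#'
#' Three flattenings, one row per customer: `sum_over_weeks` (annual total
#' per product group, `n x p`), `sum_over_groups` (weekly total, `n x t`),
#' and `vectorized` (every group-week cell, `n x (p t)`, columns ordered
#' week-major to match column-stacking of the `p x t` slices, so Kronecker
#' identities with the tensorial loadings hold without permutation).
#'
#' @param tensor a [purchase_tensor()].
#' @param scheme one of `"sum_over_weeks"`, `"sum_over_groups"`,
#'   `"vectorized"`.
#' @return list of class `matricized` with fields `scheme`, `data` (matrix
#'   with customer rownames and provenance-carrying column names).
#' @export
matricize <- function(tensor,
                      scheme = c("sum_over_weeks", "sum_over_groups",
                                 "vectorized")) {
  scheme <- match.arg(scheme)
  v <- tensor$values
  d <- dim(v)
  data <- switch(scheme,
    sum_over_weeks = {
      m <- apply(v, c(1L, 2L), sum)
      colnames(m) <- tensor$groups
      m
    },
    sum_over_groups = {
      m <- apply(v, c(1L, 3L), sum)
      colnames(m) <- paste0("w", tensor$weeks)
      m
    },
    vectorized = {
      m <- matrix(aperm(v, c(1L, 2L, 3L)), d[1L], d[2L] * d[3L])
      colnames(m) <- paste0(rep(tensor$groups, times = d[3L]), "@w",
                            rep(tensor$weeks, each = d[2L]))
      m
    })
  rownames(data) <- tensor$customer_ids
  structure(list(scheme = scheme, data = data), class = "matricized")
}

#' Standard PCA of matricized data
#'
#' Column-centers the matrix, eigendecomposes the sample covariance
#' (denominator `n - 1`) and applies the same eigenvector sign convention
#' as the tensorial fit; scores are the centered data times the loadings.
#'
#' @param matricized a `matricized` object (or plain matrix).
#' @param k number of components to retain.
#' @return list of class `std_pca` with `loadings` (columns orthonormal,
#'   sign-fixed), `scores` (`n x k`), the full `eigenvalues` spectrum and
#'   per-component `explained` fractions.
#' @export
standard_pca <- function(matricized, k) {
  X <- if (inherits(matricized, "matricized")) matricized$data else
    as.matrix(matricized)
  k <- as.integer(k)
  if (k < 1L || k > ncol(X)) stop("k must be in 1..ncol")
  Xc <- sweep(X, 2L, colMeans(X))
  S <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(S, symmetric = TRUE)
  V <- fix_signs(e$vectors[, seq_len(k), drop = FALSE])
  rownames(V) <- colnames(X)
  colnames(V) <- paste0("PC", seq_len(k))
  ev <- pmax(e$values, 0)
  structure(list(loadings = V, scores = Xc %*% V,
                 eigenvalues = e$values,
                 explained = ev / sum(ev),
                 scheme = if (inherits(matricized, "matricized"))
                   matricized$scheme else NA_character_),
            class = "std_pca")
}

#' Correlation between tensorial and standard PCA scores
#'
#' Pearson correlation between the tensorial score of one
#' (product-component, time-component) pair and one standard-PCA score
#' column. Since loading signs are a convention on both sides, the absolute
#' value is reported alongside.
#'
#' @param tpca_scores a `tpca_scores` array.
#' @param pca a `std_pca` result (or a score matrix).
#' @param pair tensorial component pair, default the (1,1) component.
#' @param component standard-PCA component index, default 1.
#' @return list with `r` and `abs_r`.
#' @export
score_correlation <- function(tpca_scores, pca, pair = c(1, 1),
                              component = 1) {
  s1 <- score_vector(tpca_scores, pair)
  S <- if (inherits(pca, "std_pca")) pca$scores else as.matrix(pca)
  if (length(s1) != nrow(S)) stop("score vectors must have equal length")
  s2 <- S[, component]
  if (stats::sd(s1) == 0 || stats::sd(s2) == 0)
    stop("zero-variance scores: correlation undefined")
  r <- stats::cor(s1, s2)
  list(r = r, abs_r = abs(r))
}

#' Compare tensorial PCA with standard PCA on matricized data
#'
#' Runs standard PCA on the three matricizations and correlates each
#' scheme's leading scores with the tensorial (1,1) component (the product
#' pattern weighted by the weekly-average time direction). The qualitative
#' capability flags record which kinds of pattern each flattening can
#' express: schemes that retain the product axis can find product patterns,
#' schemes that retain the week axis can find time patterns, and only the
#' vectorized scheme (like the tensorial model) addresses
#' product-group-specific time trends.
#'
#' @param tensor a [purchase_tensor()].
#' @param model a fitted `tpca` model on the same tensor.
#' @param scores optional precomputed [tpca_project()] scores.
#' @param k components retained per scheme (default 3, capped at the column
#'   count).
#' @return list of class `pca_comparison`: per-scheme `std_pca` results,
#'   a data.frame `correlations` (scheme, |r| against the tensorial (1,1)
#'   scores for PCA component 1), and the capability table.
#' @export
compare_pca <- function(tensor, model, scores = NULL, k = 3) {
  if (is.null(scores)) scores <- tpca_project(model, tensor)
  schemes <- c("sum_over_weeks", "sum_over_groups", "vectorized")
  fits <- lapply(schemes, function(sch) {
    m <- matricize(tensor, sch)
    standard_pca(m, min(k, ncol(m$data)))
  })
  names(fits) <- schemes
  corr <- do.call(rbind, lapply(schemes, function(sch) {
    sc <- score_correlation(scores, fits[[sch]], pair = c(1, 1),
                            component = 1)
    data.frame(scheme = sch, r = sc$r, abs_r = sc$abs_r,
               explained_pc1 = fits[[sch]]$explained[1L],
               stringsAsFactors = FALSE)
  }))
  capability <- data.frame(
    scheme = c(schemes, "tensorial"),
    product_patterns = c(TRUE, FALSE, TRUE, TRUE),
    time_patterns = c(FALSE, TRUE, TRUE, TRUE),
    pattern_specific_trends = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  structure(list(fits = fits, correlations = corr, capability = capability),
            class = "pca_comparison")
}

#' @export
print.pca_comparison <- function(x, ...) {
  cat("standard-PCA comparison (|r| vs tensorial (1,1) scores):\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
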