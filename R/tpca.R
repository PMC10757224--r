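#' Center a purchase tensor over customers
#'
#' Subtracts the elementwise mean slice `M` (the `p x t` average over all
#' customers) from every customer slice.
#'
#' @param tensor a [purchase_tensor()] with at least two customers.
#' @return object of class `centered_tensor` with fields `values`
#'   (`n x p x t`, customer means all zero), `mean_matrix` and labels.
#' @export
center_tensor <- function(tensor) {
  if (inherits(tensor, "centered_tensor")) return(tensor)
  v <- tensor$values
  n <- dim(v)[1L]
  if (n < 2L) stop("centering needs at least 2 customers")
  M <- apply(v, c(2L, 3L), mean)
  centered <- v - rep(M, each = n)
  structure(list(values = centered, mean_matrix = M,
                 customer_ids = tensor$customer_ids,
                 groups = tensor$groups, weeks = tensor$weeks),
            class = "centered_tensor")
}

# unfold centered values to mode x (other * n)
unfold_mode <- function(values, mode) {
  d <- dim(values)
  if (mode == 1L) {
    matrix(aperm(values, c(2L, 3L, 1L)), d[2L], d[3L] * d[1L])
  } else {
    matrix(aperm(values, c(3L, 2L, 1L)), d[3L], d[2L] * d[1L])
  }
}

#' Modal covariance matrix of a centered tensor
#'
#' Mode 1 aggregates over weeks: `S1 = (1/(n t)) sum_i Y_i Y_i^T` measures
#' linear dependency among product groups. Mode 2 aggregates over groups:
#' `S2 = (1/(n p)) sum_i Y_i^T Y_i`. Both are symmetric positive
#' semidefinite; eigenvectors and explained-variance fractions do not depend
#' on the normalization constant, and under iid entrywise noise the
#' eigenvalues sit on the per-entry variance scale.
#'
#' @param centered a `centered_tensor` from [center_tensor()].
#' @param mode 1 (product groups) or 2 (weeks).
#' @return symmetric `p x p` or `t x t` matrix.
#' @export
modal_covariance <- function(centered, mode) {
  if (!inherits(centered, "centered_tensor"))
    stop("`centered` must come from center_tensor()")
  if (!mode %in% c(1L, 2L)) stop("mode must be 1 or 2")
  d <- dim(centered$values)
  U <- unfold_mode(centered$values, as.integer(mode))
  denom <- if (mode == 1L) d[1L] * d[3L] else d[1L] * d[2L]
  S <- tcrossprod(U) / denom
  (S + t(S)) / 2
}

# Sign convention: in each eigenvector the entry of largest absolute value
# (lowest index on ties) is made positive, so loadings are reproducible
# across linear-algebra backends.
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Fit a tensorial PCA model
#'
#' Centers the tensor, eigendecomposes both modal covariance matrices and
#' retains the leading `p0` product directions and `t0` time directions.
#' Scores for each customer are the bilinear projections
#' `Z_i = U1^T (Y_i - M) U2`, one score per (product-component,
#' time-component) pair; see [tpca_project()].
#'
#' @param tensor a [purchase_tensor()] (or `centered_tensor`).
#' @param p0 number of product components, `1 <= p0 <= p`.
#' @param t0 number of time components, `1 <= t0 <= t`.
#' @return object of class `tpca` with the mean matrix, loading matrices
#'   `U1` (`p x p0`) and `U2` (`t x t0`), both full eigenvalue spectra,
#'   per-mode explained-variance fractions of the selected components, and
#'   the dimension labels.
#' @export
fit_tpca <- function(tensor, p0, t0) {
  centered <- center_tensor(tensor)
  d <- dim(centered$values)
  p0 <- as.integer(p0); t0 <- as.integer(t0)
  if (p0 < 1L || p0 > d[2L]) stop("p0 must be in 1..p")
  if (t0 < 1L || t0 > d[3L]) stop("t0 must be in 1..t")
  e1 <- eigen(modal_covariance(centered, 1L), symmetric = TRUE)
  e2 <- eigen(modal_covariance(centered, 2L), symmetric = TRUE)
  U1 <- fix_signs(e1$vectors[, seq_len(p0), drop = FALSE])
  U2 <- fix_signs(e2$vectors[, seq_len(t0), drop = FALSE])
  dimnames(U1) <- list(centered$groups, paste0("PC", seq_len(p0)))
  dimnames(U2) <- list(paste0("w", centered$weeks), paste0("PC", seq_len(t0)))
  ev1 <- pmax(e1$values, 0); ev2 <- pmax(e2$values, 0)
  structure(list(
    mean_matrix = centered$mean_matrix,
    U1 = U1, U2 = U2,
    eigenvalues = list(mode1 = e1$values, mode2 = e2$values),
    explained = list(mode1 = sum(ev1[seq_len(p0)]) / sum(ev1),
                     mode2 = sum(ev2[seq_len(t0)]) / sum(ev2)),
    p0 = p0, t0 = t0,
    groups = centered$groups, weeks = centered$weeks,
    n = d[1L]), class = "tpca")
}

#' @export
print.tpca <- function(x, ...) {
  cat(sprintf("tpca model: %d x %d components (groups x weeks), n = %d\n",
              x$p0, x$t0, x$n))
  cat(sprintf("  explained variance: %.1f%% (product mode), %.1f%% (time mode)\n",
              100 * x$explained$mode1, 100 * x$explained$mode2))
  invisible(x)
}

#' Project a tensor onto a fitted tensorial PCA model
#'
#' Computes `Z_i = U1^T (Y_i - M) U2` for every customer slice.
#'
#' @param model a `tpca` model.
#' @param tensor a [purchase_tensor()] with the same group and week labels.
#' @return object of class `tpca_scores`: an `n x p0 x t0` array, dimension
#'   names `(customer, product component, time component)`.
#' @export
tpca_project <- function(model, tensor) {
  if (!identical(tensor$groups, model$groups) ||
      !identical(tensor$weeks, model$weeks))
    stop("tensor labels do not match the fitted model")
  v <- tensor$values
  n <- dim(v)[1L]
  centered <- v - rep(model$mean_matrix, each = n)
  p0 <- model$p0; t0 <- model$t0
  scores <- array(0, dim = c(n, p0, t0),
                  dimnames = list(tensor$customer_ids,
                                  colnames(model$U1), colnames(model$U2)))
  for (i in seq_len(n)) {
    scores[i, , ] <- crossprod(model$U1, centered[i, , ]) %*% model$U2
  }
  class(scores) <- c("tpca_scores", class(scores))
  scores
}

#' @rdname tpca_project
#' @param object,... S3 method arguments; `...` must contain `tensor`.
#' @export
predict.tpca <- function(object, tensor, ...) tpca_project(object, tensor)

#' Reconstruct a tensor from scores
#'
#' Inverse of the projection map: `Y_i ~ M + U1 Z_i U2^T`. Exact when the
#' model has full rank in both modes.
#'
#' @param model a `tpca` model.
#' @param scores a `tpca_scores` array with matching component counts.
#' @return an `n x p x t` numeric array with the model's dimension labels
#'   (reconstructions may be slightly negative; they are approximations,
#'   not purchase tensors).
#' @export
tpca_reconstruct <- function(model, scores) {
  d <- dim(scores)
  if (d[2L] != model$p0 || d[3L] != model$t0)
    stop("score dimensions do not match the model ranks")
  n <- d[1L]
  out <- array(0, dim = c(n, nrow(model$U1), nrow(model$U2)),
               dimnames = list(dimnames(scores)[[1L]],
                               model$groups, paste0("w", model$weeks)))
  for (i in seq_len(n)) {
    out[i, , ] <- model$mean_matrix +
      model$U1 %*% scores[i, , ] %*% t(model$U2)
  }
  out
}

#' Distance between the subspaces spanned by two orthonormal bases
#'
#' Frobenius norm of the difference of the orthogonal projectors;
#' zero iff the column spans coincide.
#'
#' @param U,V matrices with the same number of rows and orthonormal columns.
#' @return nonnegative scalar.
#' @export
subspace_distance <- function(U, V) {
  PU <- tcrossprod(U)
  PV <- tcrossprod(V)
  sqrt(sum((PU - PV)^2))
}
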