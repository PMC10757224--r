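#' Augmentation (ladle-type) estimate of the number of components in a mode
#'
#' Chooses the mode-wise rank by combining the eigenvalue scree with a
#' measure of eigenvector stability under data augmentation. The noise
#' scale is estimated as the mean of the smallest `ceil(d/2)` eigenvalues of
#' the mode's modal covariance (`d` = mode dimension). Each of `M` replicates
#' appends `r` rows (mode 1) or columns (mode 2) of iid centered Gaussian
#' noise at that scale to every centered slice and eigendecomposes the
#' augmented modal covariance; true signal eigenvectors barely leak into the
#' appended pure-noise coordinates, noise eigenvectors leak heavily.
#' For `k = 0..K_max` the criterion is
#' `g(k) = w_f * f_tilde(k) + w_phi * phi(k)`, where `f(k)` is the average
#' cumulative squared norm of the augmented coordinate blocks of the leading
#' `k` eigenvectors (`f(0) = 0`), `f_tilde` is `f` normalized by
#' `1 + sum(f)`, and `phi(k) = lambda_(k+1) / sum_{j<=K_max+1} lambda_j`
#' uses the original (non-augmented) spectrum. The estimate is the argmin,
#' with ties resolved toward the smaller rank.
#'
#' @param tensor a [purchase_tensor()] or `centered_tensor`.
#' @param mode 1 (product groups) or 2 (weeks).
#' @param r number of appended noise coordinates; default
#'   `max(1, ceiling(d / 5))`.
#' @param M number of augmentation replicates (default 50; at least 2).
#' @param K_max largest candidate rank; default `min(d - 1, 30)`.
#' @param seed integer seed for the augmentation noise.
#' @param weights length-2 nonnegative weights for `(f_tilde, phi)`;
#'   equal weighting by default.
#' @return object of class `order_selection`: `k_hat`, the criterion curve
#'   `g` with components `f_tilde` and `phi` (indexed `k = 0..K_max`), the
#'   replicate count, augmentation size, noise scale `sigma_hat` and seed.
#' @export
augmentation_order <- function(tensor, mode, r = NULL, M = 50, K_max = NULL,
                               seed = 1L, weights = c(1, 1)) {
  if (!mode %in% c(1L, 2L)) stop("mode must be 1 or 2")
  if (M < 2) stop("need at least 2 augmentation replicates")
  if (length(weights) != 2L || any(weights < 0))
    stop("weights must be two nonnegative numbers")
  centered <- center_tensor(tensor)
  dims <- dim(centered$values)
  n <- dims[1L]
  d <- if (mode == 1L) dims[2L] else dims[3L]
  other <- if (mode == 1L) dims[3L] else dims[2L]
  if (is.null(r)) r <- max(1L, ceiling(d / 5))
  r <- as.integer(r)
  if (is.null(K_max)) K_max <- min(d - 1L, 30L)
  K_max <- as.integer(K_max)
  if (K_max < 1L || K_max >= d) stop("K_max must be in 1..(d-1)")
  U <- unfold_mode(centered$values, as.integer(mode))   # d x (other*n)
  denom <- n * other
  lambda <- eigen(tcrossprod(U) / denom, symmetric = TRUE,
                  only.values = TRUE)$values
  if (max(abs(lambda)) <= 0)
    stop("degenerate all-zero tensor: no variation to analyse")
  n_small <- ceiling(d / 2)
  sigma_hat <- sqrt(max(mean(sort(lambda)[seq_len(n_small)]), 0))
  if (sigma_hat <= 0) sigma_hat <- sqrt(max(lambda) * 1e-12)
  m_cols <- ncol(U)
  leak <- matrix(0, M, K_max)
  withr::with_seed(seed, {
    for (b in seq_len(M)) {
      N <- matrix(stats::rnorm(r * m_cols, sd = sigma_hat), r, m_cols)
      Ua <- rbind(U, N)
      Sa <- tcrossprod(Ua) / denom
      vecs <- eigen((Sa + t(Sa)) / 2, symmetric = TRUE)$vectors
      block <- vecs[(d + 1L):(d + r), seq_len(K_max), drop = FALSE]
      leak[b, ] <- colSums(block^2)
    }
  })
  f <- c(0, cumsum(colMeans(leak)))              # k = 0..K_max
  f_tilde <- f / (1 + sum(f))
  phi <- lambda[seq_len(K_max + 1L)] / sum(lambda[seq_len(K_max + 1L)])
  g <- weights[1L] * f_tilde + weights[2L] * phi
  k_hat <- which.min(g) - 1L                     # ties -> smallest k
  structure(list(mode = as.integer(mode), k_hat = k_hat, g = g,
                 f_tilde = f_tilde, f = f, phi = phi,
                 eigenvalues = lambda, M = as.integer(M), r = r,
                 K_max = K_max, sigma_hat = sigma_hat,
                 weights = weights, seed = as.integer(seed)),
            class = "order_selection")
}

#' @export
print.order_selection <- function(x, ...) {
  cat(sprintf("order_selection (mode %d): k_hat = %d (K_max = %d, M = %d, r = %d)\n",
              x$mode, x$k_hat, x$K_max, x$M, x$r))
  invisible(x)
}

#' Select the number of components for both modes
#'
#' Runs [augmentation_order()] on the product-group mode and the week mode.
#'
#' @inheritParams augmentation_order
#' @param seed root seed; the two modes use `seed` and `seed + 1`.
#' @return list with `p0_hat`, `t0_hat` and the two `order_selection`
#'   result objects (`mode1`, `mode2`).
#' @export
select_orders <- function(tensor, r = NULL, M = 50, K_max = NULL, seed = 1L,
                          weights = c(1, 1)) {
  centered <- center_tensor(tensor)
  res1 <- augmentation_order(centered, 1L, r = r, M = M, K_max = K_max,
                             seed = seed, weights = weights)
  res2 <- augmentation_order(centered, 2L, r = r, M = M, K_max = K_max,
                             seed = seed + 1L, weights = weights)
  list(p0_hat = res1$k_hat, t0_hat = res2$k_hat,
       mode1 = res1, mode2 = res2)
}

#' Scree elbow fallback
#'
#' Position of the largest consecutive eigenvalue ratio: the rank `k`
#' maximizing `lambda_k / lambda_(k+1)`. A crude cross-check for the
#' augmentation estimator on strong-signal data.
#'
#' @param eigenvalues nonincreasing nonnegative spectrum.
#' @param K_max largest rank considered (default all but the last value).
#' @return the elbow position (integer rank).
#' @export
scree_elbow <- function(eigenvalues, K_max = length(eigenvalues) - 1L) {
  lam <- pmax(eigenvalues[seq_len(K_max + 1L)], .Machine$double.eps)
  which.max(lam[seq_len(K_max)] / lam[-1L])
}
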