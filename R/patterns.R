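score_vector <- function(scores, pair) {
  d <- dim(scores)
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[1L] < 1L || pair[2L] < 1L ||
      pair[1L] > d[2L] || pair[2L] > d[3L])
    stop("component pair out of range for these scores")
  s <- scores[, pair[1L], pair[2L]]
  names(s) <- dimnames(scores)[[1L]]
  s
}

#' Stratify customers into high / typical / low by a component score
#'
#' Ranks customers by the score of one (product-component, time-component)
#' pair and labels the top `floor(q n)` as `"high"`, the bottom
#' `floor(q n)` as `"low"` and the remainder `"typical"` (the 10/80/10
#' split at the default `q = 0.10`). Score ties are broken by stable
#' customer order.
#'
#' @param scores a `tpca_scores` array from [tpca_project()].
#' @param pair integer pair `(j1, j2)` selecting the component.
#' @param q tail fraction, `0 <= q < 0.5`.
#' @return data.frame with columns `customer_id`, `score` and `label`
#'   (factor with levels low/typical/high), in original customer order.
#' @export
stratify <- function(scores, pair, q = 0.10) {
  if (q < 0 || q >= 0.5) stop("q must be in [0, 0.5)")
  s <- score_vector(scores, pair)
  n <- length(s)
  n_tail <- floor(q * n)
  ord <- order(s, seq_len(n))          # ascending, stable in customer order
  label <- rep("typical", n)
  if (n_tail > 0L) {
    label[ord[seq_len(n_tail)]] <- "low"
    label[ord[(n - n_tail + 1L):n]] <- "high"
  }
  data.frame(customer_id = names(s), score = unname(s),
             label = factor(label, levels = c("low", "typical", "high")),
             stringsAsFactors = FALSE)
}

#' Decile labels from a component score
#'
#' Rank-based split into 10 near-equal groups: decile 1 holds the lowest
#' scores and decile 10 the highest. When `n` is not a multiple of 10 the
#' remainder is absorbed by the lowest deciles (sizes differ by at most 1);
#' ties are broken by stable customer order.
#'
#' @inheritParams stratify
#' @return named integer vector of decile labels (1..10) in customer order.
#' @export
score_deciles <- function(scores, pair) {
  s <- score_vector(scores, pair)
  n <- length(s)
  if (n < 10L) stop("deciles need at least 10 customers")
  base <- n %/% 10L
  rem <- n %% 10L
  sizes <- rep(base, 10L) + c(rep(1L, rem), rep(0L, 10L - rem))
  ord <- order(s, seq_len(n))
  lab <- integer(n)
  lab[ord] <- rep(1:10, times = sizes)
  stats::setNames(lab, names(s))
}

#' Standardized expenditure profile of a customer group
#'
#' Standardizes every (group, week) cell across ALL customers (population
#' standard deviation; constant cells map to 0) and averages the z values
#' over the member set. The all-customer profile is exactly zero, so entries
#' read as "this group spends x SDs more/less than the average customer on
#' this cell".
#'
#' @param tensor a [purchase_tensor()].
#' @param members character vector of member customer ids (nonempty subset).
#' @return list of class `group_profile` with the `p x t` matrix `profile`
#'   and the member count `n_members`.
#' @export
group_profile <- function(tensor, members) {
  members <- as.character(members)
  if (length(members) == 0L) stop("member set must be nonempty")
  idx <- match(members, tensor$customer_ids)
  if (anyNA(idx)) stop("unknown customer id(s) in member set")
  v <- tensor$values
  n <- dim(v)[1L]
  mu <- apply(v, c(2L, 3L), mean)
  sd_pop <- sqrt(apply(v, c(2L, 3L), function(x) mean((x - mean(x))^2)))
  z <- (v - rep(mu, each = n)) / rep(ifelse(sd_pop > 0, sd_pop, 1), each = n)
  z <- z * rep((sd_pop > 0) * 1, each = n)
  profile <- apply(z[idx, , , drop = FALSE], c(2L, 3L), mean)
  dimnames(profile) <- list(tensor$groups, paste0("w", tensor$weeks))
  structure(list(profile = profile, n_members = length(members)),
            class = "group_profile")
}

#' Mean weekly percentage spent on a product subset, by decile
#'
#' For each customer and week, the percentage of that week's total spend
#' going to the named product subset; weeks in which a customer spent
#' nothing at all are excluded from that customer's average (an absent week
#' expresses no purchase composition). Cells are means over the customers
#' of each decile.
#'
#' @param tensor a [purchase_tensor()].
#' @param deciles named integer vector from [score_deciles()] (aligned with
#'   the tensor's customers).
#' @param subset nonempty character vector of product-group labels.
#' @return `10 x t` matrix of mean percentages (NaN where a decile has no
#'   contributing customer in a week).
#' @export
trajectory_by_decile <- function(tensor, deciles, subset) {
  subset <- as.character(subset)
  if (length(subset) == 0L) stop("product subset must be nonempty")
  if (length(bad <- setdiff(subset, tensor$groups)))
    stop("unknown group(s): ", paste(bad, collapse = ", "))
  if (length(deciles) != length(tensor$customer_ids))
    stop("decile labels do not align with the tensor's customers")
  tot <- apply(tensor$values, c(1L, 3L), sum)                  # n x t
  sub <- apply(tensor$values[, tensor$groups %in% subset, , drop = FALSE],
               c(1L, 3L), sum)
  pct <- ifelse(tot > 0, 100 * sub / tot, NA_real_)
  out <- matrix(NA_real_, 10L, ncol(pct),
                dimnames = list(paste0("D", 1:10),
                                paste0("w", tensor$weeks)))
  for (d in 1:10) {
    rows <- pct[deciles == d, , drop = FALSE]
    if (nrow(rows)) out[d, ] <- colMeans(rows, na.rm = TRUE)
  }
  out
}

#' Flag atypical weeks and product groups from loadings
#'
#' A label is atypical if its loading exceeds `threshold` in absolute value
#' in at least one of the first `n_components` columns of the corresponding
#' mode's loading matrix. On purchase data scaled per customer, holiday
#' weeks and dominant zero-inflated groups surface this way and are then
#' peeled before refitting.
#'
#' @param model a fitted `tpca` model (fitted to the unpeeled tensor).
#' @param threshold positive loading magnitude cutoff (default 0.3).
#' @param n_components how many leading components to scan per mode; scalar
#'   or pair `(product, time)`; defaults to all fitted components.
#' @return list with character vectors `groups` and integer vector `weeks`.
#' @export
flag_atypical <- function(model, threshold = 0.3, n_components = NULL) {
  if (threshold <= 0) stop("threshold must be positive")
  if (is.null(n_components)) n_components <- c(model$p0, model$t0)
  if (length(n_components) == 1L) n_components <- rep(n_components, 2L)
  n_components <- as.integer(n_components)
  if (n_components[1L] > model$p0 || n_components[2L] > model$t0)
    stop("n_components exceeds the fitted ranks")
  hit1 <- apply(abs(model$U1[, seq_len(n_components[1L]), drop = FALSE]) >
                  threshold, 1L, any)
  hit2 <- apply(abs(model$U2[, seq_len(n_components[2L]), drop = FALSE]) >
                  threshold, 1L, any)
  list(groups = model$groups[hit1], weeks = model$weeks[hit2])
}

#' Hierarchically cluster loading rows
#'
#' Agglomerative clustering of the rows of a loading matrix with
#' correlation distance `1 - Pearson(x, y)` and average linkage, for
#' ordering heat-map rows so that variables with similar patterns sit
#' together. Constant rows are assigned the maximal distance 1 to every
#' other row.
#'
#' @param loadings numeric matrix with at least 2 rows and 2 columns.
#' @return an [stats::hclust] object (merge tree, heights, leaf `order`).
#' @export
cluster_loadings <- function(loadings) {
  loadings <- as.matrix(loadings)
  if (nrow(loadings) < 2L) stop("need at least 2 rows to cluster")
  if (ncol(loadings) < 2L) stop("need at least 2 columns for correlation")
  sds <- apply(loadings, 1L, stats::sd)
  D <- matrix(1, nrow(loadings), nrow(loadings))
  ok <- sds > 0
  if (any(ok)) {
    C <- stats::cor(t(loadings[ok, , drop = FALSE]))
    D[ok, ok] <- 1 - C
  }
  diag(D) <- 0
  dimnames(D) <- list(rownames(loadings), rownames(loadings))
  stats::hclust(stats::as.dist(D), method = "average")
}
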