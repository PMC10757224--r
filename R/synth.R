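#' Configuration for the synthetic loyalty-card generator
#'
#' Bundles and validates all generative parameters. The generator draws
#' customer slices from the separable latent model
#' \deqn{Y_i = M + A Z_i B^T + E_i,}
#' where `A` (`p x p0`) and `B` (`t x t0`) have orthonormal columns built
#' from interpretable templates, the latent matrix `Z_i` has independent
#' zero-mean entries with the given standard deviations, and `E_i` is iid
#' Gaussian noise. Expenditure mode additionally clamps at zero, masks
#' zero-inflated product groups (tobacco/alcohol-like non-purchasers) and
#' boosts the holiday-week columns of the mean matrix.
#'
#' Latent standard deviations are assigned to (product-component,
#' time-component) pairs in row-major order: for ranks `(p0, t0)` the pair
#' `(j1, j2)` receives `latent_sds[(j1 - 1) * t0 + j2]`.
#'
#' @param n_customers number of customers `n`.
#' @param n_groups number of product groups `p`.
#' @param n_weeks number of weeks `t`.
#' @param true_ranks integer pair `(p0, t0)` of true mode-wise ranks.
#' @param latent_sds strictly decreasing positive sds, length `p0 * t0`.
#' @param noise_sd sd of the iid entrywise noise.
#' @param mean_matrix_scale overall scale of the nonnegative mean matrix, in
#'   currency units per group-week cell (default 2, i.e. an annual mean of
#'   roughly 1000 over 10 groups x 52 weeks).
#' @param holiday_weeks week indices carrying holiday spikes.
#' @param holiday_boost relative boost of the mean at holiday weeks; scalar
#'   or one value per holiday week. Defaults emulate spikes of 16\%, 16\%
#'   and 26\% above the average week at weeks 12, 25 and 51.
#' @param seasonal_amplitude relative amplitude in `[0, 1)` of the annual
#'   seasonal cycle of the mean matrix; alternate groups peak in winter and
#'   summer.
#' @param zero_inflation_prob per-group probability that a customer never
#'   purchases that group; scalar or length-`p` vector. The default inflates
#'   only the last three groups (labelled beer, wine_cider, cigarettes).
#' @param mode `"gaussian"` (exactly separable, may go negative) or
#'   `"expenditure"` (clamped, zero-inflated, holiday-boosted; nonnegative).
#' @param seed integer seed; identical configs generate identical tensors.
#'
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_customers = 500, n_groups = 10, n_weeks = 52,
                             true_ranks = c(3, 2),
                             latent_sds = c(8, 6, 4, 3, 2, 1),
                             noise_sd = 1, mean_matrix_scale = 2,
                             holiday_weeks = c(12, 25, 51),
                             holiday_boost = c(0.16, 0.16, 0.26),
                             seasonal_amplitude = 0.3,
                             zero_inflation_prob = NULL,
                             mode = c("expenditure", "gaussian"),
                             seed = 1L) {
  mode <- match.arg(mode)
  default_holidays <- missing(holiday_weeks)
  n <- as.integer(n_customers); p <- as.integer(n_groups)
  t <- as.integer(n_weeks)
  stopifnot(n >= 1, p >= 1, t >= 1)
  true_ranks <- as.integer(true_ranks)
  if (length(true_ranks) != 2L || any(true_ranks < 1L))
    stop("true_ranks must be two positive counts")
  if (true_ranks[1L] > p || true_ranks[2L] > t)
    stop("true_ranks must not exceed the tensor dimensions")
  k <- prod(true_ranks)
  if (length(latent_sds) != k)
    stop("latent_sds must have length p0 * t0 = ", k)
  if (any(latent_sds <= 0) || any(diff(latent_sds) >= 0))
    stop("latent_sds must be strictly decreasing positive reals")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (mean_matrix_scale < 0) stop("mean_matrix_scale must be nonnegative")
  holiday_weeks <- as.integer(holiday_weeks)
  if (default_holidays && length(holiday_weeks)) {
    keep <- holiday_weeks <= t            # default holidays pruned to range
    if (length(holiday_boost) == length(holiday_weeks))
      holiday_boost <- holiday_boost[keep]
    holiday_weeks <- holiday_weeks[keep]
  }
  if (length(setdiff(holiday_weeks, seq_len(t))))
    stop("holiday_weeks must lie in 1..n_weeks")
  if (length(holiday_boost) == 1L)
    holiday_boost <- rep(holiday_boost, length(holiday_weeks))
  if (length(holiday_boost) != length(holiday_weeks) || any(holiday_boost < 0))
    stop("holiday_boost must be nonnegative, one value per holiday week")
  if (seasonal_amplitude < 0 || seasonal_amplitude >= 1)
    stop("seasonal_amplitude must be in [0, 1)")
  if (is.null(zero_inflation_prob)) {
    zero_inflation_prob <- rep(0, p)
    vice <- (p - min(2L, p - 1L)):p   # beer / wine-cider / cigarettes
    zero_inflation_prob[vice] <- 0.6
  }
  if (length(zero_inflation_prob) == 1L)
    zero_inflation_prob <- rep(zero_inflation_prob, p)
  if (length(zero_inflation_prob) != p ||
      any(zero_inflation_prob < 0 | zero_inflation_prob > 1))
    stop("zero_inflation_prob must be length-p probabilities")
  structure(list(n_customers = n, n_groups = p, n_weeks = t,
                 true_ranks = true_ranks, latent_sds = as.numeric(latent_sds),
                 noise_sd = noise_sd, mean_matrix_scale = mean_matrix_scale,
                 holiday_weeks = holiday_weeks, holiday_boost = holiday_boost,
                 seasonal_amplitude = seasonal_amplitude,
                 zero_inflation_prob = zero_inflation_prob,
                 mode = mode, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Default product-group labels: named blocks that the product factor
# templates load on, filler groups, and two zero-inflated vice groups.
default_group_labels <- function(p) {
  b <- max(1L, p %/% 4L)
  labels <- character(p)
  idx <- 1L
  add <- function(labels, idx, new) {
    take <- min(length(new), p - idx + 1L)
    if (take > 0L) labels[idx:(idx + take - 1L)] <- new[seq_len(take)]
    list(labels = labels, idx = idx + take)
  }
  st <- add(labels, idx, paste0("ready_to_eat_", seq_len(b)))
  st <- add(st$labels, st$idx, paste0("fresh_", seq_len(b)))
  st <- add(st$labels, st$idx, "red_meat")
  n_rest <- p - (st$idx - 1L)
  if (n_rest > 3L)
    st <- add(st$labels, st$idx, paste0("staple_", seq_len(n_rest - 3L)))
  st <- add(st$labels, st$idx, c("beer", "wine_cider", "cigarettes"))
  labels <- st$labels
  labels[labels == ""] <- paste0("grp_", which(labels == ""))
  labels
}

# Orthonormalize template columns (plus random fill) by sequential QR,
# keeping each column positively aligned with its template.
orthonormal_from_templates <- function(templates, dim_full, rank) {
  n_tpl <- ncol(templates)
  fill <- if (rank > n_tpl) {
    matrix(stats::rnorm(dim_full * (rank - n_tpl)), dim_full)
  } else NULL
  raw <- cbind(templates[, seq_len(min(n_tpl, rank)), drop = FALSE], fill)
  qrd <- qr(raw)
  if (qrd$rank < rank) stop("templates are rank deficient")
  Q <- qr.Q(qrd)[, seq_len(rank), drop = FALSE]
  for (j in seq_len(min(n_tpl, rank))) {
    if (sum(Q[, j] * templates[, j]) < 0) Q[, j] <- -Q[, j]
  }
  if (rank > n_tpl) {
    for (j in (n_tpl + 1L):rank) {
      i <- which.max(abs(Q[, j]))
      if (Q[i, j] < 0) Q[, j] <- -Q[, j]
    }
  }
  Q
}

time_templates <- function(t) {
  tpl <- cbind(
    rep(1, t),
    c(rep(1, floor(t / 2)), rep(-1, ceiling(t / 2))),
    cos(2 * pi * (seq_len(t) - 1) / t))
  tpl[, seq_len(min(3L, t)), drop = FALSE]
}

product_templates <- function(p) {
  b <- max(1L, p %/% 4L)
  tpl <- matrix(0, p, 3L)
  tpl[, 1L] <- 1
  if (p >= 2L * b) {
    tpl[seq_len(b), 2L] <- 1          # ready-to-eat block
    tpl[(b + 1L):(2L * b), 2L] <- -1  # fresh block
  } else tpl[1L, 2L] <- 1
  tpl[min(2L * b + 1L, p), 3L] <- 1   # red-meat spike
  tpl[, seq_len(min(3L, p)), drop = FALSE]
}

#' Build interpretable orthonormal factor bases
#'
#' The time basis orthonormalizes, in order: a flat (weekly-average) column,
#' a first-half vs second-half contrast, a one-cycle sinusoid (summer vs
#' winter), then random orthogonal fill. The product basis: a flat positive
#' column, a sparse ready-to-eat vs fresh block contrast, a single red-meat
#' spike, then random fill.
#'
#' @param p,t mode dimensions.
#' @param p0,t0 number of basis columns per mode (`p0 <= p`, `t0 <= t`).
#' @param seed integer seed for the random fill columns.
#' @return list with orthonormal-column matrices `A` (`p x p0`) and
#'   `B` (`t x t0`).
#' @export
make_factor_bases <- function(p, t, p0, t0, seed = 1L) {
  if (p0 > p || t0 > t) stop("requested rank exceeds mode dimension")
  if (p0 < 1L || t0 < 1L) stop("ranks must be at least 1")
  withr::with_seed(seed, factor_bases(p, t, p0, t0))
}

# RNG-consuming core; callers manage seeding
factor_bases <- function(p, t, p0, t0) {
  A <- orthonormal_from_templates(product_templates(p), p, p0)
  B <- orthonormal_from_templates(time_templates(t), t, t0)
  list(A = A, B = B)
}

# Nonnegative mean matrix: per-group weights declining from 1.5 to 0.5 times
# the overall scale, with alternating winter/summer seasonal tilt.
mean_matrix <- function(p, t, scale, seasonal_amplitude) {
  wt <- seq(1.5, 0.5, length.out = p)
  season <- cos(2 * pi * (seq_len(t) - 1) / t)      # +1 in week 1 (winter)
  dirs <- rep_len(c(1, -1, 0), p)
  M <- outer(wt, rep(1, t)) *
    (1 + seasonal_amplitude * outer(dirs, season))
  M * scale
}

#' Simulate a purchase tensor with known latent structure
#'
#' Draws `n` customer slices from the separable model described in
#' [synthetic_config()]. In gaussian mode the tensor equals
#' `M + A Z_i B^T + E_i` exactly (and may contain negative values); in
#' expenditure mode the holiday-boosted mean is added, values are clamped at
#' zero and zero-inflated groups are masked per customer, yielding a
#' realistic nonnegative loyalty-card tensor.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `tensor` (a [purchase_tensor()]) and `truth`,
#'   a `synthetic_truth` object carrying the bases `A` and `B`, the latent
#'   sds, the mean matrix actually used, the latent draws `Z`
#'   (`n x p0 x t0`) and a per-customer archetype label naming the
#'   (product-component, time-component) pair with the largest standardized
#'   latent score.
#' @export
simulate_tensor <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, simulate_tensor_impl(config))
}

simulate_tensor_impl <- function(config) {
  n <- config$n_customers; p <- config$n_groups; t <- config$n_weeks
  p0 <- config$true_ranks[1L]; t0 <- config$true_ranks[2L]
  bases <- factor_bases(p, t, p0, t0)
  A <- bases$A; B <- bases$B
  M <- mean_matrix(p, t, config$mean_matrix_scale, config$seasonal_amplitude)
  # latent sds in row-major (j1, j2) order -> column-stacked vec(Z) order
  sds_rowmajor <- config$latent_sds
  row_of <- rep(seq_len(p0), times = t0)   # j1 for vec index (j2-1)*p0+j1
  col_of <- rep(seq_len(t0), each = p0)    # j2
  sds_vec <- sds_rowmajor[(row_of - 1L) * t0 + col_of]
  Zvec <- matrix(stats::rnorm(n * p0 * t0), n) *
    matrix(sds_vec, n, p0 * t0, byrow = TRUE)
  # vec(A Z B^T) = (B x A) vec(Z), column-stacking convention
  K <- kronecker(B, A)                     # (t*p) x (t0*p0)
  signal <- Zvec %*% t(K)                  # n x (p*t), week-major columns
  noise <- if (config$noise_sd > 0) {
    matrix(stats::rnorm(n * p * t, sd = config$noise_sd), n)
  } else matrix(0, n, p * t)
  M_used <- M
  if (config$mode == "expenditure" && length(config$holiday_weeks)) {
    M_used[, config$holiday_weeks] <-
      M_used[, config$holiday_weeks] *
      rep(1 + config$holiday_boost, each = p)
  }
  flat <- signal + noise +
    matrix(as.vector(M_used), n, p * t, byrow = TRUE)
  if (config$mode == "expenditure") {
    flat <- pmax(flat, 0)
    zi <- config$zero_inflation_prob
    if (any(zi > 0)) {
      mask <- matrix(stats::runif(n * p), n, p) <
        matrix(zi, n, p, byrow = TRUE)    # TRUE = non-purchaser
      week_block <- rep(seq_len(p), times = t)
      flat <- flat * (1 - mask[, week_block, drop = FALSE])
    }
  }
  values <- array(aperm(array(t(flat), dim = c(p, t, n)), c(3L, 1L, 2L)),
                  dim = c(n, p, t))
  labels <- default_group_labels(p)
  tensor <- purchase_tensor(values, paste0("C", seq_len(n)), labels,
                            seq_len(t),
                            check_nonnegative = config$mode == "expenditure")
  Z <- array(0, dim = c(n, p0, t0))
  for (j in seq_len(p0 * t0)) Z[, row_of[j], col_of[j]] <- Zvec[, j]
  std <- abs(Zvec) / matrix(sds_vec, n, p0 * t0, byrow = TRUE)
  arch_idx <- max.col(std, ties.method = "first")
  archetypes <- sprintf("P%d:T%d", row_of[arch_idx], col_of[arch_idx])
  truth <- structure(list(A = A, B = B, latent_sds = sds_rowmajor,
                          mean_matrix = M_used, Z = Z,
                          archetypes = archetypes,
                          holiday_weeks = config$holiday_weeks,
                          mode = config$mode),
                     class = "synthetic_truth")
  list(tensor = tensor, truth = truth)
}

#' Write a purchase tensor as long-format transactions
#'
#' Emits one `customer_id,week,group,amount` row per nonzero cell.
#' Optionally appends synthetic customers that violate the cohort exclusion
#' criteria (too many zero-purchase weeks, or annual total below the
#' threshold) with known ids, so that downstream filters can be audited.
#'
#' @param tensor a [purchase_tensor()].
#' @param path output file path.
#' @param inject optional list with counts `n_zero_weeks` and `n_low_total`
#'   of excludable customers to append; their ids are returned in the
#'   manifest. Injected absentee customers purchase nothing during their
#'   first 9 weeks (and a healthy total of 600 over the rest); low-total
#'   customers spend a total of 400 spread over all weeks.
#' @param manifest_path optional path for a JSON manifest of injected ids.
#' @return (invisibly) the manifest list with elements
#'   `injected_zero_weeks` and `injected_low_total`.
#' @export
write_transactions <- function(tensor, path, inject = NULL,
                               manifest_path = NULL) {
  v <- tensor$values
  nz <- which(v != 0, arr.ind = TRUE)
  df <- data.frame(
    customer_id = tensor$customer_ids[nz[, 1L]],
    week = tensor$weeks[nz[, 3L]],
    group = tensor$groups[nz[, 2L]],
    amount = v[nz], stringsAsFactors = FALSE)
  df <- df[order(match(df$customer_id, tensor$customer_ids),
                 df$week, match(df$group, tensor$groups)), ]
  manifest <- list(injected_zero_weeks = character(0),
                   injected_low_total = character(0))
  t <- length(tensor$weeks); p <- length(tensor$groups)
  if (!is.null(inject)) {
    n_zw <- inject$n_zero_weeks %||% 0L
    n_lt <- inject$n_low_total %||% 0L
    extra <- list()
    if (n_zw > 0L) {
      if (t < 10L) stop("need at least 10 weeks to inject absentee customers")
      ids <- sprintf("EXCL_ZW_%d", seq_len(n_zw))
      active <- tensor$weeks[-seq_len(9L)]   # 9 zero weeks, total kept high
      for (id in ids) {
        extra[[length(extra) + 1L]] <- data.frame(
          customer_id = id, week = active, group = tensor$groups[1L],
          amount = 600 / length(active), stringsAsFactors = FALSE)
      }
      manifest$injected_zero_weeks <- ids
    }
    if (n_lt > 0L) {
      ids <- sprintf("EXCL_LT_%d", seq_len(n_lt))
      for (id in ids) {
        extra[[length(extra) + 1L]] <- data.frame(
          customer_id = id, week = tensor$weeks, group = tensor$groups[p],
          amount = 400 / t, stringsAsFactors = FALSE)
      }
      manifest$injected_low_total <- ids
    }
    if (length(extra)) df <- rbind(df, do.call(rbind, extra))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(manifest_path))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
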