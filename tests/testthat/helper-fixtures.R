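# Shared fixtures and independent oracles used across test files.

# tiny labelled tensor from an explicit n x p x t array
toy_tensor <- function(values, nonneg = TRUE) {
  d <- dim(values)
  purchase_tensor(values, paste0("C", seq_len(d[1])),
                  paste0("g", seq_len(d[2])), seq_len(d[3]),
                  check_nonnegative = nonneg)
}

random_tensor <- function(n, p, t, seed, nonneg = FALSE) {
  set.seed(seed)
  v <- array(rnorm(n * p * t), c(n, p, t))
  if (nonneg) v <- abs(v)
  toy_tensor(v, nonneg = nonneg)
}

# naive triple-loop modal covariance accumulation (oracle for mode 1/2)
naive_modal_covariance <- function(centered, mode) {
  v <- centered$values
  n <- dim(v)[1]; p <- dim(v)[2]; t <- dim(v)[3]
  if (mode == 1) {
    S <- matrix(0, p, p)
    for (i in seq_len(n)) for (w in seq_len(t))
      S <- S + v[i, , w] %o% v[i, , w]
    S / (n * t)
  } else {
    S <- matrix(0, t, t)
    for (i in seq_len(n)) for (g in seq_len(p))
      S <- S + v[i, g, ] %o% v[i, g, ]
    S / (n * p)
  }
}

# brute-force average-linkage agglomeration on a distance matrix; returns
# the sequence of merged cluster member sets and merge heights
naive_average_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  dist_cl <- function(a, b) mean(D[clusters[[a]], clusters[[b]], drop = FALSE])
  merges <- list(); heights <- numeric(0)
  repeat {
    ids <- which(active)
    if (length(ids) < 2) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
      d <- dist_cl(ids[i], ids[j])
      if (d < best_d) { best_d <- d; best <- c(ids[j], ids[i]) }
    }
    merges[[length(merges) + 1]] <-
      sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    active[best[2]] <- FALSE
  }
  list(members = merges, heights = heights)
}

# member sets at each hclust merge step
hclust_member_sets <- function(hc) {
  sets <- list()
  for (step in seq_len(nrow(hc$merge))) {
    members <- integer(0)
    grab <- function(k) {
      if (k < 0) -k else sets[[k]]
    }
    members <- c(grab(hc$merge[step, 1]), grab(hc$merge[step, 2]))
    sets[[step]] <- sort(members)
  }
  sets
}
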