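scores_from_vector <- function(s) {
  n <- length(s)
  sc <- array(0, c(n, 1, 1),
              dimnames = list(paste0("C", seq_len(n)), "PC1", "PC1"))
  sc[, 1, 1] <- s
  class(sc) <- c("tpca_scores", class(sc))
  sc
}

test_that("stratification produces the 10/80/10 split on distinct scores", {
  set.seed(1)
  st <- stratify(scores_from_vector(sample(seq_len(1000))), c(1, 1), 0.10)
  expect_equal(as.vector(table(st$label)), c(100, 800, 100))
  # the labels follow the score order
  expect_true(all(st$score[st$label == "high"] > 900))
  expect_true(all(st$score[st$label == "low"] <= 100))
})

test_that("stratification floor semantics and tie handling", {
  st0 <- stratify(scores_from_vector(rnorm(50)), c(1, 1), q = 0)
  expect_true(all(st0$label == "typical"))

  # n = 5, q = 0.1: floor(0.5) = 0 in each tail
  st5 <- stratify(scores_from_vector(rep(1, 5)), c(1, 1), 0.10)
  expect_true(all(st5$label == "typical"))

  # all-tied scores: stable customer order decides the tails
  tied <- stratify(scores_from_vector(rep(2, 10)), c(1, 1), 0.10)
  expect_equal(tied$label[1], factor("low", c("low", "typical", "high")))
  expect_equal(as.vector(table(tied$label)), c(1, 8, 1))

  expect_error(stratify(scores_from_vector(rnorm(10)), c(1, 1), 0.5), "q")
})

test_that("stratification and deciles are invariant to monotone transforms", {
  set.seed(4)
  s <- rnorm(200)
  sc1 <- scores_from_vector(s)
  sc2 <- scores_from_vector(exp(3 * s))   # strictly increasing transform
  expect_identical(stratify(sc1, c(1, 1))$label, stratify(sc2, c(1, 1))$label)
  expect_identical(score_deciles(sc1, c(1, 1)), score_deciles(sc2, c(1, 1)))
})

test_that("deciles have near-equal sizes with the remainder at the bottom", {
  d100 <- score_deciles(scores_from_vector(rnorm(100)), c(1, 1))
  expect_equal(as.vector(table(d100)), rep(10, 10))

  s <- rnorm(103)
  d103 <- score_deciles(scores_from_vector(s), c(1, 1))
  expect_equal(as.vector(table(d103)), c(11, 11, 11, rep(10, 7)))
  # monotone in score
  expect_true(all(diff(d103[order(s)]) >= 0))
  expect_error(score_deciles(scores_from_vector(rnorm(9)), c(1, 1)),
               "at least 10")
})

test_that("group profiles are all-customer-standardized cell means", {
  # one cell with values 1, 2, 3 across customers: member {C3} reads
  # (3 - 2) / sd_pop = 1.2247
  v <- array(0, c(3, 1, 1))
  v[, 1, 1] <- c(1, 2, 3)
  tensor <- toy_tensor(v)
  gp <- group_profile(tensor, "C3")
  expect_equal(gp$profile[1, 1], 1 / sqrt(2 / 3), tolerance = 1e-4)

  r <- random_tensor(12, 3, 4, seed = 6, nonneg = TRUE)
  all_prof <- group_profile(r, r$customer_ids)
  expect_lt(max(abs(all_prof$profile)), 1e-12)

  vconst <- array(5, c(4, 2, 2))
  expect_true(all(group_profile(toy_tensor(vconst), "C1")$profile == 0))
  expect_error(group_profile(r, character(0)), "nonempty")
})

test_that("high and low strata have mirror-image profiles", {
  cfg <- synthetic_config(1000, 10, 52, c(3, 3), c(12, 10, 8, 7, 6, 5, 4, 3, 2),
                          noise_sd = 1, mode = "gaussian", seed = 9)
  sim <- simulate_tensor(cfg)
  fit <- fit_tpca(sim$tensor, 3, 3)
  sc <- tpca_project(fit, sim$tensor)
  st <- stratify(sc, c(2, 3), 0.10)   # ready-vs-fresh x summer-vs-winter
  ph <- group_profile(sim$tensor, st$customer_id[st$label == "high"])$profile
  pl <- group_profile(sim$tensor, st$customer_id[st$label == "low"])$profile
  cosine <- sum(ph * pl) / sqrt(sum(ph^2) * sum(pl^2))
  expect_lte(cosine, -0.8)
})

test_that("weekly trajectories are composition percentages", {
  # 2 customers x 2 groups x 2 weeks with printed spends
  v <- array(0, c(20, 2, 2))
  v[, 1, 1] <- 3; v[, 2, 1] <- 1    # week 1: 75% on g1
  v[, 1, 2] <- 1; v[, 2, 2] <- 4    # week 2: 20% on g1
  tensor <- toy_tensor(v)
  dec <- stats::setNames(rep(1:10, 2), tensor$customer_ids)
  traj <- trajectory_by_decile(tensor, dec, "g1")
  expect_equal(unname(traj[1, ]), c(75, 20))

  # subset = everything -> 100 wherever defined; zero weeks excluded
  v[1, , 2] <- 0
  t2 <- toy_tensor(v)
  all_traj <- trajectory_by_decile(t2, dec, t2$groups)
  expect_true(all(all_traj[is.finite(all_traj)] == 100))
  expect_error(trajectory_by_decile(t2, dec, character(0)), "nonempty")
})

test_that("seasonal archetypes surface in decile trajectories", {
  cfg <- synthetic_config(1000, 10, 52, c(3, 3), c(12, 10, 8, 7, 6, 5, 4, 3, 2),
                          noise_sd = 1, mode = "expenditure", seed = 10,
                          zero_inflation_prob = 0)
  sim <- simulate_tensor(cfg)
  resc <- rescale_annual(apply_exclusions(sim$tensor)$tensor)
  # deciles by the true (ready-vs-fresh, summer-vs-winter) latent score
  A <- sim$truth$A; B <- sim$truth$B
  n <- dim(resc$values)[1]
  M <- apply(resc$values, c(2, 3), mean)
  z23 <- sapply(seq_len(n),
                function(i) (crossprod(A, resc$values[i, , ] - M) %*% B)[2, 3])
  dec <- score_deciles(scores_from_vector(z23), c(1, 1))
  names(dec) <- resc$customer_ids
  subset <- grep("^ready_to_eat", resc$groups, value = TRUE)
  traj <- trajectory_by_decile(resc, dec, subset)
  winter <- which(resc$weeks %in% c(1:13, 40:52))
  summer <- which(resc$weeks %in% 14:39)
  top_diff <- mean(traj[10, winter]) - mean(traj[10, summer])
  bottom_diff <- mean(traj[1, winter]) - mean(traj[1, summer])
  # the time basis sinusoid peaks in winter, so high scorers tilt their
  # ready-to-eat share toward winter and low scorers the other way
  expect_gt(top_diff, 0)
  expect_lt(bottom_diff, 0)
  expect_gt(top_diff - bottom_diff, 5)
})

test_that("atypicality flags follow the loading threshold", {
  fake <- structure(list(
    U1 = cbind(c(1, 0, 0, 0), c(0, 0.2, 0.1, 0.1)),
    U2 = cbind(c(0.1, 0.1, 0.9), c(0.2, 0.2, 0.2)),
    p0 = 2L, t0 = 2L, groups = paste0("g", 1:4), weeks = 1:3),
    class = "tpca")
  fl <- flag_atypical(fake, 0.3)
  expect_equal(fl$groups, "g1")
  expect_equal(fl$weeks, 3L)
  none <- flag_atypical(fake, 1)
  expect_length(none$groups, 0)
  expect_length(none$weeks, 0)
  expect_error(flag_atypical(fake, 0), "positive")
  expect_error(flag_atypical(fake, 0.3, n_components = 3), "exceeds")
})

test_that("holiday-boosted weeks are flagged on rescaled purchase data", {
  cfg <- synthetic_config(800, 10, 52, c(3, 2), c(8, 6, 4, 3, 2, 1),
                          noise_sd = 1, holiday_boost = 2,
                          mode = "expenditure", seed = 5)
  sim <- simulate_tensor(cfg)
  resc <- rescale_annual(apply_exclusions(sim$tensor)$tensor)
  fit <- fit_tpca(resc, 3, 3)
  fl <- flag_atypical(fit, 0.3)
  expect_true(all(sim$truth$holiday_weeks %in% fl$weeks))
})

test_that("loading clustering matches a brute-force average-linkage oracle", {
  set.seed(8)
  L <- rbind(matrix(rnorm(12), 4), rnorm(3))  # 5 rows incl. unrelated one
  rownames(L) <- paste0("r", 1:5)
  hc <- cluster_loadings(L)
  expect_length(hc$order, 5)
  D <- 1 - cor(t(L))
  oracle <- naive_average_linkage(D)
  got <- hclust_member_sets(hc)
  expect_equal(got, oracle$members)
  expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
})

test_that("identical rows merge first at height zero", {
  L <- rbind(c(1, 2, 3, 4), c(2, 1, 0, 5), c(1, 2, 3, 4), c(0, 0, 1, 9))
  hc <- cluster_loadings(L)
  expect_equal(sort(abs(hc$merge[1, ])), c(1, 3))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_error(cluster_loadings(L[1, , drop = FALSE]), "at least 2")
})

test_that("constant rows sit at maximal distance from everything", {
  # rows 1 and 2 are perfectly anticorrelated (distance 2); the constant
  # row 3 sits at distance 1 to both, so it joins first at exactly 1
  L <- rbind(c(1, 2, 3), c(3, 2, 1), c(5, 5, 5))
  hc <- cluster_loadings(L)
  expect_true(3 %in% -hc$merge[1, ])
  expect_equal(hc$height, c(1, 1.5), tolerance = 1e-12)
})
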