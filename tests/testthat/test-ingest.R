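write_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_transactions parses well-formed files and flags bad rows", {
  path <- write_lines(c("customer_id,week,group,amount",
                        "c1,1,apples,2.5", "c1,2,bread,1", "c2,1,apples,3"))
  rec <- read_transactions(path)
  expect_equal(nrow(rec), 3)
  expect_type(rec$week, "integer")

  empty <- write_lines("customer_id,week,group,amount")
  expect_equal(nrow(read_transactions(empty)), 0)

  neg <- write_lines(c("customer_id,week,group,amount", "c1,1,apples,-5"))
  expect_error(read_transactions(neg), "negative amount.*line.*2")

  nohdr <- write_lines(c("id,week,group,amount", "c1,1,apples,5"))
  expect_error(read_transactions(nohdr), "missing column")
})

test_that("assemble_tensor sums duplicates and zero-fills gaps", {
  rec <- data.frame(customer_id = c("c1", "c1"), week = c(1L, 1L),
                    group = c("g1", "g1"), amount = c(2, 3))
  tensor <- assemble_tensor(rec, weeks = 1:4)
  expect_equal(tensor$values[1, 1, 1], 5)
  expect_equal(sum(tensor$values), 5)

  # explicit customers with an empty stream
  tensor0 <- assemble_tensor(rec[0, ], weeks = 1:3, groups = c("a", "b"),
                             customer_ids = c("x", "y"))
  expect_equal(dim(tensor0), c(2L, 2L, 3L))
  expect_true(all(tensor0$values == 0))

  # sparse weeks expand to the declared range
  rec2 <- data.frame(customer_id = "c1", week = c(1L, 52L),
                     group = "g1", amount = c(1, 1))
  t52 <- assemble_tensor(rec2, weeks = 1:52)
  expect_equal(dim(t52)[3], 52L)
  expect_equal(sum(t52$values[1, 1, 2:51]), 0)

  expect_error(assemble_tensor(rec, weeks = 1:4, groups = "other"),
               "not in the explicit list")
})

test_that("exclusion boundaries are strict as written", {
  # customer 1: exactly 9 zero weeks, total 600 -> excluded (>8 strict)
  # customer 2: exactly 8 zero weeks, total 600 -> retained
  # customer 3: 0 zero weeks, total 499.99 -> excluded (<500 strict)
  # customer 4: 0 zero weeks, total exactly 500 -> retained
  t <- 52
  v <- array(0, c(4, 1, t))
  v[1, 1, 10:t] <- 600 / (t - 9)
  v[2, 1, 9:t] <- 600 / (t - 8)
  v[3, 1, ] <- 499.99 / t
  v[4, 1, ] <- 500 / t
  res <- apply_exclusions(toy_tensor(v))
  expect_setequal(res$tensor$customer_ids, c("C2", "C4"))
  expect_equal(res$report$excluded_zero_weeks, "C1")
  expect_equal(res$report$excluded_low_total, "C3")
})

test_that("customers violating both criteria are counted once", {
  v <- array(0, c(3, 1, 52))
  v[1, 1, ] <- 20          # healthy
  v[2, 1, 1:10] <- 30      # 42 zero weeks but total 300 -> both criteria
  v[3, 1, ] <- 15          # healthy
  res <- apply_exclusions(toy_tensor(v))
  rep <- res$report
  expect_equal(rep$n_excluded_zero_weeks, 1)
  expect_equal(rep$n_excluded_low_total, 1)
  expect_equal(rep$n_excluded_overlap, 1)
  expect_equal(rep$n_final, rep$n_initial - 1)
})

test_that("listed ids are removed before the numeric criteria", {
  v <- array(1, c(3, 2, 10))
  res <- apply_exclusions(toy_tensor(v), min_total = 10,
                          drop_ids = "C2")
  expect_setequal(res$tensor$customer_ids, c("C1", "C3"))
  expect_equal(res$report$n_removed_listed, 1)
  expect_error(apply_exclusions(toy_tensor(v), min_total = 1e6),
               "empty cohort")
})

test_that("rescale_annual fixes every customer total and is idempotent", {
  tensor <- random_tensor(20, 4, 8, seed = 5, nonneg = TRUE)
  scaled <- rescale_annual(tensor)
  expect_equal(unname(customer_totals(scaled)), rep(1000, 20),
               tolerance = 1e-9)
  again <- rescale_annual(scaled)
  expect_equal(again$values, scaled$values, tolerance = 1e-12)

  # proportions preserved: a single nonzero cell absorbs the whole target
  v <- array(0, c(2, 2, 2)); v[1, 1, 1] <- 37; v[2, 2, 2] <- 4
  one <- rescale_annual(toy_tensor(v))
  expect_equal(one$values[1, 1, 1], 1000)

  vz <- array(0, c(2, 2, 2)); vz[1, 1, 1] <- 1
  expect_error(rescale_annual(toy_tensor(vz)), "apply_exclusions")
})

test_that("peel drops named slices without rescaling", {
  tensor <- random_tensor(5, 55, 52, seed = 6, nonneg = TRUE)
  peeled <- peel(tensor, drop_weeks = c(12, 25, 51),
                 drop_groups = tensor$groups[1:3])
  expect_equal(dim(peeled), c(5L, 52L, 49L))
  expect_false(any(c(12, 25, 51) %in% peeled$weeks))
  # untouched cells unchanged (no re-normalization)
  expect_equal(peeled$values[, , 1], tensor$values[, 4:55, 1])

  expect_equal(peel(tensor)$values, tensor$values)
  expect_error(peel(tensor, drop_weeks = 1:52), "degenerate")
  expect_error(peel(tensor, drop_groups = "nope"), "unknown group")
})

test_that("weekly shares are percentages summing to 100", {
  uniform <- toy_tensor(array(1, c(3, 4, 52)))
  sh <- weekly_share(uniform)
  expect_equal(unname(sh), rep(100 / 52, 52))
  expect_equal(round(sh[[1]], 1), 1.9)

  v <- array(0, c(2, 3, 5)); v[, , 2] <- 1
  sh2 <- weekly_share(toy_tensor(v))
  expect_equal(unname(sh2), c(0, 100, 0, 0, 0))

  r <- random_tensor(4, 3, 7, seed = 2, nonneg = TRUE)
  expect_equal(sum(weekly_share(r)), 100, tolerance = 1e-9)
})

test_that("row_zscore uses population sd and zeroes constant rows", {
  z <- row_zscore(rbind(c(1, 2, 3), c(5, 5, 5)))
  expect_equal(z[1, ], c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(z[2, ], c(0, 0, 0))
  r <- row_zscore(matrix(rnorm(40), 5))
  expect_equal(unname(rowMeans(r)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(sqrt(rowMeans(r^2))), rep(1, 5), tolerance = 1e-12)
})

test_that("exclusion plus rescale removes exactly the injected violators", {
  # generous mean scale keeps every legitimate customer clear of the
  # exclusion thresholds, so only the injected violators should fall
  cfg <- synthetic_config(40, 6, 52, c(2, 2), c(6, 4, 3, 2),
                          mean_matrix_scale = 4, mode = "expenditure",
                          seed = 21, zero_inflation_prob = 0)
  sim <- simulate_tensor(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  man <- write_transactions(sim$tensor, path,
                            inject = list(n_zero_weeks = 4, n_low_total = 3))
  tensor <- assemble_tensor(read_transactions(path), weeks = 1:52)
  res <- apply_exclusions(tensor)
  removed <- setdiff(tensor$customer_ids, res$tensor$customer_ids)
  expect_setequal(removed,
                  c(man$injected_zero_weeks, man$injected_low_total))
  scaled <- rescale_annual(res$tensor)
  expect_equal(unname(customer_totals(scaled)),
               rep(1000, res$report$n_final), tolerance = 1e-9)
})
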