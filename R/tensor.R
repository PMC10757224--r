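#' Labelled purchase tensor
#'
#' Container for a 3-way array of nonnegative weekly expenditures with one
#' slice per customer: dimensions are customers x product groups x weeks.
#' Absent transactions are stored as exact zeros, never as missing values.
#'
#' @param values numeric array of dimension `n x p x t` with finite,
#'   nonnegative entries (gaussian-mode synthetic tensors may carry negative
#'   values; set `check_nonnegative = FALSE` for those).
#' @param customer_ids character vector of `n` unique customer identifiers.
#' @param groups character vector of `p` unique product-group labels.
#' @param weeks increasing integer vector of `t` week indices (1-based).
#' @param check_nonnegative enforce nonnegativity of `values`.
#'
#' @return An object of class `purchase_tensor`: a list with elements
#'   `values`, `customer_ids`, `groups`, `weeks`.
#' @export
purchase_tensor <- function(values, customer_ids, groups, weeks,
                            check_nonnegative = TRUE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-way array (customers x groups x weeks)")
  d <- dim(values)
  customer_ids <- as.character(customer_ids)
  groups <- as.character(groups)
  weeks <- as.integer(weeks)
  if (length(customer_ids) != d[1L] || length(groups) != d[2L] ||
      length(weeks) != d[3L])
    stop("label lengths do not match array dimensions")
  if (anyDuplicated(customer_ids)) stop("customer ids must be unique")
  if (anyDuplicated(groups)) stop("group labels must be unique")
  if (is.unsorted(weeks, strictly = TRUE)) stop("weeks must be increasing")
  if (anyNA(values) || any(!is.finite(values)))
    stop("tensor values must be finite and non-missing")
  if (check_nonnegative && any(values < 0))
    stop("tensor values must be nonnegative")
  dimnames(values) <- list(customer_ids, groups, paste0("w", weeks))
  structure(list(values = values, customer_ids = customer_ids,
                 groups = groups, weeks = weeks),
            class = "purchase_tensor")
}

#' @export
print.purchase_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("purchase_tensor: %d customers x %d product groups x %d weeks\n",
              d[1L], d[2L], d[3L]))
  tot <- sum(x$values)
  cat(sprintf("  grand total: %.2f; nonzero cells: %d/%d\n",
              tot, sum(x$values != 0), length(x$values)))
  invisible(x)
}

#' @export
dim.purchase_tensor <- function(x) dim(x$values)

n_customers <- function(x) dim(x$values)[1L]

#' Annual total expenditure per customer
#'
#' @param tensor a [purchase_tensor()].
#' @return named numeric vector of per-customer sums over all groups and weeks.
#' @export
customer_totals <- function(tensor) {
  apply(tensor$values, 1L, sum)
}

#' Remove customers, keeping labels and order of the rest
#' @noRd
subset_customers <- function(tensor, keep) {
  purchase_tensor(tensor$values[keep, , , drop = FALSE],
                  tensor$customer_ids[keep], tensor$groups, tensor$weeks,
                  check_nonnegative = FALSE)
}

#' Apply cohort exclusion filters
#'
#' Removes customers who appear to shop mostly elsewhere: those with strictly
#' more than `max_zero_weeks` weeks without any registered purchase, and those
#' whose annual total falls strictly below `min_total` (compared with a 1e-9
#' absolute tolerance, so a total of exactly the threshold is retained). An
#' optional explicit id list (e.g. store personnel) is removed first, before
#' the numeric criteria are evaluated.
#'
#' @param tensor a [purchase_tensor()] assembled on the full week range.
#' @param max_zero_weeks retained customers have at most this many all-zero
#'   weeks (default 8 of 52, about 15\%).
#' @param min_total minimum annual expenditure retained, in currency units
#'   (default 500).
#' @param drop_ids optional character vector of ids removed unconditionally
#'   before the numeric criteria.
#'
#' @return list with elements `tensor` (the filtered [purchase_tensor()]) and
#'   `report`, an `exclusion_report` tallying each criterion and their overlap.
#' @export
apply_exclusions <- function(tensor, max_zero_weeks = 8, min_total = 500,
                             drop_ids = NULL) {
  ids0 <- tensor$customer_ids
  n_initial <- length(ids0)
  listed <- intersect(as.character(drop_ids), ids0)
  work <- if (length(listed)) {
    subset_customers(tensor, !(ids0 %in% listed))
  } else tensor
  ids <- work$customer_ids
  # weeks with no registered purchases at all: all-zero columns per customer
  week_tot <- apply(work$values, c(1L, 3L), sum)
  zero_weeks <- rowSums(week_tot == 0)
  totals <- rowSums(week_tot)
  excl_zw <- ids[zero_weeks > max_zero_weeks]
  excl_lt <- ids[totals < min_total - 1e-9]
  excluded <- union(excl_zw, excl_lt)
  keep <- !(ids %in% excluded)
  if (!any(keep))
    stop("all customers excluded: empty cohort after filtering")
  report <- structure(list(
    n_initial = n_initial,
    n_removed_listed = length(listed),
    n_excluded_zero_weeks = length(excl_zw),
    n_excluded_low_total = length(excl_lt),
    n_excluded_overlap = length(intersect(excl_zw, excl_lt)),
    n_final = sum(keep),
    excluded_zero_weeks = excl_zw,
    excluded_low_total = excl_lt,
    removed_listed = listed,
    max_zero_weeks = max_zero_weeks,
    min_total = min_total), class = "exclusion_report")
  list(tensor = subset_customers(work, keep), report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("exclusion_report\n")
  cat(sprintf("  initial customers : %d\n", x$n_initial))
  if (x$n_removed_listed)
    cat(sprintf("  removed (listed)  : %d\n", x$n_removed_listed))
  cat(sprintf("  >%d zero weeks     : %d\n", x$max_zero_weeks,
              x$n_excluded_zero_weeks))
  cat(sprintf("  total < %.0f       : %d\n", x$min_total,
              x$n_excluded_low_total))
  cat(sprintf("  overlap           : %d\n", x$n_excluded_overlap))
  cat(sprintf("  final cohort      : %d\n", x$n_final))
  invisible(x)
}

#' Rescale each customer's annual expenditure to a fixed total
#'
#' Multiplies every customer slice by a constant so that the sum over all
#' groups and weeks equals `target` (default 1000 currency units), giving
#' every customer equal weight while preserving within-customer proportions.
#'
#' @param tensor a [purchase_tensor()]; every customer total must be positive,
#'   which [apply_exclusions()] guarantees.
#' @param target the per-customer annual total after rescaling.
#' @return the rescaled [purchase_tensor()].
#' @export
rescale_annual <- function(tensor, target = 1000) {
  totals <- customer_totals(tensor)
  if (any(totals <= 0))
    stop("customers with zero total expenditure present; ",
         "run apply_exclusions() first")
  v <- tensor$values * (target / totals)  # recycles over the first dimension
  purchase_tensor(v, tensor$customer_ids, tensor$groups, tensor$weeks,
                  check_nonnegative = FALSE)
}

#' Peel atypical weeks and product groups from a tensor
#'
#' Drops named week and group slices (e.g. holiday weeks and dominant
#' alcohol/tobacco groups) so that everyday purchase patterns can be
#' re-analysed. No re-scaling is performed: the peeled tensor keeps the
#' already-scaled expenditures, so customer totals fall below the original
#' annual target.
#'
#' @param tensor a [purchase_tensor()].
#' @param drop_weeks integer week indices to remove (must exist in the tensor).
#' @param drop_groups character group labels to remove.
#' @return the reduced [purchase_tensor()], label order preserved.
#' @export
peel <- function(tensor, drop_weeks = integer(0), drop_groups = character(0)) {
  drop_weeks <- as.integer(drop_weeks)
  drop_groups <- as.character(drop_groups)
  if (length(bad <- setdiff(drop_weeks, tensor$weeks)))
    stop("unknown week(s): ", paste(bad, collapse = ", "))
  if (length(bad <- setdiff(drop_groups, tensor$groups)))
    stop("unknown group(s): ", paste(bad, collapse = ", "))
  keep_w <- !(tensor$weeks %in% drop_weeks)
  keep_g <- !(tensor$groups %in% drop_groups)
  if (!any(keep_w)) stop("cannot peel all weeks: degenerate tensor")
  if (!any(keep_g)) stop("cannot peel all groups: degenerate tensor")
  purchase_tensor(tensor$values[, keep_g, keep_w, drop = FALSE],
                  tensor$customer_ids, tensor$groups[keep_g],
                  tensor$weeks[keep_w], check_nonnegative = FALSE)
}

#' Percentage of yearly purchases falling in each week
#'
#' With purchases distributed evenly over 52 weeks every share would be
#' 100/52, about 1.9\%; holiday weeks stand out above that line.
#'
#' @param tensor a [purchase_tensor()] with positive grand total.
#' @return named numeric vector of percentages summing to 100.
#' @export
weekly_share <- function(tensor) {
  wk <- apply(tensor$values, 3L, sum)
  tot <- sum(wk)
  if (tot <= 0) stop("tensor grand total must be positive")
  stats::setNames(100 * wk / tot, tensor$weeks)
}

#' Row-wise z scores of a summed expenditure matrix
#'
#' Standardizes each row (product group) of a `p x t` matrix to mean 0 and
#' population standard deviation 1 (denominator `t`). Constant rows map to
#' all-zero rows.
#'
#' @param mat numeric matrix, rows = product groups, columns = weeks.
#' @return matrix of the same shape with standardized rows.
#' @export
row_zscore <- function(mat) {
  mat <- as.matrix(mat)
  mu <- rowMeans(mat)
  centered <- mat - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  out <- centered / ifelse(sd_pop > 0, sd_pop, 1)
  out[sd_pop == 0, ] <- 0
  out
}
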