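#' Read long-format purchase transactions
#'
#' Parses a delimited text file with header
#' `customer_id,week,group,amount`: one row per observed purchase cell.
#' Weeks are 1-based integers, amounts nonnegative decimals. Malformed rows
#' (non-integer week, missing or negative amount) abort with the offending
#' line numbers.
#'
#' @param path path to the transaction file.
#' @param sep field separator (default comma).
#' @return a data.frame of records with columns `customer_id` (character),
#'   `week` (integer), `group` (character), `amount` (numeric).
#' @export
read_transactions <- function(path, sep = ",") {
  if (!file.exists(path)) stop("transaction file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c("character", "character",
                                         "character", "character"),
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  required <- c("customer_id", "week", "group", "amount")
  if (length(miss <- setdiff(required, names(df))))
    stop("transaction file is missing column(s): ",
         paste(miss, collapse = ", "))
  df <- df[required]
  if (nrow(df) == 0L) {
    return(data.frame(customer_id = character(0), week = integer(0),
                      group = character(0), amount = numeric(0),
                      stringsAsFactors = FALSE))
  }
  week <- suppressWarnings(as.integer(df$week))
  amount <- suppressWarnings(as.numeric(df$amount))
  # header is line 1, so data row k sits on file line k + 1
  bad_week <- which(is.na(week) | week < 1L)
  bad_amt <- which(is.na(amount) | !is.finite(amount))
  neg_amt <- which(!is.na(amount) & amount < 0)
  if (length(bad_week))
    stop("malformed week on line(s): ",
         paste(bad_week + 1L, collapse = ", "))
  if (length(bad_amt))
    stop("malformed amount on line(s): ",
         paste(bad_amt + 1L, collapse = ", "))
  if (length(neg_amt))
    stop("negative amount on line(s): ",
         paste(neg_amt + 1L, collapse = ", "))
  data.frame(customer_id = df$customer_id, week = week, group = df$group,
             amount = amount, stringsAsFactors = FALSE)
}

#' Assemble a purchase tensor from transaction records
#'
#' Builds the labelled customers x groups x weeks array. Duplicate
#' (customer, week, group) rows are summed; cells without a record are 0.
#' Customers are ordered by first appearance unless an explicit list is
#' given (which also materializes all-zero customers); groups follow the
#' given list or lexicographic order.
#'
#' @param records data.frame from [read_transactions()].
#' @param weeks integer vector of the full week range (default `1:52`);
#'   records outside it are an error.
#' @param groups optional explicit group-label ordering; records with a
#'   group outside the list are an error.
#' @param customer_ids optional explicit customer ordering.
#' @return a [purchase_tensor()].
#' @export
assemble_tensor <- function(records, weeks = 1:52, groups = NULL,
                            customer_ids = NULL) {
  weeks <- as.integer(weeks)
  if (is.null(customer_ids)) {
    customer_ids <- unique(records$customer_id)
  } else {
    customer_ids <- as.character(customer_ids)
    if (length(bad <- setdiff(records$customer_id, customer_ids)))
      stop("records contain customers not in the explicit list: ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (is.null(groups)) {
    groups <- sort(unique(records$group))
  } else {
    groups <- as.character(groups)
    if (length(bad <- setdiff(records$group, groups)))
      stop("records contain group(s) not in the explicit list: ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (length(bad <- setdiff(records$week, weeks)))
    stop("records contain week(s) outside the declared range: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  n <- length(customer_ids); p <- length(groups); t <- length(weeks)
  if (n == 0L) stop("no customers to assemble")
  values <- array(0, dim = c(n, p, t))
  if (nrow(records)) {
    ci <- match(records$customer_id, customer_ids)
    gi <- match(records$group, groups)
    wi <- match(records$week, weeks)
    key <- (ci - 1) + n * ((gi - 1) + p * (wi - 1))
    agg <- rowsum(records$amount, group = key)
    values[as.numeric(rownames(agg)) + 1] <- agg[, 1L]
  }
  purchase_tensor(values, customer_ids, groups, weeks)
}
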