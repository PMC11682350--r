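#' Chi-square test of equal-choice responding
#'
#' Goodness-of-fit test of forced-choice counts against the 50/50 split
#' expected under random responding: with `n = correct + incorrect`,
#' `X^2 = (correct - n/2)^2 / (n/2) + (incorrect - n/2)^2 / (n/2)`
#' `     = (correct - incorrect)^2 / n`,
#' on 1 degree of freedom, without continuity correction, with the
#' two-sided p-value from the chi-square survival function. This is the
#' convention used throughout for 2AFC and duo-trio panel counts.
#'
#' @param correct,incorrect Non-negative trial counts (total at least 1).
#' @return List of class `chisq_equal`: `statistic`, `df` (1), `p_value`,
#'   `n`.
#' @export
#' @examples
#' chisq_equal(81, 55)$statistic  # 4.97
chisq_equal <- function(correct, incorrect) {
  stopifnot(length(correct) == 1, length(incorrect) == 1,
            correct >= 0, incorrect >= 0)
  n <- correct + incorrect
  if (n < 1) stop("at least one trial is required")
  stat <- (correct - incorrect)^2 / n
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 n = n),
            class = "chisq_equal")
}

#' @export
print.chisq_equal <- function(x, ...) {
  cat("Chi-square vs. chance:", round(x$statistic, 3), "on 1 df, p =",
      format.pval(x$p_value, digits = 3), "(n =", x$n, "trials)\n")
  invisible(x)
}

#' Aggregate forced-choice counts
#'
#' Elementwise sum of correct and incorrect tallies over conditions.
#'
#' @param counts Data frame with `correct` and `incorrect` columns (one row
#'   per condition), or a list of such rows.
#' @return List with summed `correct` and `incorrect`.
#' @export
aggregate_counts <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(nrow(counts) >= 1, all(c("correct", "incorrect") %in% names(counts)))
    return(list(correct = sum(counts$correct), incorrect = sum(counts$incorrect)))
  }
  stopifnot(length(counts) >= 1)
  list(correct = sum(vapply(counts, function(x) x$correct, numeric(1))),
       incorrect = sum(vapply(counts, function(x) x$incorrect, numeric(1))))
}

#' Per-row, per-group and overall discrimination statistics
#'
#' Renders the standard sensory-test summary: a chi-square against chance
#' for every row, for every level of an optional grouping column (e.g. the
#' added odor descriptor), and for the overall aggregate.
#'
#' @param counts Data frame with columns `label`, `correct`, `incorrect`
#'   and optionally the grouping column.
#' @param group_by Name of the grouping column, or `NULL` for per-row and
#'   overall only.
#' @return Data frame with columns `scope` (`row`/`group`/`overall`),
#'   `label`, `correct`, `incorrect`, `statistic`, `p_value`.
#' @export
sensory_report <- function(counts, group_by = NULL) {
  stopifnot(is.data.frame(counts),
            all(c("label", "correct", "incorrect") %in% names(counts)))
  row_of <- function(scope, label, c_ok, c_bad) {
    ct <- chisq_equal(c_ok, c_bad)
    data.frame(scope = scope, label = label, correct = c_ok,
               incorrect = c_bad, statistic = ct$statistic,
               p_value = ct$p_value)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i)
    row_of("row", counts$label[i], counts$correct[i], counts$incorrect[i])))
  if (!is.null(group_by)) {
    if (!group_by %in% names(counts))
      stop("grouping column '", group_by, "' not found")
    for (g in unique(counts[[group_by]])) {
      sub <- counts[counts[[group_by]] == g, ]
      agg <- aggregate_counts(sub)
      out <- rbind(out, row_of("group", g, agg$correct, agg$incorrect))
    }
  }
  agg <- aggregate_counts(counts)
  out <- rbind(out, row_of("overall", "all", agg$correct, agg$incorrect))
  rownames(out) <- NULL
  out
}

#' Read a sensory counts CSV
#'
#' Expected columns: `label`, optional grouping columns, `correct`,
#' `incorrect`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of counts.
#' @export
read_sensory_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "correct", "incorrect")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sensory counts CSV is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(df$correct < 0) || any(df$incorrect < 0))
    stop("counts must be non-negative")
  df
}
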