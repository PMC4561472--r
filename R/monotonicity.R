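#' Rest-score groups for manifest monotonicity checking
#'
#' For a target item, the rest score is the total over the remaining items.
#' Respondents are sorted by rest score and adjacent rest-score values are
#' merged greedily from the low end until every group holds at least
#' `minsize` respondents (a short final group is merged backward). A tied
#' rest-score value is never split across groups.
#'
#' @param matrix a coded `response_matrix`.
#' @param item item id or column index of the target item.
#' @param minsize minimum respondents per group.
#' @param min_rest_items minimum number of non-missing rest items a
#'   respondent needs to contribute (default `J - 2`).
#' @return A list with `rest` (rest score per contributing respondent),
#'   `group` (integer group index, ordered by rest score), `rows` (row
#'   indices into `matrix`), and `n_groups`.
#' @export
rest_score_groups <- function(matrix, item, minsize,
                              min_rest_items = ncol(matrix) - 2L) {
  X <- unclass(matrix)
  j <- if (is.character(item)) match(item, colnames(X)) else item
  if (is.na(j) || j < 1L || j > ncol(X)) stop_fv("unknown item '%s'", item)
  rest_obs <- rowSums(!is.na(X[, -j, drop = FALSE]))
  use <- !is.na(X[, j]) & rest_obs >= min_rest_items
  if (minsize > sum(use))
    stop_fv("minsize (%d) exceeds the number of usable respondents (%d)",
            minsize, sum(use))
  rows <- which(use)
  rest <- rowSums(X[rows, -j, drop = FALSE], na.rm = TRUE)
  ord <- order(rest)
  rows <- rows[ord]; rest <- rest[ord]
  # greedy merge of adjacent rest-score values from the low end
  runs <- rle(rest)
  grp_of_run <- integer(length(runs$lengths))
  g <- 1L; acc <- 0L
  for (r in seq_along(runs$lengths)) {
    grp_of_run[r] <- g
    acc <- acc + runs$lengths[r]
    if (acc >= minsize && r < length(runs$lengths)) { g <- g + 1L; acc <- 0L }
  }
  # if final group is short, merge it backward
  if (acc < minsize && g > 1L) grp_of_run[grp_of_run == g] <- g - 1L
  grp <- rep(grp_of_run, runs$lengths)
  grp <- match(grp, sort(unique(grp)))
  list(rest = rest, group = grp, rows = rows, n_groups = max(grp))
}

#' Manifest monotonicity check over rest-score groups
#'
#' Mokken-style check that the probability of endorsing category `k` or
#' above of each item is non-decreasing in the rest score. For every item,
#' category `k >= 1` and ordered pair of rest-score groups, the comparison
#' is *active* when both group estimates of `P(X >= k)` lie strictly
#' inside (0, 1); a *violation* occurs when the lower group's estimate
#' exceeds the higher group's; significance uses a one-sided unpooled
#' two-proportion z-test at level `alpha`.
#'
#' @param matrix a coded `response_matrix`.
#' @param minsize minimum respondents per rest-score group.
#' @param alpha significance level (default 0.05).
#' @param min_rest_items see [rest_score_groups()].
#' @return An object of class `monotonicity_report`: per-item data frame
#'   `summary` (groups, active comparisons, violations, significant
#'   violations, maximum violation magnitude) and `details` of individual
#'   violations.
#' @export
check_monotonicity <- function(matrix, minsize, alpha = 0.05,
                               min_rest_items = ncol(matrix) - 2L) {
  X <- unclass(matrix)
  J <- ncol(X)
  ids <- colnames(X) %||% paste0("item", seq_len(J))
  summ <- data.frame(item = ids, minsize = minsize, n_groups = 0L,
                     active = 0L, violations = 0L, significant = 0L,
                     max_violation = 0)
  details <- list()
  for (j in seq_len(J)) {
    gr <- rest_score_groups(matrix, j, minsize, min_rest_items)
    xg <- X[gr$rows, j]
    G <- gr$n_groups
    summ$n_groups[j] <- G
    ng <- tabulate(gr$group, G)
    m <- max(xg)
    for (k in seq_len(m)) {
      pk <- vapply(seq_len(G), function(g)
        mean(xg[gr$group == g] >= k), numeric(1))
      for (g1 in seq_len(G - 1L)) for (g2 in (g1 + 1L):G) {
        if (pk[g1] <= 0 || pk[g1] >= 1 || pk[g2] <= 0 || pk[g2] >= 1) next
        summ$active[j] <- summ$active[j] + 1L
        if (pk[g1] > pk[g2]) {
          summ$violations[j] <- summ$violations[j] + 1L
          diff <- pk[g1] - pk[g2]
          summ$max_violation[j] <- max(summ$max_violation[j], diff)
          se <- sqrt(pk[g1] * (1 - pk[g1]) / ng[g1] +
                     pk[g2] * (1 - pk[g2]) / ng[g2])
          z <- diff / se
          p <- stats::pnorm(z, lower.tail = FALSE)
          sig <- p < alpha
          if (sig) summ$significant[j] <- summ$significant[j] + 1L
          details[[length(details) + 1L]] <- data.frame(
            item = ids[j], category = k, group_low = g1, group_high = g2,
            p_low = pk[g1], p_high = pk[g2], z = z, p_value = p,
            significant = sig)
        }
      }
    }
  }
  structure(list(summary = summ,
                 details = if (length(details)) do.call(rbind, details)
                           else NULL,
                 alpha = alpha, minsize = minsize),
            class = "monotonicity_report")
}

#' Monotonicity sweep over several minsize levels
#'
#' Runs [check_monotonicity()] at `minsize = N / d` for each divisor `d`
#' (defaults 10, 50, 500: the recommended level for large samples plus two
#' stricter levels). Smaller minsize yields more rest-score groups, hence
#' more active comparisons and higher sensitivity — along with more
#' sampling-error violations.
#'
#' @param matrix a coded `response_matrix`.
#' @param divisors numeric vector of sample-size divisors.
#' @param ... passed to [check_monotonicity()].
#' @return Named list of `monotonicity_report`s, one per divisor
#'   (`"N/10"` etc.).
#' @export
monotonicity_sweep <- function(matrix, divisors = c(10, 50, 500), ...) {
  n <- nrow(matrix)
  out <- lapply(divisors, function(d)
    check_monotonicity(matrix, minsize = max(1L, floor(n / d)), ...))
  names(out) <- paste0("N/", divisors)
  out
}

#' @export
print.monotonicity_report <- function(x, ...) {
  cat(sprintf("Monotonicity check (minsize = %d, alpha = %.2f)\n",
              x$minsize, x$alpha))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
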