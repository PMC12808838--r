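# Nonparametric group comparisons
#
# Two rank tests are used downstream: Kruskal-Wallis to compare specialist-RN
# skill mix between shift types within a unit, and Mann-Whitney U to compare
# the provision ratio between weekdays and weekends within a shift type.
#
# Both report the tie-corrected statistic. p-values: for small samples
# (total n <= 10 for Kruskal-Wallis; min group n <= 8 and no ties for
# Mann-Whitney) an exact method is used — exhaustive permutation enumeration
# for Kruskal-Wallis, the exact U distribution for Mann-Whitney — otherwise
# the chi-square / tie-corrected normal approximation. Degenerate inputs
# (all observations identical) are flagged and reported with p = 1.

new_staffing_test <- function(test_name, method, statistic, df = NA_real_,
                              p_value, n_per_group, degenerate = FALSE,
                              groups = NULL) {
  structure(
    list(test_name = test_name, method = method,
         statistic = unname(statistic), df = unname(df),
         p_value = unname(min(1, p_value)), n_per_group = n_per_group,
         degenerate = degenerate, groups = groups),
    class = "staffing_test"
  )
}

#' @export
print.staffing_test <- function(x, ...) {
  cat("<staffing_test> ", x$test_name, " (", x$method, ")\n", sep = "")
  if (!is.null(x$groups)) cat("  groups:", x$groups, "\n")
  cat(sprintf("  statistic = %.4f%s, p = %.4g, n = %s%s\n",
              x$statistic,
              if (!is.na(x$df)) sprintf(", df = %d", as.integer(x$df)) else "",
              x$p_value, paste(x$n_per_group, collapse = "/"),
              if (x$degenerate) " [degenerate: no variation]" else ""))
  invisible(x)
}

# Tie-corrected Kruskal-Wallis H on mid-ranks:
# H = (N - 1) * SSB / SST, algebraically equal to the classical
# (12 / (N (N+1))) * sum n_g (rbar_g - rbar)^2 divided by the tie-correction
# factor. Cross-checked against stats::kruskal.test in the test suite.
kw_statistic <- function(values, group_sizes) {
  r <- rank(values)
  rbar <- mean(r)
  idx <- rep(seq_along(group_sizes), group_sizes)
  group_means <- tapply(r, idx, mean)
  ssb <- sum(group_sizes * (group_means - rbar)^2)
  sst <- sum((r - rbar)^2)
  if (sst == 0) return(0)
  (length(values) - 1) * ssb / sst
}

# Number of distinct assignments of N items to groups of the given sizes.
n_assignments <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

# Exhaustive permutation p-value: enumerate every assignment of the pooled
# observations to groups of the observed sizes and count assignments whose H
# is at least the observed one.
kw_exact_p <- function(values, group_sizes, h_obs) {
  n <- length(values)
  count <- 0L
  total <- 0L
  recurse <- function(remaining, sizes_left) {
    if (length(sizes_left) == 1) {
      perm <- c(assigned, remaining)
      h <- kw_statistic(values[perm], group_sizes)
      count <<- count + (h >= h_obs - 1e-9)
      total <<- total + 1L
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes_left[1], simplify = FALSE)
    for (p in picks) {
      assigned <<- c(assigned, p)
      recurse(setdiff(remaining, p), sizes_left[-1])
      assigned <<- assigned[seq_len(length(assigned) - sizes_left[1])]
    }
  }
  assigned <- integer()
  recurse(seq_len(n), group_sizes)
  count / total
}

#' Kruskal-Wallis rank test
#'
#' @param samples List of two or more numeric vectors (the groups).
#' @param groups Optional description of what the groups are.
#' @return A `staffing_test` object: tie-corrected H statistic, degrees of
#'   freedom, p-value, per-group sizes, method used.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
kruskal_wallis <- function(samples, groups = NULL) {
  if (!is.list(samples) || length(samples) < 2) {
    stop("kruskal_wallis needs a list of at least 2 groups")
  }
  samples <- lapply(samples, function(x) as.numeric(x[!is.na(x)]))
  sizes <- lengths(samples)
  if (any(sizes < 1)) stop("every group must contain at least one observation")
  values <- unlist(samples)
  n <- length(values)
  if (n < 3) stop("at least 3 observations are required in total")
  k <- length(samples)

  if (length(unique(values)) == 1) {
    return(new_staffing_test("kruskal_wallis", "degenerate", 0, k - 1, 1,
                             sizes, degenerate = TRUE, groups = groups))
  }
  h <- kw_statistic(values, sizes)
  if (n <= 10 && n_assignments(sizes) <= 20000) {
    p <- kw_exact_p(values, sizes, h)
    method <- "exact permutation"
  } else {
    p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
    method <- "chi-square approximation"
  }
  new_staffing_test("kruskal_wallis", method, h, k - 1, p, sizes,
                    groups = groups)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact when both groups are small (min n <= 8) and there are no ties;
#' tie-corrected normal approximation with continuity correction otherwise.
#' Delegates to [stats::wilcox.test()].
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param groups Optional description of what the two groups are.
#' @return A `staffing_test` object with the U statistic (for `a`) and
#'   two-sided p-value.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4)) # U = 0, complete separation
mann_whitney <- function(a, b, groups = NULL) {
  a <- as.numeric(a[!is.na(a)])
  b <- as.numeric(b[!is.na(b)])
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty")
  }
  if (length(unique(c(a, b))) == 1) {
    return(new_staffing_test("mann_whitney", "degenerate",
                             length(a) * length(b) / 2, p_value = 1,
                             n_per_group = c(length(a), length(b)),
                             degenerate = TRUE, groups = groups))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && min(length(a), length(b)) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                       alternative = "two.sided")
  )
  new_staffing_test(
    "mann_whitney",
    if (exact) "exact" else "tie-corrected normal approximation",
    wt$statistic, p_value = wt$p.value,
    n_per_group = c(length(a), length(b)), groups = groups
  )
}

# Flatten staffing_test objects into a tidy table (used by the pipeline).
tests_to_table <- function(tests) {
  dplyr::bind_rows(lapply(tests, function(t) {
    tibble::tibble(test_name = t$test_name, groups = t$groups %||% NA_character_,
                   method = t$method, statistic = t$statistic, df = t$df,
                   p_value = t$p_value,
                   n_per_group = paste(t$n_per_group, collapse = "/"),
                   degenerate = t$degenerate)
  }))
}
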