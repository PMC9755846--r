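#' Merge deletion calls from two assays
#'
#' Combines per-sample boolean calls from two assays either as "positive
#' by at least one" (`"or"`) or "positive by both" (`"and"`).
#'
#' @param call_a,call_b Logical vectors (recycled as usual).
#' @param mode `"or"` or `"and"`.
#' @return Logical vector.
#' @export
merge_calls <- function(call_a, call_b, mode = c("or", "and")) {
  mode <- match.arg(mode)
  stopifnot(is.logical(call_a), is.logical(call_b),
            !anyNA(call_a), !anyNA(call_b))
  if (mode == "or") call_a | call_b else call_a & call_b
}

#' 2x2 contingency table
#'
#' Cell orientation: `a` = exposed & outcome-positive, `b` = exposed &
#' outcome-negative, `c` = unexposed & outcome-positive, `d` =
#' unexposed & outcome-negative.
#'
#' @param a,b,c,d Non-negative integer counts, total > 0.
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) == 0) stop("table total must be > 0")
  structure(as.list(cells), class = "contingency_2x2")
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$c, tab$b, tab$d), nrow = 2,
         dimnames = list(exposure = c("exposed", "unexposed"),
                         outcome = c("positive", "negative")))
}

#' Odds ratio with Wald confidence interval
#'
#' `OR = (a d)/(b c)`; 95% CI by the log-OR Wald method
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. With a zero cell
#' the OR is 0 or infinite and flagged; the Haldane-Anscombe correction
#' (add 0.5 to every cell) is available.
#'
#' @param tab A [contingency_2x2()].
#' @param conf_level Confidence level, default 0.95.
#' @param correction Apply the Haldane-Anscombe 0.5 correction
#'   (default `FALSE`).
#' @return List with `or`, `ci_low`, `ci_high`, `method`,
#'   `zero_cell` flag.
#' @export
odds_ratio <- function(tab, conf_level = 0.95, correction = FALSE) {
  stopifnot(inherits(tab, "contingency_2x2"))
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  zero <- any(cells == 0)
  method <- "wald"
  if (correction) {
    cells <- cells + 0.5
    method <- "wald_haldane_anscombe"
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (all(cells > 0) && is.finite(or) && or > 0) {
    se <- sqrt(sum(1 / cells))
    ci <- exp(log(or) + c(-1, 1) * z * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  list(or = or, ci_low = ci[1], ci_high = ci[2], method = method,
       zero_cell = zero && !correction)
}

#' Fisher's exact test (two-sided, point-probability rule)
#'
#' Conditional on both margins, the two-sided p-value sums the
#' hypergeometric probabilities of every table whose probability does
#' not exceed that of the observed table. The alternative "doubling"
#' rule (twice the smaller one-sided tail, capped at 1) is available.
#'
#' @param tab A [contingency_2x2()].
#' @param rule `"point"` (default) or `"double"`.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab, rule = c("point", "double")) {
  rule <- match.arg(rule)
  stopifnot(inherits(tab, "contingency_2x2"))
  m <- tab$a + tab$b        # exposed margin
  n <- tab$c + tab$d        # unexposed margin
  k <- tab$a + tab$c        # outcome-positive margin
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab$a, m, n, k)
  if (rule == "point") {
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(probs[support <= tab$a])
    upper <- sum(probs[support >= tab$a])
    p <- min(1, 2 * min(lower, upper))
  }
  min(1, p)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Thin wrapper over [stats::chisq.test()] with the package's table
#' orientation; errors on a zero margin, where the statistic is
#' undefined.
#'
#' @param tab A [contingency_2x2()].
#' @param yates Apply the Yates continuity correction (default `FALSE`).
#' @return List with `statistic` and `p_value` (1 df).
#' @export
chi_square <- function(tab, yates = FALSE) {
  stopifnot(inherits(tab, "contingency_2x2"))
  m <- as_matrix_2x2(tab)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: chi-square statistic undefined")
  ht <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Cochran-Armitage trend test for ordered proportions
#'
#' Tests for a linear trend in positivity across >= 3 ordered groups
#' (e.g. pTNM stage I-II / III / IV) with integer scores. The statistic
#' is `T = sum s_i (r_i - n_i p)` with variance
#' `p(1-p) (sum n_i s_i^2 - (sum n_i s_i)^2 / N)` under the pooled
#' proportion `p`; `z = T / sqrt(var)`, two-sided p from the normal
#' approximation (no continuity correction).
#'
#' @param positives Integer vector of positive counts per group.
#' @param n Integer vector of group sizes.
#' @param scores Numeric scores, default `0, 1, 2, ...`.
#' @return List with `z`, `p_value`, and the per-group `proportions`.
#' @export
cochran_armitage_trend <- function(positives, n,
                                   scores = seq_along(n) - 1) {
  stopifnot(length(positives) == length(n), length(n) >= 3L,
            length(scores) == length(n))
  if (any(positives < 0 | positives > n)) stop("need 0 <= positives <= n")
  N <- sum(n)
  R <- sum(positives)
  p <- R / N
  Tstat <- sum(scores * (positives - n * p))
  v <- p * (1 - p) * (sum(n * scores^2) - sum(n * scores)^2 / N)
  if (v <= .Machine$double.eps) {
    return(list(z = 0, p_value = 1, proportions = positives / n))
  }
  z <- Tstat / sqrt(v)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)),
       proportions = positives / n)
}

#' Materialize a 2x2 table from a per-sample call table
#'
#' Cross-tabulates a boolean call column against one level of a
#' categorical covariate. The resulting cells follow the printed table
#' layout: `a` = covariate-positive & call-positive, `b` =
#' covariate-positive & call-negative, `c` = covariate-negative &
#' call-positive, `d` = covariate-negative & call-negative (the odds
#' ratio is invariant to this transposition). Samples with a missing
#' covariate value are dropped and counted in `n_dropped`.
#'
#' @param calls Data frame with one row per sample, containing the call
#'   column and the covariate column.
#' @param exposure Name of a logical column (e.g. `"call_p16light"`).
#' @param outcome Name of a covariate column.
#' @param positive_level Covariate level treated as outcome-positive.
#' @return A [contingency_2x2()] with attribute `n_dropped`.
#' @export
build_contingency <- function(calls, exposure, outcome, positive_level) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) == 0L) stop("empty call table")
  if (!exposure %in% names(calls)) stop("unknown exposure column: ", exposure)
  if (!outcome %in% names(calls)) stop("unknown covariate: ", outcome)
  ex <- calls[[exposure]]
  ov <- calls[[outcome]]
  if (!is.logical(ex)) stop("exposure column must be logical")
  keep <- !is.na(ov)
  ex <- ex[keep]
  ov <- ov[keep]
  if (!positive_level %in% ov)
    stop("unknown level '", positive_level, "' for covariate ", outcome)
  if (length(unique(ov)) < 2L)
    stop("degenerate table: covariate ", outcome, " has a single level")
  pos <- ov == positive_level
  # rows follow the covariate (positive level first), columns the call,
  # matching the layout in which association tables are printed
  tab <- contingency_2x2(a = sum(pos & ex), b = sum(pos & !ex),
                         c = sum(!pos & ex), d = sum(!pos & !ex))
  attr(tab, "n_dropped") <- sum(!keep)
  tab
}

#' Association report for one exposure across covariates
#'
#' For each requested covariate/positive-level pair, builds the 2x2
#' table against the exposure call and reports the odds ratio with Wald
#' CI, chi-square p (when all expected counts are adequate) and
#' Fisher's exact p.
#'
#' @param calls Per-sample call table (see [build_contingency()]).
#' @param exposure Logical call column name.
#' @param outcomes Named character vector: `names()` are covariate
#'   columns, values are the positive level.
#' @return Data frame with one row per covariate: counts, `or`,
#'   `ci_low`, `ci_high`, `chisq_p`, `fisher_p`, `n_dropped`.
#' @export
associate <- function(calls, exposure, outcomes) {
  rows <- lapply(seq_along(outcomes), function(i) {
    cov <- names(outcomes)[i]
    lvl <- outcomes[[i]]
    tab <- build_contingency(calls, exposure, cov, lvl)
    orr <- odds_ratio(tab)
    chi <- tryCatch(chi_square(tab)$p_value, error = function(e) NA_real_)
    data.frame(covariate = cov, positive_level = lvl,
               a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
               chisq_p = chi, fisher_p = fisher_exact(tab),
               n_dropped = attr(tab, "n_dropped"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
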