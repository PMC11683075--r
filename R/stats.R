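# Between-group comparison protocol: Levene's test gating Student vs Welch,
# plus the Wilcoxon rank-sum test.

new_stat_result <- function(test_name, statistic, p_value, n1, n2, direction) {
  stopifnot(p_value >= 0, p_value <= 1 || is.na(p_value))
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n1 = n1, n2 = n2,
                 direction = direction),
            class = "hrl_stat")
}

#' @export
print.hrl_stat <- function(x, ...) {
  cat("<hrl_stat>", x$test_name, ": statistic =", format(x$statistic),
      ", p =", format.pval(x$p_value), ", n = (", x$n1, ",", x$n2,
      "), direction =", x$direction, "\n")
  invisible(x)
}

check_two_samples <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("both samples need at least 2 non-missing values")
  list(x = x, y = y)
}

#' Levene's test for equality of variances (center = mean)
#'
#' Classical Levene's test on absolute deviations from the group means,
#' computed by \code{car::leveneTest(center = mean)}. Two identical constant
#' samples are an exact no-evidence case and return W = 0, p = 1.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @return an \code{hrl_stat} with the W statistic and F-distribution p-value.
#' @export
levene_test <- function(x, y) {
  s <- check_two_samples(x, y); x <- s$x; y <- s$y
  z <- c(abs(x - mean(x)), abs(y - mean(y)))
  if (stats::var(z) == 0) {
    return(new_stat_result("levene", 0, 1, length(x), length(y),
                           sign(mean(x) - mean(y))))
  }
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  lt <- car::leveneTest(c(x, y), g, center = mean)
  new_stat_result("levene", lt[1, "F value"], lt[1, "Pr(>F)"],
                  length(x), length(y), sign(mean(x) - mean(y)))
}

#' Two-sample t-test (Student or Welch)
#'
#' Pooled-variance Student t with df \eqn{n_1 + n_2 - 2} when
#' \code{equal_variance}, Welch t with Satterthwaite df otherwise. Two-sided
#' p-value; the sign of the mean difference is reported separately in
#' \code{direction}.
#'
#' @inheritParams levene_test
#' @param equal_variance logical; pool the variances?
#' @return an \code{hrl_stat}.
#' @export
two_sample_t <- function(x, y, equal_variance = FALSE) {
  s <- check_two_samples(x, y); x <- s$x; y <- s$y
  tt <- stats::t.test(x, y, var.equal = equal_variance)
  new_stat_result(if (equal_variance) "student_t" else "welch_t",
                  tt$statistic, tt$p.value, length(x), length(y),
                  sign(mean(x) - mean(y)))
}

#' Levene-gated two-sample t-test
#'
#' The comparison protocol used throughout: run Levene's test first; if it
#' rejects equal variances at \code{variance_alpha}, use Welch's t-test,
#' otherwise Student's. The chosen branch is recorded in \code{test_name}.
#'
#' @inheritParams levene_test
#' @param variance_alpha significance level of the variance gate. Default 0.05.
#' @return an \code{hrl_stat} with \code{test_name} "student_t" or "welch_t".
#' @export
auto_t <- function(x, y, variance_alpha = 0.05) {
  lev <- levene_test(x, y)
  two_sample_t(x, y, equal_variance = lev$p_value >= variance_alpha)
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with midranks for ties. Exact enumeration
#' for small samples (both n <= 20, no ties), normal approximation with
#' continuity correction otherwise.
#'
#' @inheritParams levene_test
#' @return an \code{hrl_stat} with the W statistic; \code{direction} is the
#'   sign of the median difference.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  s <- check_two_samples(x, y); x <- s$x; y <- s$y
  ties <- any(duplicated(c(x, y)))
  use_exact <- max(length(x), length(y)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  new_stat_result("wilcoxon_rank_sum", wt$statistic, wt$p.value,
                  length(x), length(y),
                  sign(stats::median(x) - stats::median(y)))
}

#' Compare two condition results metric by metric
#'
#' Applies the comparison protocol to each shared metric column of two
#' replicate tables. Replicates with a missing metric value (e.g. a
#' zero-intake episode has no average reward per intake) are dropped for
#' that metric, and the drop count is reported.
#'
#' @param res_a,res_b \code{condition_result} data frames from
#'   \code{\link{run_condition}}.
#' @param metrics metric columns to compare; default all shared metric
#'   columns.
#' @param test \code{"auto_t"} (Levene-gated t, the default) or
#'   \code{"wilcoxon"}.
#' @return data frame report: one row per metric with the test name,
#'   statistic, p-value, direction (sign of mean difference, A minus B),
#'   sample sizes, drop count, and significance flags.
#' @export
compare_conditions <- function(res_a, res_b, metrics = NULL,
                               test = c("auto_t", "wilcoxon")) {
  test <- match.arg(test)
  reserved <- c("condition", "replicate", "seed")
  if (is.null(metrics))
    metrics <- setdiff(intersect(names(res_a), names(res_b)), reserved)
  if (!length(metrics)) stop("no shared metric columns to compare")
  rows <- lapply(metrics, function(mname) {
    a <- res_a[[mname]]; b <- res_b[[mname]]
    n_dropped <- sum(is.na(a)) + sum(is.na(b))
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    st <- if (test == "auto_t") auto_t(a, b) else wilcoxon_rank_sum(a, b)
    data.frame(metric = mname,
               condition_a = res_a$condition[1], condition_b = res_b$condition[1],
               test_name = st$test_name, statistic = st$statistic,
               p_value = st$p_value, direction = st$direction,
               n_a = st$n1, n_b = st$n2, n_dropped = n_dropped,
               significant_0.05 = st$p_value < 0.05,
               significant_0.001 = st$p_value < 0.001,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
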