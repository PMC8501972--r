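#' Significance stars for a p-value
#'
#' The annotation convention used throughout the assay's figures:
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Character vector of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
p_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Two-sample Student's t-test on normalized enrichment values
#'
#' Two-sided, pooled-variance (equal-variance) Student's t by default, the
#' test the assay reports; degrees of freedom are n_a + n_b - 2. A Welch
#' (unequal-variance) variant is available behind `var_equal = FALSE` but is
#' off by default.
#'
#' @param a,b numeric vectors of per-cell normalized values (each n >= 2).
#' @param label_a,label_b group labels carried into the result.
#' @param var_equal pool the variances (classical Student's t) when `TRUE`.
#' @return An object of class `rf3h_ttest` with fields `group_a`, `group_b`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`, `t_statistic`, `df`, `p_value`,
#'   `stars`, `method`. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' students_t_test(c(1, 2, 3), c(1, 2, 3, 4))
students_t_test <- function(a, b, label_a = "a", label_b = "b",
                            var_equal = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least 2 non-missing values for a t-test.")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal, alternative = "two.sided")
  structure(
    list(group_a = label_a, group_b = label_b,
         mean_a = mean(a), mean_b = mean(b),
         n_a = length(a), n_b = length(b),
         t_statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value), stars = p_stars(ht$p.value),
         method = if (var_equal) "Student (pooled variance)" else "Welch"),
    class = "rf3h_ttest"
  )
}

#' @export
print.rf3h_ttest <- function(x, ...) {
  cat(sprintf("%s t-test: %s (n=%d, mean %.3g) vs %s (n=%d, mean %.3g)\n",
              x$method, x$group_a, x$n_a, x$mean_a, x$group_b, x$n_b, x$mean_b))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g %s\n",
              x$t_statistic, x$df, x$p_value, x$stars))
  invisible(x)
}

#' @rdname students_t_test
#' @param x an `rf3h_ttest` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.rf3h_ttest <- function(x, ...) {
  tibble(group_a = x$group_a, group_b = x$group_b,
         mean_a = x$mean_a, mean_b = x$mean_b,
         n_a = x$n_a, n_b = x$n_b,
         t_statistic = x$t_statistic, df = x$df,
         p_value = x$p_value, stars = x$stars)
}

#' @rdname students_t_test
#' @exportS3Method generics::glance
glance.rf3h_ttest <- function(x, ...) {
  tibble(t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
         stars = x$stars, method = x$method)
}

#' Compare every condition against the control group
#'
#' Runs the two-sample Student's t-test of each non-control condition's
#' normalized values against the control's, one row per comparison. No
#' multiple-testing correction is applied; comparisons are reported
#' marginally, as the assay's figures do.
#'
#' @param records normalized measurement tibble (QC-passing cells are used).
#' @param control control condition label.
#' @param var_equal see [students_t_test()].
#' @return Tibble with one row per comparison: `group_a` (condition),
#'   `group_b` (control), means, ns, `t_statistic`, `df`, `p_value`,
#'   `stars`.
#' @export
compare_to_control <- function(records, control, var_equal = TRUE) {
  vals <- records %>% filter(.data$qc_pass, !is.na(.data$normalized_value))
  if (!control %in% vals$condition) {
    abort(sprintf("Control condition '%s' has no usable cells.", control))
  }
  ctrl_vals <- vals$normalized_value[vals$condition == control]
  others <- setdiff(unique(vals$condition), control)
  purrr::map_dfr(others, function(cond) {
    tidy(students_t_test(vals$normalized_value[vals$condition == cond],
                         ctrl_vals, label_a = cond, label_b = control,
                         var_equal = var_equal))
  })
}
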