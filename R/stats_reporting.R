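#' Condition-level summary of per-cell localization fractions
#'
#' Mirrors the box-plot reporting convention used for per-cell
#' localization data: median, first/third quartiles (hinges), whiskers,
#' plus mean and sample standard deviation, with the number of cells and
#' embryos recorded (cells, typically 25 from 5 embryos, are the unit of
#' analysis). Quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7).
#'
#' @param table A `cell_fraction_table` (see [cell_fraction_table()]).
#' @param condition,stage Optional filters; `NULL` keeps all rows.
#' @param whiskers `"tukey"` (most extreme values within 1.5 IQR of the
#'   hinges, the ggplot2 default) or `"minmax"`.
#' @return One-row data frame: `condition`, `stage`, `n_cells`,
#'   `n_embryos`, `mean`, `stdev`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`.
#' @export
summarize_condition <- function(table, condition = NULL, stage = NULL,
                                whiskers = c("tukey", "minmax")) {
  whiskers <- match.arg(whiskers)
  stopifnot(is.data.frame(table), "fraction_percent" %in% names(table))
  rows <- table
  if (!is.null(condition)) rows <- rows[rows$condition %in% condition, , drop = FALSE]
  if (!is.null(stage)) rows <- rows[rows$stage %in% stage, , drop = FALSE]
  if (nrow(rows) == 0L) stop("empty group: no cells match the requested condition/stage")
  if (nrow(rows) < 2L) stop("a condition summary needs >= 2 cells (have ",
                            nrow(rows), ")")
  v <- rows$fraction_percent
  q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
  if (whiskers == "tukey") {
    iqr <- q[3L] - q[1L]
    lo <- min(v[v >= q[1L] - 1.5 * iqr])
    hi <- max(v[v <= q[3L] + 1.5 * iqr])
  } else {
    lo <- min(v); hi <- max(v)
  }
  data.frame(condition = paste(unique(rows$condition), collapse = "+"),
             stage = paste(unique(rows$stage), collapse = "+"),
             n_cells = length(v), n_embryos = length(unique(rows$embryo_id)),
             mean = mean(v), stdev = stats::sd(v), median = q[2L],
             q1 = q[1L], q3 = q[3L], whisker_low = lo, whisker_high = hi,
             stringsAsFactors = FALSE)
}

#' Welch t-test between two groups of per-cell fractions
#'
#' Unequal-variance (Welch) t-test with Welch-Satterthwaite degrees of
#' freedom, the convention for comparing per-cell localization fractions
#' between conditions. One-tailed p-values use the caller-specified
#' direction; the two-tailed p doubles the smaller tail. When both groups
#' have zero variance and equal means the comparison is degenerate and
#' `t = 0, p = 1` is returned by convention (with a message).
#'
#' @param group_a,group_b Numeric vectors (>= 2 finite values each).
#' @param tails 1 or 2.
#' @param direction For one-tailed tests: `"greater"` tests whether
#'   `group_a` exceeds `group_b`; `"less"` the reverse.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return A list: `t`, `df`, `p`, `tails`, `method`.
#' @export
t_test <- function(group_a, group_b, tails = 2,
                   direction = c("greater", "less"), var_equal = FALSE) {
  direction <- match.arg(direction)
  stopifnot(tails %in% c(1, 2))
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 finite values")
  method <- if (var_equal) "Student" else "Welch"
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      message("both groups constant with equal means: t = 0, p = 1 by convention")
      return(list(t = 0, df = length(group_a) + length(group_b) - 2,
                  p = 1, tails = tails, method = method))
    }
    message("both groups constant with different means: p = 0 by convention")
    tt <- if (mean(group_a) > mean(group_b)) Inf else -Inf
    p1 <- if ((direction == "greater") == (tt > 0)) 0 else 1
    return(list(t = tt, df = length(group_a) + length(group_b) - 2,
                p = if (tails == 2) 0 else p1, tails = tails, method = method))
  }
  alt <- if (tails == 2) "two.sided" else direction
  ht <- stats::t.test(group_a, group_b, alternative = alt,
                      var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), tails = tails, method = method)
}

#' Significance star labels
#'
#' The figure-legend convention: `p >= 0.05` is not significant ("n.s.");
#' `p < 0.05` one star, `p < 0.01` two, `p < 0.001` three. Boundaries are
#' strict (`p = 0.05` is "n.s.").
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s.")))
}

#' Dot-plot with box-plot of per-cell fractions by condition
#'
#' Box (median + hinges + whiskers), jittered per-cell dots, a red dot at
#' the mean, and significance stars for requested pairwise comparisons.
#' The underlying condition summaries are also written as CSV next to the
#' figure so every plotted number is regenerable.
#'
#' @param table A `cell_fraction_table`.
#' @param comparisons Optional list of pairwise comparisons, each a list
#'   with `a`, `b` (condition names), and optionally `tails` (default 2)
#'   and `direction` (default "greater").
#' @param file Optional figure path (PNG/SVG/PDF by extension); the
#'   summary CSV goes to `<file>_summary.csv`. `NULL` skips writing.
#' @param whiskers Passed to [summarize_condition()].
#' @return The ggplot object, invisibly; attribute `summary` holds the
#'   per-condition summary table, attribute `tests` the comparison table.
#' @export
render_boxplot <- function(table, comparisons = NULL, file = NULL,
                           whiskers = "tukey") {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  conds <- unique(table$condition)
  summ <- do.call(rbind, lapply(conds, function(cc)
    summarize_condition(table, condition = cc, whiskers = whiskers)))
  tests <- NULL
  if (!is.null(comparisons)) {
    tests <- do.call(rbind, lapply(comparisons, function(cmp) {
      if (!all(c(cmp$a, cmp$b) %in% conds))
        stop("comparison references unknown condition: ",
             paste(setdiff(c(cmp$a, cmp$b), conds), collapse = ", "))
      ta <- table$fraction_percent[table$condition == cmp$a]
      tb <- table$fraction_percent[table$condition == cmp$b]
      res <- t_test(ta, tb, tails = cmp$tails %||% 2,
                    direction = cmp$direction %||% "greater")
      data.frame(a = cmp$a, b = cmp$b, t = res$t, df = res$df, p = res$p,
                 tails = res$tails, stars = significance_stars(res$p),
                 stringsAsFactors = FALSE)
    }))
  }
  cond <- fraction_percent <- NULL  # appease R CMD check NSE
  gg <- ggplot2::ggplot(table, ggplot2::aes(x = condition, y = fraction_percent)) +
    ggplot2::geom_boxplot(outlier.shape = NA,
                          coef = if (whiskers == "tukey") 1.5 else Inf) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red", size = 2) +
    ggplot2::labs(y = "localized mRNA (% of total)", x = NULL)
  if (!is.null(tests) && nrow(tests)) {
    ymax <- max(table$fraction_percent)
    step <- 0.08 * max(ymax, 1)
    for (i in seq_len(nrow(tests))) {
      xa <- match(tests$a[i], conds); xb <- match(tests$b[i], conds)
      yy <- ymax + i * step
      gg <- gg + ggplot2::annotate("segment", x = xa, xend = xb, y = yy, yend = yy) +
        ggplot2::annotate("text", x = (xa + xb) / 2, y = yy + 0.4 * step,
                          label = tests$stars[i], size = 3)
    }
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = 1.2 + 1.1 * length(conds), height = 4,
                    dpi = 150)
    utils::write.csv(summ, paste0(tools::file_path_sans_ext(file),
                                  "_summary.csv"), row.names = FALSE)
    if (!is.null(tests))
      utils::write.csv(tests, paste0(tools::file_path_sans_ext(file),
                                     "_tests.csv"), row.names = FALSE)
  }
  attr(gg, "summary") <- summ
  attr(gg, "tests") <- tests
  invisible(gg)
}
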