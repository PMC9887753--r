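#' Unpaired two-tailed t test between two groups
#'
#' Classic Student t test (pooled variance, two-sided), reporting group
#' means with standard errors of the mean as in figure-legend style.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 values.
#' @param labels Group labels (length 2).
#' @param metric Name of the compared quantity, for reporting.
#' @return A `group_comparison`: list with `metric`, `groups`, `n`, `means`,
#'   `sems`, `test`, `statistic`, `df`, `p_value`, `posthoc` (NULL here) and
#'   a figure-legend style `summary` string.
#' @export
compare_two_groups <- function(values_a, values_b,
                               labels = c("group1", "group2"),
                               metric = "value") {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stopf("each group needs at least 2 finite values")
  }
  if (var(values_a) == 0 && var(values_b) == 0) {
    stopf("zero variance in both groups; the t test is undefined")
  }
  tt <- t.test(values_a, values_b, var.equal = TRUE,
               alternative = "two.sided")
  means <- c(mean(values_a), mean(values_b))
  sems <- c(sd(values_a) / sqrt(length(values_a)),
            sd(values_b) / sqrt(length(values_b)))
  structure(list(
    metric = metric, groups = labels,
    n = c(length(values_a), length(values_b)),
    means = means, sems = sems,
    test = "unpaired two-tailed t test",
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = unname(tt$p.value), posthoc = NULL,
    summary = sprintf(
      "%s: %s %.3g +/- %.3g (n=%d) vs %s %.3g +/- %.3g (n=%d), mean +/- SEM, P = %.3g",
      metric, labels[1], means[1], sems[1], length(values_a),
      labels[2], means[2], sems[2], length(values_b), tt$p.value)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", x$summary, "\n")
  if (!is.null(x$posthoc)) {
    cat("post hoc (", attr(x$posthoc, "adjust"), "):\n", sep = "")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Sidak adjustment of p-values
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons.
#'
#' @param p Raw p-values.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  pmin(1, 1 - (1 - p)^m)
}

#' One- or two-way ANOVA with Sidak or Tukey post hoc comparisons
#'
#' One-way: omnibus F over `groups`; pairwise comparisons use the pooled
#' residual variance and are Sidak-adjusted (default) or Tukey-adjusted
#' (studentized range). Two-way: full-factorial `y ~ A * B` (all cells must
#' be present); the omnibus table reports both main effects and the
#' interaction, and pairwise comparisons run over the `A:B` cell means.
#'
#' @param values Numeric response vector.
#' @param groups Factor (or coercible) of group labels; for two-way, the
#'   first factor.
#' @param design `"one-way"` or `"two-way"`.
#' @param factor2 Second factor for the two-way design.
#' @param adjust `"sidak"` or `"tukey"`.
#' @param metric Name of the compared quantity, for reporting.
#' @return A `group_comparison` with `posthoc`: a data.frame of pairwise
#'   contrasts (`contrast`, `diff`, `t`, `p_raw`, `p_adj`).
#' @export
compare_multi_groups <- function(values, groups,
                                 design = c("one-way", "two-way"),
                                 factor2 = NULL,
                                 adjust = c("sidak", "tukey"),
                                 metric = "value") {
  design <- match.arg(design)
  adjust <- match.arg(adjust)
  keep <- is.finite(values)
  values <- values[keep]
  g1 <- factor(groups[keep])

  if (design == "one-way") {
    if (nlevels(g1) < 3L) stopf("one-way design needs at least 3 groups")
    dat <- data.frame(y = values, g = g1)
    fit <- aov(y ~ g, data = dat)
    cells <- g1
  } else {
    if (is.null(factor2)) stopf("two-way design needs factor2")
    g2 <- factor(factor2[keep])
    tab <- table(g1, g2)
    if (any(tab == 0)) {
      stopf("two-way design requires every factor combination to be present")
    }
    dat <- data.frame(y = values, a = g1, b = g2)
    fit <- aov(y ~ a * b, data = dat)
    cells <- interaction(g1, g2, sep = ":", drop = TRUE)
  }

  an <- summary(fit)[[1]]
  rownames(an) <- trimws(rownames(an))
  df_res <- fit$df.residual
  mse <- an["Residuals", "Mean Sq"]
  # relative guard: numerically-zero residual variance (constant groups)
  if (!is.finite(mse) || mse <= max(mean(values^2), 1e-300) * 1e-20) {
    stopf("zero within-group variance; the omnibus F is undefined")
  }
  omni <- an[rownames(an) != "Residuals", , drop = FALSE]

  lev <- levels(cells)
  nlev <- length(lev)
  ns <- tapply(values, cells, length)
  ms <- tapply(values, cells, mean)
  ses <- tapply(values, cells, sd) / sqrt(ns)
  pairs <- utils::combn(nlev, 2)
  m <- ncol(pairs)
  ph <- data.frame(contrast = character(m), diff = numeric(m),
                   t = numeric(m), p_raw = numeric(m), p_adj = numeric(m),
                   stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(mse * (1 / ns[i1] + 1 / ns[i2]))
    tstat <- (ms[i1] - ms[i2]) / se
    p_raw <- 2 * pt(-abs(tstat), df_res)
    p_adj <- if (adjust == "sidak") {
      sidak_adjust(p_raw, m)
    } else {
      ptukey(abs(tstat) * sqrt(2), nlev, df_res, lower.tail = FALSE)
    }
    ph$contrast[j] <- paste(lev[i1], "-", lev[i2])
    ph$diff[j] <- ms[i1] - ms[i2]
    ph$t[j] <- tstat
    ph$p_raw[j] <- p_raw
    ph$p_adj[j] <- min(1, p_adj)
  }
  attr(ph, "adjust") <- adjust

  omni_p <- omni[["Pr(>F)"]]
  structure(list(
    metric = metric, groups = lev, n = as.integer(ns),
    means = as.numeric(ms), sems = as.numeric(ses),
    test = sprintf("%s ANOVA + %s post hoc", design,
                   if (adjust == "sidak") "Sidak" else "Tukey"),
    statistic = omni[["F value"]], df = c(omni[["Df"]], df_res),
    p_value = omni_p, omnibus = omni, posthoc = ph,
    summary = sprintf("%s: %s ANOVA omnibus P = %s", metric, design,
                      paste(sprintf("%.3g", omni_p), collapse = " / "))
  ), class = "group_comparison")
}

#' Stratify values into bottom- and top-quartile groups with IQR cleaning
#'
#' Q1 and Q3 are computed on the full vector (linear-interpolation quantile,
#' type 7 by default); values at or below Q1 form the low group, values at
#' or above Q3 the high group. Within each group, values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (IQR from the full vector) are then moved
#' to the excluded-outliers set.
#'
#' @param values Numeric vector, at least 8 values, not all identical.
#' @param ids Identifiers parallel to `values`; defaults to names or
#'   positions.
#' @param quantile_type Quantile convention passed to [stats::quantile()]
#'   (recorded in the output).
#' @return A `quantile_strata`: `low_ids`, `high_ids`,
#'   `excluded_outlier_ids`, pre-exclusion `assigned_low` / `assigned_high`,
#'   `q1`, `q3`, `iqr`, `fences`, `quantile_type`.
#' @export
stratify_quartiles <- function(values, ids = NULL, quantile_type = 7) {
  if (is.null(ids)) {
    ids <- if (!is.null(names(values))) names(values) else seq_along(values)
  }
  if (length(ids) != length(values)) stopf("ids and values lengths differ")
  keep <- is.finite(values)
  values <- values[keep]; ids <- ids[keep]
  if (length(values) < 8L) {
    stopf("need at least 8 values to stratify, got %d", length(values))
  }
  q <- quantile(values, c(0.25, 0.75), type = quantile_type, names = FALSE)
  if (q[1] == q[2]) {
    stopf("degenerate quartiles (Q1 == Q3); values are too concentrated")
  }
  iqr <- q[2] - q[1]
  fences <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)

  lo <- values <= q[1]
  hi <- values >= q[2]
  out <- values < fences[1] | values > fences[2]
  structure(list(
    low_ids = ids[lo & !out],
    high_ids = ids[hi & !out],
    excluded_outlier_ids = ids[(lo | hi) & out],
    assigned_low = ids[lo], assigned_high = ids[hi],
    q1 = q[1], q3 = q[2], iqr = iqr, fences = fences,
    quantile_type = quantile_type
  ), class = "quantile_strata")
}

#' Write a group comparison as TSV (+ JSON diagnostics)
#'
#' @param cmp A `group_comparison`.
#' @param path Output TSV path; a JSON twin with the full object is written
#'   alongside as `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_comparison_tsv <- function(cmp, path) {
  df <- data.frame(metric = cmp$metric, group = cmp$groups, n = cmp$n,
                   mean = cmp$means, sem = cmp$sems, test = cmp$test,
                   p_value = paste(sprintf("%.6g", cmp$p_value),
                                   collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cmp), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", force = TRUE)
  invisible(path)
}
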