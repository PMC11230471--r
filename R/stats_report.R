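#' t-tests with the reporting conventions used here
#'
#' One-sample, paired and unpaired (Student, equal-variance by default)
#' t-tests with one- or two-tailed p-values, wrapping the classical test
#' behind a uniform result record. Degenerate (zero-variance) inputs do not
#' error: with a zero effect the statistic is reported as 0 with p = 1, with
#' a nonzero effect as signed infinity with the limiting p (0 in the tested
#' tail, 1 otherwise), and the result carries a `degenerate` flag.
#'
#' @param x numeric vector (first group / differences source).
#' @param y second group (unpaired) or paired counterpart; `NULL` for
#'   one-sample.
#' @param kind `"one_sample"`, `"paired"` or `"unpaired"`.
#' @param tail `"two"`, `"left"` (effect < null) or `"right"` (effect > null).
#' @param null_value null hypothesis value (one-sample / paired difference).
#' @param var_equal unpaired only: pooled-variance Student test (default) or
#'   Welch when `FALSE`.
#' @param labels optional group labels (length 2 for unpaired/paired).
#' @return A list of class `"t_test_result"`: `test_kind`, `tail`, `n` (or
#'   `n1`,`n2`), `statistic`, `df`, `p_value`, `effect` (mean difference or
#'   mean - null), `mean`, `sem`, `degenerate`, `labels`.
#' @export
t_test <- function(x, y = NULL, kind = c("one_sample", "paired", "unpaired"),
                   tail = c("two", "left", "right"), null_value = 0,
                   var_equal = TRUE, labels = NULL) {
  kind <- match.arg(kind)
  tail <- match.arg(tail)
  alternative <- switch(tail, two = "two.sided", left = "less",
                        right = "greater")
  if (kind == "one_sample") {
    if (!is.null(y)) stop("one_sample takes a single vector")
    if (length(x) < 2) stop("precondition error: n >= 2 required")
    d <- x - null_value
  } else {
    if (is.null(y)) stop(kind, " requires two vectors")
    if (length(x) < 2 || length(y) < 2) {
      stop("precondition error: n >= 2 per group required")
    }
    if (kind == "paired" && length(x) != length(y)) {
      stop("precondition error: paired samples must have equal lengths")
    }
    d <- if (kind == "paired") x - y - null_value else NULL
  }
  # zero variance up to float jitter (t.test rejects "essentially constant"
  # data at ~10 eps of the mean; use the same relative scale)
  near_zero <- function(v) {
    sd(v) <= 1e-12 * (abs(mean(v)) + max(abs(v)) + 1)
  }
  degenerate <- if (kind == "unpaired") {
    near_zero(x) && near_zero(y)
  } else {
    near_zero(d)
  }
  effect <- if (kind == "unpaired") mean(x) - mean(y) - null_value else mean(d)
  if (degenerate) {
    statistic <- if (effect == 0) 0 else sign(effect) * Inf
    p <- if (effect == 0) 1 else {
      switch(tail,
             two = 0,
             left = if (effect < 0) 0 else 1,
             right = if (effect > 0) 0 else 1)
    }
    df <- switch(kind, one_sample = length(x) - 1, paired = length(x) - 1,
                 unpaired = length(x) + length(y) - 2)
  } else {
    tt <- if (kind == "unpaired") {
      stats::t.test(x, y, alternative = alternative, mu = null_value,
                    var.equal = var_equal)
    } else if (kind == "paired") {
      stats::t.test(x, y, alternative = alternative, mu = null_value,
                    paired = TRUE)
    } else {
      stats::t.test(x, alternative = alternative, mu = null_value)
    }
    statistic <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  res <- list(test_kind = kind, tail = tail, statistic = statistic, df = df,
              p_value = p, effect = effect, degenerate = degenerate,
              labels = labels)
  if (kind == "unpaired") {
    res$n1 <- length(x)
    res$n2 <- length(y)
    res$mean <- c(mean(x), mean(y))
    res$sem <- c(sd(x) / sqrt(length(x)), sd(y) / sqrt(length(y)))
  } else {
    res$n <- length(x)
    res$mean <- mean(if (kind == "paired") x - y else x)
    res$sem <- sd(if (kind == "paired") x - y else x) / sqrt(length(x))
  }
  class(res) <- "t_test_result"
  res
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t test, %s tailed: t = %.4g, df = %.4g, p = %.4g%s\n",
              gsub("_", " ", x$test_kind), x$tail, x$statistic, x$df,
              x$p_value, if (x$degenerate) " (degenerate variance)" else ""))
  invisible(x)
}

#' Significance stars
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `"ns"` otherwise.
#'
#' @param p p-value(s).
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) NA_character_
    else if (pp < 0.001) "***"
    else if (pp < 0.01) "**"
    else if (pp < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Group-level report table
#'
#' Assembles a figure-legend-style table from per-session metric values:
#' per-group n, mean, SEM (and median, min, max), plus the requested test.
#' With `test = "one_sample"` each group is tested against `null_value`; with
#' `"paired"` or `"unpaired"` the two groups named by `compare` (default: the
#' first two) are tested against each other and the test is reported on the
#' first of them. Groups with n = 1 get descriptives only and a note.
#'
#' @param values numeric metric values, one per session.
#' @param groups group label per value.
#' @param test `"none"`, `"one_sample"`, `"paired"` or `"unpaired"`.
#' @param tail passed to [t_test()].
#' @param null_value one-sample null.
#' @param compare which two groups to test (character length 2).
#' @return A data.frame: `group, n, mean, sem, median, min, max, test, tail,
#'   t, df, p, stars, note`.
#' @export
group_report <- function(values, groups,
                         test = c("none", "one_sample", "paired", "unpaired"),
                         tail = "two", null_value = 0, compare = NULL) {
  test <- match.arg(test)
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  levs <- unique(groups)
  out <- do.call(rbind, lapply(levs, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               median = median(v), min = min(v), max = max(v),
               test = "none", tail = NA_character_, t = NA_real_,
               df = NA_real_, p = NA_real_, stars = NA_character_,
               note = "")
  }))
  run_test <- function(g1, v1, v2 = NULL, kind) {
    i <- which(out$group == g1)
    if (length(v1) < 2 || (!is.null(v2) && length(v2) < 2)) {
      out$note[i] <<- "test skipped: n < 2"
      return(invisible())
    }
    tt <- t_test(v1, v2, kind = kind, tail = tail, null_value = null_value)
    out$test[i] <<- kind
    out$tail[i] <<- tail
    out$t[i] <<- tt$statistic
    out$df[i] <<- tt$df
    out$p[i] <<- tt$p_value
    out$stars[i] <<- p_stars(tt$p_value)
    if (tt$degenerate) out$note[i] <<- "degenerate variance"
  }
  if (test == "one_sample") {
    for (g in levs) run_test(g, values[groups == g], kind = "one_sample")
  } else if (test %in% c("paired", "unpaired")) {
    cmp <- compare %||% head(levs, 2)
    if (length(cmp) != 2 || !all(cmp %in% levs)) {
      stop("parameter error: compare must name two present groups")
    }
    run_test(cmp[1], values[groups == cmp[1]], values[groups == cmp[2]], test)
  }
  rownames(out) <- NULL
  out
}
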