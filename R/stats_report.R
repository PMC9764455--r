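# Group-comparison conventions used throughout the pipeline: pooled
# two-sample Student t-tests (two-tailed or right-tailed), mean/SD/2SD
# summaries, and a pipeline-level comparison report over metric tables.

#' Two-sample Student t-test with the pipeline's conventions
#'
#' Pooled-variance Student t by default (Welch via `var_equal = FALSE`).
#' The statistic is oriented as `mean(b) - mean(a)`, so the right tail
#' tests whether the *second* group is greater; the orientation is echoed
#' in the result to prevent silent sign errors. Degenerate input (zero
#' pooled variance) yields `t = 0, p = 1` when the means are equal and an
#' error otherwise.
#'
#' @param a,b numeric vectors of per-individual measurements (n >= 2
#'   each).
#' @param tail `"two"` or `"right"` (right = `mean(b) > mean(a)`).
#' @param var_equal pooled variance (TRUE, default) or Welch.
#' @return object of class `phq_ttest`: `statistic`, `df`, `p`, `tail`,
#'   `means`, `sds`, `n`, `orientation`.
#' @examples
#' t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
t_test <- function(a, b, tail = c("two", "right"), var_equal = TRUE) {
  tail <- match.arg(tail)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("both samples need n >= 2")
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b)))) {
    stop("samples must be finite and complete")
  }
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) {
      if (ma == mb) {
        return(new_phq_ttest(0, na + nb - 2, 1, tail, ma, mb,
                             sqrt(va), sqrt(vb), na, nb))
      }
      stop("zero pooled variance with unequal means; t is degenerate")
    }
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    if (va == 0 && vb == 0) {
      if (ma == mb) {
        return(new_phq_ttest(0, na + nb - 2, 1, tail, ma, mb, 0, 0, na, nb))
      }
      stop("zero variance with unequal means; t is degenerate")
    }
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tt <- (mb - ma) / se
  p <- if (tail == "two") {
    2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  } else {
    stats::pt(tt, df, lower.tail = FALSE)
  }
  new_phq_ttest(tt, df, p, tail, ma, mb, sqrt(va), sqrt(vb), na, nb)
}

new_phq_ttest <- function(tt, df, p, tail, ma, mb, sda, sdb, na, nb) {
  structure(
    list(statistic = tt, df = df, p = p, tail = tail,
         means = c(a = ma, b = mb), sds = c(a = sda, b = sdb),
         n = c(a = na, b = nb),
         orientation = "t > 0 means the second group (b) is greater"),
    class = "phq_ttest"
  )
}

#' @export
print.phq_ttest <- function(x, ...) {
  cat(sprintf(
    "Student t: t = %.4g, df = %.4g, p = %.4g (%s-tailed)\n  mean a = %.4g (sd %.4g, n %d); mean b = %.4g (sd %.4g, n %d)\n  %s\n",
    x$statistic, x$df, x$p, x$tail, x$means["a"], x$sds["a"], x$n["a"],
    x$means["b"], x$sds["b"], x$n["b"], x$orientation
  ))
  invisible(x)
}

#' Mean, SD and 2-SD interval of a sample
#'
#' The summary convention used in the figures this pipeline feeds:
#' centre line = mean, box = one SD, tails = two SDs (~95% for a normal
#' sample). Sample SD uses the n - 1 denominator; with a single value the
#' SD and interval are reported missing.
#'
#' @param x numeric vector (n >= 1).
#' @return list with `mean`, `sd`, `interval` (`mean -/+ 2 sd`), `n`.
#' @export
group_summary <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 1 || anyNA(x)) stop("need >= 1 finite values")
  m <- mean(x)
  s <- if (length(x) > 1) stats::sd(x) else NA_real_
  list(mean = m, sd = s,
       interval = if (is.na(s)) c(NA_real_, NA_real_) else c(m - 2 * s,
                                                             m + 2 * s),
       n = length(x))
}

#' Pipeline-level group-comparison report
#'
#' Takes a long metric table (one row per individual measurement) and,
#' for every metric, computes group summaries and the requested t-test
#' between the two groups. No multiple-testing adjustment is applied by
#' default — raw p values are reported, with a printed caveat when more
#' than 10 metrics are tested; pass `adjust` for Benjamini-Hochberg or
#' other [stats::p.adjust()] methods. Metrics missing for a group are
#' reported as absent, never imputed; with a single group only summaries
#' are produced.
#'
#' @param data long data frame with columns `metric`, `group`, `value`
#'   (and optionally `sample_id`).
#' @param tail `"two"` or `"right"`, passed to [t_test()]; right tests
#'   the second group level greater.
#' @param reference reference group (the `a` side); default: first
#'   appearing group.
#' @param adjust p-adjustment method (default `"none"`).
#' @param alpha significance level used for the `flagged` column.
#' @return object of class `phq_report`: `table` (per-metric data frame
#'   with means, SDs, n, t, df, p, `flagged`) and `groups`.
#' @export
comparison_report <- function(data, tail = c("two", "right"),
                              reference = NULL, adjust = "none",
                              alpha = 0.05) {
  tail <- match.arg(tail)
  stopifnot(all(c("metric", "group", "value") %in% names(data)))
  groups <- unique(as.character(data$group))
  if (length(groups) > 2) stop("comparison_report supports 1 or 2 groups")
  if (is.null(reference)) reference <- groups[1]
  other <- setdiff(groups, reference)
  metrics <- unique(as.character(data$metric))
  if (length(metrics) > 10 && length(groups) == 2) {
    message(sprintf(
      "note: %d metrics tested without multiple-testing adjustment%s",
      length(metrics),
      if (adjust == "none") "; raw p values reported" else ""
    ))
  }
  rows <- lapply(metrics, function(mt) {
    d <- data[data$metric == mt & is.finite(data$value), ]
    va <- d$value[d$group == reference]
    row <- data.frame(metric = mt,
                      mean_a = NA_real_, sd_a = NA_real_, n_a = length(va),
                      mean_b = NA_real_, sd_b = NA_real_, n_b = NA_integer_,
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      note = "")
    if (length(va) >= 1) {
      sa <- group_summary(va)
      row$mean_a <- sa$mean; row$sd_a <- sa$sd
    }
    if (length(groups) == 2) {
      vb <- d$value[d$group == other]
      row$n_b <- length(vb)
      if (length(vb) >= 1) {
        sb <- group_summary(vb)
        row$mean_b <- sb$mean; row$sd_b <- sb$sd
      }
      if (length(va) >= 2 && length(vb) >= 2) {
        tt <- t_test(va, vb, tail = tail)
        row$t <- tt$statistic; row$df <- tt$df; row$p <- tt$p
      } else {
        row$note <- "metric absent or underpowered in a group"
      }
    }
    row
  })
  tab <- do.call(rbind, rows)
  if (length(groups) == 2) {
    tab$p_adj <- stats::p.adjust(tab$p, method = adjust)
    tab$flagged <- !is.na(tab$p_adj) & tab$p_adj < alpha
  }
  structure(
    list(table = tab, groups = c(reference = reference, other = other),
         tail = tail, adjust = adjust, alpha = alpha),
    class = "phq_report"
  )
}

#' @export
print.phq_report <- function(x, ...) {
  cat(sprintf("Comparison report: %s%s, %s-tailed t, adjust = %s\n",
              x$groups[["reference"]],
              if (length(x$groups) > 1) paste0(" vs ", x$groups[["other"]]) else "",
              x$tail, x$adjust))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to CSV and JSON
#'
#' @param report a [comparison_report()].
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "phq_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "report.csv")
  js <- file.path(dir, "report.json")
  utils::write.csv(report$table, csv, row.names = FALSE)
  jsonlite::write_json(
    list(groups = as.list(report$groups), tail = report$tail,
         adjust = report$adjust, alpha = report$alpha,
         table = report$table),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(csv = csv, json = js))
}
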