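#' Build the animals x time-points group table
#'
#' Assembles the repeated-measures table feeding [rm_anova()]: one row per
#' animal, one column per 15-min interval end label, including the
#' pre-injection control (the `(-15, 0]` interval, label 0, shown as
#' `"pre"`). Every session must cover every requested label.
#'
#' @param traces Named list of interval traces, one per animal: each either
#'   an `interval_series` in trace mode ([average_intervals()]) or a list
#'   with `labels` and `values`.
#' @param labels Numeric label set to use; defaults to the labels of the
#'   first session.
#' @return An object of class `group_time_series`: list with `values`
#'   (matrix animals x labels, dF/F0 %), `labels` (numeric, 0 = pre) and
#'   `animals`.
#' @export
build_group_table <- function(traces, labels = NULL) {
  stopifnot(is.list(traces), length(traces) >= 2)
  if (is.null(names(traces)) || any(names(traces) == "")) {
    names(traces) <- paste0("animal", seq_along(traces))
  }
  labels <- labels %||% traces[[1]]$labels
  vals <- matrix(NA_real_, length(traces), length(labels),
                 dimnames = list(names(traces),
                                 ifelse(labels == 0, "pre",
                                        format(labels, trim = TRUE))))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    pos <- match(labels, tr$labels)
    if (anyNA(pos)) {
      stop(sprintf("session `%s` does not cover label(s): %s",
                   names(traces)[i],
                   paste(labels[is.na(pos)], collapse = ", ")),
           call. = FALSE)
    }
    vals[i, ] <- tr$values[pos]
  }
  structure(list(values = vals, labels = labels, animals = names(traces)),
            class = "group_time_series")
}

#' One-way repeated-measures ANOVA with paired post-hoc vs the pre control
#'
#' Partitions the total sum of squares of the complete animals x labels
#' table into subject, time and error components with the standard
#' two-way (subject x time, one observation per cell) decomposition:
#' `SS_subject = k * sum((row means - grand)^2)`,
#' `SS_time = n * sum((column means - grand)^2)`, and
#' `SS_error = SS_total - SS_subject - SS_time`. The omnibus statistic is
#' `F = (SS_time / (k - 1)) / (SS_error / ((n - 1)(k - 1)))` referred to the
#' F distribution. No sphericity correction is applied.
#'
#' Post-hoc: each non-control label is compared against the pre-injection
#' control by a paired t test; p values are adjusted by the chosen
#' family-wise procedure (Holm by default).
#'
#' When the error sum of squares is numerically zero the omnibus p cannot
#' be computed from the F distribution: the result carries
#' `degenerate = TRUE` and `p_omnibus` is reported at the machine-epsilon
#' bound (or 1 when the time effect is also zero).
#'
#' @param table A [build_group_table()] result (complete, >= 2 animals,
#'   >= 2 labels).
#' @param p_adjust Multiplicity adjustment for the post-hoc family:
#'   `"holm"` (default), `"bonferroni"` or `"none"`.
#' @return An object of class `rm_anova_result`: `f_stat`, `df_time`,
#'   `df_error`, `p_omnibus`, `degenerate`, sums of squares (`ss`), and a
#'   `posthoc` data frame (label, mean_diff, t_stat, p_raw, p_adjusted,
#'   significant_0.05, significant_0.01).
#' @export
rm_anova <- function(table, p_adjust = c("holm", "bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(table, "group_time_series"))
  x <- table$values
  if (anyNA(x)) stop("repeated-measures table has missing cells",
                     call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need >= 2 animals and >= 2 labels", call. = FALSE)
  grand <- mean(x)
  ss_total <- sum((x - grand)^2)
  ss_subject <- k * sum((rowMeans(x) - grand)^2)
  ss_time <- n * sum((colMeans(x) - grand)^2)
  ss_error <- ss_total - ss_subject - ss_time
  df_time <- k - 1L
  df_error <- (n - 1L) * (k - 1L)
  tol <- max(ss_total, 1) * 1e-12
  degenerate <- ss_error <= tol
  if (degenerate) {
    if (ss_time <= tol) {
      f_stat <- 0; p_omnibus <- 1
    } else {
      f_stat <- Inf; p_omnibus <- .Machine$double.eps
    }
  } else {
    f_stat <- (ss_time / df_time) / (ss_error / df_error)
    p_omnibus <- stats::pf(f_stat, df_time, df_error, lower.tail = FALSE)
  }

  pre_col <- which(table$labels == 0)
  posthoc <- NULL
  if (length(pre_col) == 1) {
    others <- setdiff(seq_len(k), pre_col)
    ph <- lapply(others, function(j) {
      d <- x[, j] - x[, pre_col]
      sdd <- stats::sd(d)
      if (sdd == 0) {
        tt <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
        pr <- if (mean(d) == 0) 1 else .Machine$double.eps
      } else {
        tt <- mean(d) / (sdd / sqrt(n))
        pr <- 2 * stats::pt(-abs(tt), df = n - 1)
      }
      data.frame(label = table$labels[j], mean_diff = mean(d), t_stat = tt,
                 p_raw = pr)
    })
    posthoc <- do.call(rbind, ph)
    posthoc$p_adjusted <- stats::p.adjust(posthoc$p_raw, method = p_adjust)
    posthoc$significant_0.05 <- posthoc$p_adjusted < 0.05
    posthoc$significant_0.01 <- posthoc$p_adjusted < 0.01
  }
  structure(
    list(f_stat = f_stat, df_time = df_time, df_error = df_error,
         p_omnibus = p_omnibus, degenerate = degenerate,
         ss = c(total = ss_total, subject = ss_subject, time = ss_time,
                error = ss_error),
         posthoc = posthoc, p_adjust = p_adjust, table = table),
    class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("<rm_anova_result> F(%d, %d) = %.3f, p = %.4g%s\n",
              x$df_time, x$df_error, x$f_stat, x$p_omnibus,
              if (x$degenerate) " (degenerate error variance)" else ""))
  if (!is.null(x$posthoc)) {
    sig <- x$posthoc[x$posthoc$significant_0.05, "label"]
    cat(sprintf("  post-hoc vs pre (%s): %d/%d labels significant at 0.05%s\n",
                x$p_adjust, length(sig), nrow(x$posthoc),
                if (length(sig)) paste0(" (", paste(sig, collapse = ", "),
                                        " min)") else ""))
  }
  invisible(x)
}

#' Annotated per-label summary with significance stars
#'
#' Mean, SD and SEM per label, annotated with `*` (adjusted p < 0.05) and
#' `**` (adjusted p < 0.01) for the post-hoc comparisons against the
#' pre-injection control -- the table behind the group bar plots.
#'
#' @param result An [rm_anova()] result.
#' @return Data frame with columns `label`, `mean`, `sd`, `sem`,
#'   `p_adjusted`, `stars`.
#' @export
significance_report <- function(result) {
  stopifnot(inherits(result, "rm_anova_result"))
  x <- result$table$values
  labs <- result$table$labels
  out <- data.frame(
    label = labs,
    mean = colMeans(x),
    sd = apply(x, 2, stats::sd),
    sem = apply(x, 2, stats::sd) / sqrt(nrow(x)),
    p_adjusted = NA_real_,
    stars = "",
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(result$posthoc)) {
    m <- match(out$label, result$posthoc$label)
    out$p_adjusted <- result$posthoc$p_adjusted[m]
    out$stars <- ifelse(!is.na(m) & result$posthoc$significant_0.01[m], "**",
                        ifelse(!is.na(m) & result$posthoc$significant_0.05[m],
                               "*", ""))
  }
  out
}
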