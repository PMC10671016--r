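#!/usr/bin/env Rscript
# Group-level statistics: per condition, assemble the animals x 15-min
# time-points table (including the pre-injection control), run the one-way
# repeated-measures ANOVA with Holm-adjusted paired post-hoc comparisons
# against the control, and write the group table, the annotated summary
# and a mean +/- SD bar figure under results/groups/<drug>/.

suppressPackageStartupMessages(library(cmosdff))

session_dirs <- list.dirs(file.path("results", "sessions"),
                          recursive = FALSE)
stopifnot(length(session_dirs) > 0)

traces_by_drug <- list()
for (sdir in session_dirs) {
  rec <- read_session(file.path(sdir, "stack.tif"))
  meta <- attr(rec, "metadata")
  dff <- compute_dff(rec, compute_f0(rec, meta$baseline_window))
  tr <- average_intervals(dff, 15, mode = "trace")
  traces_by_drug[[meta$drug_label]][[meta$animal_id]] <- tr
}

for (drug in names(traces_by_drug)) {
  table <- build_group_table(traces_by_drug[[drug]])
  fit <- rm_anova(table, p_adjust = "holm")
  report <- significance_report(fit)
  gdir <- file.path("results", "groups", drug)
  df <- as.data.frame(table$values)
  write_results(
    gdir,
    tables = list(group_table = cbind(animal_id = table$animals, df),
                  significance = report),
    results = list(anova = list(
      f_stat = fit$f_stat, df_time = fit$df_time, df_error = fit$df_error,
      p_omnibus = fit$p_omnibus, posthoc = fit$posthoc)),
    figures = list(group_bars = function(p)
      render_group_bars(report, p, main = drug)))
  starred <- report$label[report$stars != ""]
  message(sprintf("%-13s F(%d,%d) = %8.2f, p = %10.3g; starred labels: %s",
                  drug, fit$df_time, fit$df_error, fit$f_stat,
                  fit$p_omnibus,
                  if (length(starred)) paste(starred, collapse = ", ")
                  else "none"))
}
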