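#!/usr/bin/env Rscript
# Evaluation in three parts:
#  (1) summary of the synthetic cohort's remaining-time matrix and its
#      indicator comparison (blocked ANOVA + Bonferroni pairwise tests);
#  (2) the same statistics recomputed on the published six-cow table;
#  (3) a seeded 100-replicate turning-point recovery study quantifying the
#      detectors' systematic early bias against the generator's truth.

source("analysis/00_cohort.R")

specs <- cohort_specs()

## (1) synthetic cohort ------------------------------------------------------
signals <- utils::read.csv(file.path(paths$results, "cohort_signals.csv"))
retro <- signals[signals$mode == "retrospective", ]
m_syn <- remaining_matrix(data.frame(subject_id = retro$subject_id,
                                     indicator = retro$indicator,
                                     hours = retro$remaining_h))
s_syn <- summarize_remaining(m_syn)
cat("Synthetic cohort remaining-time marginals (h):\n")
print(within(s_syn$rows, { mean <- round(mean, 1); sd <- round(sd, 1) }))
utils::write.csv(cbind(indicator = rownames(m_syn), as.data.frame(m_syn)),
                 file.path(paths$results, "cohort_remaining_matrix.csv"),
                 row.names = FALSE)

truth_offsets <- vapply(specs, function(sp) {
  if (sp$mode == "rise_decline") sp$turning_offset else NA_real_
}, numeric(1))
mad_rem <- m_syn["MAD", names(truth_offsets)]
cat("\nMAD remaining vs true turning offset (h):\n")
print(round(rbind(remaining = mad_rem, truth = truth_offsets,
                  early_by = mad_rem - truth_offsets), 1))

## (2) published table -------------------------------------------------------
m_pub <- calving_study_hours()
s_pub <- summarize_remaining(m_pub)
cat("\nPublished-table marginals (h):\n")
print(within(s_pub$rows, { mean <- round(mean, 1); sd <- round(sd, 1) }))

omni <- omnibus_compare(m_pub)
cat(sprintf("\nBlocked omnibus (complete triples, %d cows): F = %.2f, p = %.3f\n",
            omni$n_subjects, omni$F, omni$p))
pw <- pairwise_all(m_pub, complete_triples = TRUE)
for (nm in names(pw$pairs)) {
  p <- pw$pairs[[nm]]
  cat(sprintf("  %s: F = %.2f, p = %.3g %s\n", nm, p$F, p$p,
              ifelse(p$p < pw$alpha_adjusted, "(significant at 0.05/3)", "")))
}
d6 <- pairwise_compare(m_pub, c("MAD", "MACD"))
cat(sprintf("  MAD leads MACD by %.2f +/- %.2f h (all %d cows)\n",
            d6$mean_diff, d6$sd_diff, d6$n))
comparison <- c(
  sprintf("omnibus_block_F=%.6f", omni$F),
  sprintf("omnibus_block_p=%.6f", omni$p),
  vapply(names(pw$pairs), function(nm) {
    sprintf("%s_F=%.6f", gsub("-", "_", nm), pw$pairs[[nm]]$F)
  }, character(1)),
  sprintf("mad_macd_diff_mean=%.6f", d6$mean_diff),
  sprintf("mad_macd_diff_sd=%.6f", d6$sd_diff))
writeLines(comparison, file.path(paths$results, "comparison_report.txt"))

## (3) recovery study ----------------------------------------------------------
st <- run_recovery_study(n_rep = 100, indicators = c("SMA", "MAD", "MACD"),
                         seed = 20240918 %% 100000L, tolerance = 2)
cat("\nTurning-point recovery, 100 default-spec replicates:\n")
rec_rows <- lapply(names(st$reports), function(nm) {
  r <- st$reports[[nm]]
  data.frame(indicator = nm, bias_h = round(r$bias, 2),
             rmse_h = round(r$rmse, 2), prop_within_2h = r$prop_within,
             not_found = r$n_not_found)
})
rec_df <- do.call(rbind, rec_rows)
print(rec_df)
utils::write.csv(rec_df, file.path(paths$results, "recovery_report.csv"),
                 row.names = FALSE)
cat("\nNote: the MAD/MACD peaks systematically precede the true trend corner\n")
cat("(symmetric trend smoothing lets the post-peak decline pull the smoothed\n")
cat("slope down before the corner), so their signed errors are negative; the\n")
cat("SMA-series peak, whose trailing lag offsets that effect, is nearly\n")
cat("unbiased. See the methods vignette.\n")
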