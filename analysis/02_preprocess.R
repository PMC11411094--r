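#!/usr/bin/env Rscript
# Clean and bin each cow's beat series: running 30% outlier exclusion,
# 30-min averaging, linear gap imputation. Reports how many beats the
# artifact rule removed versus how many artifacts were injected.

source("analysis/00_cohort.R")

specs <- cohort_specs()
for (id in names(specs)) {
  dir <- file.path(paths$scratch, id)
  beats <- read_beat_csv(file.path(dir, "beats.csv"))
  filt <- filter_outliers(beats)
  binned <- bin_series(filt$beats,
                       n_bins = as.integer(specs[[id]]$duration / 0.5),
                       calving_time = specs[[id]]$calving_time)
  n_missing <- sum(is.na(binned$rr_ms))
  binned <- impute_gaps(binned)
  write_binned_csv(binned, file.path(dir, "binned.csv"))
  cat(sprintf("  %s: removed %d/%d beats (%.2f%%); %d bins, %d imputed\n",
              id, length(filt$removed), nrow(beats),
              100 * length(filt$removed) / nrow(beats),
              nrow(binned), n_missing))
}
cat("Binned series written.\n")
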