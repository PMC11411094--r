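#!/usr/bin/env Rscript
# Compute the technical-indicator panel (SMA 12, MAD 12, MACD 12/26,
# RSI 14; percent modes) on each cow's extracted trend.

source("analysis/00_cohort.R")

specs <- cohort_specs()
for (id in names(specs)) {
  dir <- file.path(paths$scratch, id)
  comp <- read_components_csv(file.path(dir, "components.csv"))
  panel <- indicator_panel(comp$trend_ms)
  # carry the true bin grid
  for (nm in names(panel)) panel[[nm]]$time <- comp$bin_start_h
  write_indicator_csv(panel, file.path(dir, "indicators.csv"))
  cat(sprintf(
    "  %s: MAD peak %.2f%%, MACD peak %.2f%%, RSI range [%.0f, %.0f]\n",
    id, max(panel$MAD$value, na.rm = TRUE),
    max(panel$MACD$value, na.rm = TRUE),
    min(panel$RSI$value, na.rm = TRUE), max(panel$RSI$value, na.rm = TRUE)))
}
cat("Indicator panels written.\n")
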