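#!/usr/bin/env Rscript
# Insurance coverage and the legacy estimator: compute coverage by band
# from the beneficiary and population panels, scale the public-sector
# counts by it (the pre-claims-data way of estimating private
# hospitalizations), and compare with the reported private caseload.

suppressMessages({
  library(aicm)
  library(dplyr)
})

cfg <- read_run_config("results/run_2015.yaml")
population <- suppressMessages(
  read_table_file(cfg$paths$population, "panel", kind = "population"))
beneficiaries <- suppressMessages(
  read_table_file(cfg$paths$beneficiaries, "panel", kind = "beneficiaries"))
cov <- compute_coverage(beneficiaries, population)
readr::write_csv(cov$by_band, "results/coverage_by_band.csv")

sus_counts <- suppressMessages(
  read_table_file("results/sus_selection.csv", "counts"))
reported <- suppressMessages(
  read_table_file("results/ans_selection_total.csv", "counts"))

legacy <- legacy_private_estimate(aggregate_regions(sus_counts, "BR"), cov)
write_counts_table(legacy, "results/legacy_private_estimate.csv")
over <- estimated_reported_ratio(legacy, reported)
readr::write_csv(over$by_band, "results/legacy_vs_reported_ratio.csv")

cat(sprintf("overall insurance coverage: %.2f%%\n", 100 * cov$overall))
cat(sprintf("coverage-based estimate of private hospitalizations: %s\n",
            format(counts_total(legacy), big.mark = ",")))
cat(sprintf(
  "the legacy estimator over-reports the claims caseload %.2f-fold,\n%s\n",
  over$total,
  "so the reported (diagnosis and/or procedure) counts are used instead"))
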