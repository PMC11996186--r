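#!/usr/bin/env Rscript
# Case selection: identify abortion hospitalizations (ICD-10 O03-O08 in
# any diagnosis field) in the public-sector admissions, and abortion care
# events in the private claims by diagnosis and/or procedure after
# event-level linkage. Writes the selection tables and the
# diagnosis-vs-procedure comparison.

suppressMessages({
  library(aicm)
  library(dplyr)
  library(tidyr)
})

cfg <- read_run_config("results/run_2015.yaml")
rule <- selection_rule()

sus <- suppressMessages(read_table_file(cfg$paths$sus, "sus_admissions"))
sus_counts <- select_sus(sus, rule, cfg$year, cfg$age_range)
write_counts_table(sus_counts, "results/sus_selection.csv")

cons <- suppressMessages(read_table_file(cfg$paths$ans_cons, "ans_cons"))
det <- suppressMessages(read_table_file(cfg$paths$ans_det, "ans_det"))
events <- link_ans(cons, det, rule)
icd_only <- select_ans(events, selection_rule(mode = "icd_only"))
both <- select_ans(events, selection_rule(mode = "icd_or_procedure"))
write_counts_table(icd_only, "results/ans_selection_icd_only.csv")
write_counts_table(both, "results/ans_selection_total.csv")

ratio <- icd_procedure_ratio(both, icd_only)
readr::write_csv(ratio$by_band, "results/ans_icd_procedure_ratio.csv")

cat(sprintf("public-sector abortion hospitalizations (10-49): %s\n",
            format(counts_total(sus_counts), big.mark = ",")))
cat(sprintf("private events, diagnosis only: %s; diagnosis and/or procedure: %s\n",
            format(counts_total(icd_only), big.mark = ","),
            format(counts_total(both), big.mark = ",")))
cat(sprintf(
  "adding procedures multiplies the reported private caseload by %.1f\n",
  ratio$total))
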