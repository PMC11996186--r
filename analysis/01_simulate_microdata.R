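#!/usr/bin/env Rscript
# Step 0 of the reproduction: emit a synthetic record-level 2015 dataset
# whose aggregates equal the packaged national margins (public-sector
# admissions by state and decade band; private-insurance events by band;
# population, beneficiary and live-birth panels), plus the run
# configuration consumed by the later steps.

suppressMessages(library(aicm))

out_dir <- "results"
dir.create(file.path(out_dir, "microdata"), showWarnings = FALSE,
           recursive = TRUE)

spec <- margin_spec()
paths <- write_synthetic_dataset(spec, file.path(out_dir, "microdata"),
                                 seed = 20150101)

yaml::write_yaml(list(
  paths = list(sus = "microdata/sus_admissions.csv",
               ans_cons = "microdata/ans_cons.csv",
               ans_det = "microdata/ans_det.csv",
               population = "microdata/population.csv",
               beneficiaries = "microdata/beneficiaries.csv",
               births = "microdata/births.csv"),
  year = 2015, age_range = c(10, 49), rounding = "half_up",
  share_18_19 = 0.75,
  band_coverage = list(`10-19` = 0.18, `20-29` = 0.26, `30-39` = 0.32,
                       `40-49` = 0.27),
  factors = list(sus = c(4, 3, 5), supp = c(5, 4, 6)),
  run_scenarios = TRUE
), file.path(out_dir, "run_2015.yaml"))

sus <- suppressMessages(read_table_file(paths$sus, "sus_admissions"))
cons <- suppressMessages(read_table_file(paths$ans_cons, "ans_cons"))
cat(sprintf(
  "wrote %d public admission records and %d private care events to %s\n",
  nrow(sus), nrow(cons), file.path(out_dir, "microdata")))
cat("run configuration:", file.path(out_dir, "run_2015.yaml"), "\n")
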