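#!/usr/bin/env Rscript
# Stage 2: read, validate and filter the study table.
#
# Applies the pre-analysis rules: drop records of flagged outlier
# genotypes, drop negative growth increments (herbivory / measurement
# error), keep the two analysis years, code dead trees as growth 0,
# scale covariates without centering and log1p-transform growth.

suppressMessages(library(hybridnorm))

tables <- read_phenotype_table("results/data/synthetic_mini_gardens.csv",
                               dialect = "mini")
dataset <- filter_records(tables, years = c(2021, 2022))
print(dataset)

write_analysis_table(dataset, "results/prepared.csv",
                     "results/filter_report.json")
message("wrote results/prepared.csv and results/filter_report.json")
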