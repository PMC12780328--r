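#!/usr/bin/env Rscript
# Stage 5: genotype-specific reaction norms and provenance-level change.
#
# Predicts growth, mortality probability and combined fitness for every
# genotype over 100 equally spaced MCMT values from -23.9 to 9.8 C
# (population level, no random modes), derives climate-transfer-distance
# curves, and evaluates each genotype at its provenance under historic
# and warmed winter temperatures.

suppressMessages(library(hybridnorm))

tables <- read_phenotype_table("results/data/synthetic_mini_gardens.csv")
dataset <- filter_records(tables, years = c(2021, 2022))
fit <- fit_zigmm(make_model("full"), dataset,
                 control = list(rel_tol = 1e-7))
genotypes <- tables$genotypes[!tables$genotypes$outlier, ]

norms <- reaction_norms(fit, genotypes, mcmt_grid(-23.9, 9.8, 100))
write.csv(norms, "results/reaction_norms.csv", row.names = FALSE)

# transfer-distance representation
td <- do.call(rbind, lapply(split(norms, norms$genotype), function(d) {
  home <- genotypes$home_MCMT[genotypes$genotype == d$genotype[1]]
  transfer_distance_curve(d, home)
}))
write.csv(td, "results/transfer_distance_curves.csv", row.names = FALSE)

opt <- unique(norms[c("genotype", "optimum_mcmt", "ancestry")])
opt$home_MCMT <- genotypes$home_MCMT[match(opt$genotype,
                                           genotypes$genotype)]
opt$transfer_at_optimum <- opt$optimum_mcmt - opt$home_MCMT
write.csv(opt, "results/fitness_optima.csv", row.names = FALSE)
message(sprintf(
  "%d/%d genotypes have their fitness optimum warmer than home",
  sum(opt$transfer_at_optimum > 0), nrow(opt)))

# provenance-level change under a uniform +3 C winter warming
change <- provenance_future_change(fit, genotypes,
                                   genotypes$home_MCMT + 3)
write.csv(change, "results/provenance_future_change.csv",
          row.names = FALSE)
message(sprintf("mean fitness change at provenance under +3 C: %+.2f cm",
                mean(change$delta_fitness)))

# quick visual check of the norms (scratch output, not a deliverable)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("scratch/figures", showWarnings = FALSE, recursive = TRUE)
  library(ggplot2)
  p <- ggplot(norms, aes(mcmt, fitness, group = genotype,
                         colour = ancestry)) +
    geom_line(alpha = 0.7) +
    scale_colour_gradient(low = "darkgreen", high = "steelblue",
                          name = "P. balsamifera\nancestry") +
    labs(x = "Garden MCMT (deg C)",
         y = "Combined fitness proxy (cm)",
         title = "Predicted reaction norms across the ancestry gradient")
  ggsave("scratch/figures/reaction_norms.pdf", p, width = 7, height = 4.5)
}
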