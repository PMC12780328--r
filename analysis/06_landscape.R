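#!/usr/bin/env Rscript
# Stage 6: landscape projection of the favored ancestry.
#
# Over a synthetic climate grid (historic winter temperatures plus a
# warmed future scenario), finds the genotype with the highest predicted
# combined fitness per cell, maps its species-ancestry proportion under
# both climates, and maps the historic-to-future ancestry shift. Cells
# with winter temperatures outside the garden-supported window are
# masked.

suppressMessages(library(hybridnorm))

tables <- read_phenotype_table("results/data/synthetic_mini_gardens.csv")
dataset <- filter_records(tables, years = c(2021, 2022))
fit <- fit_zigmm(make_model("full"), dataset,
                 control = list(rel_tol = 1e-7))
genotypes <- tables$genotypes[!tables$genotypes$outlier, ]

grid <- gen_climate_grid(n_cells = 1000, mcmt_range = c(-30, 12),
                         warming = 3, seed = 20260901)
write.csv(grid, "results/climate_grid.csv", row.names = FALSE)

hist_map <- best_genotype_per_cell(fit, genotypes, grid, "historic")
fut_map <- best_genotype_per_cell(fit, genotypes, grid, "future")
shift <- ancestry_shift(hist_map, fut_map)
write.csv(hist_map, "results/projection_historic.csv", row.names = FALSE)
write.csv(fut_map, "results/projection_future.csv", row.names = FALSE)
write.csv(shift, "results/ancestry_shift.csv", row.names = FALSE)

ok <- !shift$masked
message(sprintf("unmasked cells: %d / %d", sum(ok), nrow(shift)))
message(sprintf(
  "cells where warming favors lower balsamifera ancestry: %.1f%%",
  100 * mean(shift$shift[ok] < 0)))
message(sprintf("mean ancestry shift (future - historic): %+.3f",
                mean(shift$shift[ok])))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("scratch/figures", showWarnings = FALSE, recursive = TRUE)
  library(ggplot2)
  p <- ggplot(shift[ok, ], aes(lon, lat, colour = shift)) +
    geom_point(size = 0.8) +
    scale_colour_gradient2(low = "darkgreen", mid = "grey85",
                           high = "steelblue", name = "ancestry shift") +
    labs(title = "Historic-to-future shift in best-performing ancestry")
  ggsave("scratch/figures/ancestry_shift.pdf", p, width = 7, height = 5)
}
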