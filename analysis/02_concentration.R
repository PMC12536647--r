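#!/usr/bin/env Rscript
# Stage (ii): electric-field coverage of the gel for the six studied
# nanoparticle concentrations (dipole arrays at the printed inter-particle
# spacings), plus the uniform-vs-random comparison at the 2% row.
#
# Writes one coverage row per spacing and a combined table shaped like the
# published one, with the recomputed coverage and volume-fraction columns.

library(magnetopiezo)

out <- "results/stage2_concentration"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spacings <- coverage_reference_table()$spacing_um * 1e-6
rows <- list()
for (sp in spacings) {
  cs <- run_concentration_stage(sp, out_dir = out)
  print(cs)
  rows[[length(rows) + 1L]] <- magnetopiezo:::coverage_row(cs)
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "coverage_table.csv"), row.names = FALSE)

# spatial-arrangement sensitivity at the 2% row (0.80 um spacing)
cu <- run_concentration_stage(0.80e-6)
cr <- run_concentration_stage(0.80e-6, placement = "random", seed = 2)
side <- rbind(magnetopiezo:::coverage_row(cu), magnetopiezo:::coverage_row(cr))
write.csv(side, file.path(out, "uniform_vs_random_0.80um.csv"),
          row.names = FALSE)

cat("\nMax |E| is pinned to the particle surfaces (",
    format(cu$E_max, digits = 3), " V/m at 0.80 um spacing) and varies\n",
    "little with concentration; the exceedance fractions grow with\n",
    "concentration at every threshold. Random placement shifts the\n",
    "fractions by at most ",
    format(100 * max(abs(cr$area_fraction_above - cu$area_fraction_above)),
           digits = 2), " percentage points.\n", sep = "")
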