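#!/usr/bin/env Rscript
# Taper-angle optimization: simulate the candidate cones (5/7/9/11
# degrees, end diameters 2-7 cm) and their equivalent-volume cylinders
# on the wide-FOV scanner, and compare scatter fraction, true rate and
# NECR. 2e6 pairs per configuration (the design study scale here).

suppressPackageStartupMessages({
  library(conephantom)
  library(data.table)
})
dir.create("results", showWarnings = FALSE)

n_pairs <- 2e6
seed <- 2024

cat(sprintf("Simulating 4 cones + 4 EVC cylinders at %g pairs each...\n",
            n_pairs))
sw <- taper_sweep(n_pairs = n_pairs, seed = seed, include_evc = TRUE)
tb <- sw$table[order(variant, angle)]
fwrite(tb, "results/taper_sweep.csv")

cone <- tb[variant == "cone"]
cat("\nCone phantoms:\n")
print(cone[, .(angle, SF_pct = round(100 * SF, 2),
               SF_truth_pct = round(100 * SF_truth, 2),
               R_true = round(R_true), NECR = round(NECR_system))])
cat("\nSF decreases and NECR increases as the taper angle grows:",
    "\na steeper cone packs a wider diameter range into the FOV, and the",
    "\nshorter phantom leaves less out-of-FOV material and activity.\n")

# per-slice SF profiles: how close each cone tracks its EVC
prof <- rbindlist(lapply(names(sw$profiles), function(nm) {
  ps <- sw$profiles[[nm]]
  data.table(run = nm, slice = ps$slice, SF = ps$SF, C_tot = ps$C_tot)
}))
fwrite(prof, "results/taper_profiles.csv")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)
  p <- ggplot(prof[C_tot >= 500],
              aes(slice, SF, colour = run)) +
    geom_line() +
    labs(x = "SSRB slice", y = "scatter fraction",
         title = "Per-slice SF: cones vs equivalent-volume cylinders") +
    theme_minimal()
  ggsave("results/figures/taper_profiles.png", p, width = 9, height = 5,
         dpi = 120)
}
cat("\nWrote results/taper_sweep.csv and results/taper_profiles.csv\n")
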