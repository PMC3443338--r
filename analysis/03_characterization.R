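#!/usr/bin/env Rscript
# Count-rate characterization of the fabricated cone phantom on both
# scanner presets: scatter fraction and NECR across source radial
# offsets (0/10/15/20 mm), lower energy thresholds (250/350/425 keV)
# and the three animal-size FOV segments, with the matching EVC
# cylinders. One transport per cell, re-windowed per threshold.

suppressPackageStartupMessages({
  library(conephantom)
  library(data.table)
})
dir.create("results", showWarnings = FALSE)

n_pairs <- 2e6
seed <- 77

all_rows <- list()
for (sc in list(scanner_xpet(), scanner_labpet8())) {
  cat(sprintf("== %s: sweeping offsets x thresholds x segments ==\n",
              sc$name))
  sw <- characterization_sweep(sc, n_pairs = n_pairs, seed = seed,
                               include_evc = TRUE)
  tb <- copy(sw$table)[, scanner := sc$name]
  all_rows[[sc$name]] <- tb
  if (!is.null(sw$skipped)) {
    cat("skipped cells:\n"); print(sw$skipped)
  }
}
tab <- rbindlist(all_rows)
fwrite(tab, "results/characterization.csv")

cone <- tab[variant == "cone"]
cat("\nScatter fraction (%), cone phantom:\n")
sf_wide <- dcast(cone, scanner + segment + offset ~ let_kev,
                 value.var = "SF")
let_cols <- setdiff(names(sf_wide), c("scanner", "segment", "offset"))
sf_wide[, (let_cols) := lapply(.SD, function(x) round(100 * x, 1)),
        .SDcols = let_cols]
print(sf_wide)
cat("\nThe SF increases as the radial offset decreases, the threshold",
    "\ndecreases and the object size grows; NECR moves the other way.\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)
  p <- ggplot(cone, aes(offset, 100 * SF, colour = factor(let_kev))) +
    geom_line() + geom_point() +
    facet_grid(scanner ~ segment) +
    labs(x = "source radial offset (mm)", y = "scatter fraction (%)",
         colour = "LET (keV)") +
    theme_minimal()
  ggsave("results/figures/sf_vs_offset.png", p, width = 10, height = 6,
         dpi = 120)
  p2 <- ggplot(cone, aes(offset, NECR_system, colour = factor(let_kev))) +
    geom_line() + geom_point() +
    facet_grid(scanner ~ segment, scales = "free_y") +
    labs(x = "source radial offset (mm)", y = "NECR (counts/s)",
         colour = "LET (keV)") +
    theme_minimal()
  ggsave("results/figures/necr_vs_offset.png", p2, width = 10, height = 6,
         dpi = 120)
}
cat("\nWrote results/characterization.csv\n")
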