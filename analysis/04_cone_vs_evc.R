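#!/usr/bin/env Rscript
# How well does the cone phantom stand in for discrete uniform
# cylinders? Squared Pearson correlation of SF and NECR across source
# offsets between the cone segments and their EVC counterparts, from
# the characterization sweep written by 03_characterization.R.

suppressPackageStartupMessages({
  library(conephantom)
  library(data.table)
})

tab <- fread("results/characterization.csv")

r2 <- rbindlist(lapply(split(tab, tab$scanner), function(tb) {
  sw <- structure(list(table = tb), class = "sweep_result")
  sf <- cone_vs_evc_correlation(sw, "SF")[, metric := "SF"]
  nec <- cone_vs_evc_correlation(sw, "NECR_system")[, metric := "NECR"]
  rbind(sf, nec)[, scanner := tb$scanner[1]]
}))
fwrite(r2, "results/cone_vs_evc_r2.csv")
cat("Cone-vs-EVC correlation across offsets (R^2):\n")
print(dcast(r2, scanner + segment + let_kev ~ metric,
            value.var = "r_squared")[, lapply(.SD, function(x)
              if (is.numeric(x)) round(x, 3) else x)])

# relative difference (percent of the mean) between cone and EVC SF
wide <- dcast(tab, scanner + segment + offset + let_kev ~ variant,
              value.var = "SF")
wide <- wide[!is.na(cone) & !is.na(evc)]
wide[, rel_diff_pct := round(relative_difference(cone, evc), 2)]
fwrite(wide, "results/cone_vs_evc_sf.csv")
cat("\nMedian SF relative difference cone vs EVC:",
    sprintf("%.1f%%\n", median(wide$rel_diff_pct)))
cat("Wrote results/cone_vs_evc_r2.csv and results/cone_vs_evc_sf.csv\n")
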