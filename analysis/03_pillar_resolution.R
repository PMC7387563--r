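#!/usr/bin/env Rscript
# Resolution comparison on the 3D-printed pillar phantom: three 1 mm polymer
# pillars separated by 1 mm ink-filled channels.  A 1 mm focal beam is
# stepped across the pillars in 125 um steps and the FWHM of each induced
# heat spot is plotted against beam position; the same phantom is then
# illuminated with a 1 cm widefield flat-top source and the per-pixel decay
# constant is fitted.  Both readouts pass through the identical
# resolved-peak criterion (prominence >= 20% of dynamic range, separation
# >= half the 2 mm pitch).

library(fdti)

dir.create("results", showWarnings = FALSE)

cat("Running pillar-phantom scan + widefield comparison ...\n")
t0 <- Sys.time()
res <- run_pillar_experiment(seed = 1)
cat(sprintf("done in %.1f min\n", as.numeric(Sys.time() - t0, units = "mins")))

write.csv(as.data.frame(res$scan), "results/pillar_scan_profile.csv",
          row.names = FALSE)
write.csv(res$transect, "results/pillar_widefield_transect.csv",
          row.names = FALSE)
counts <- data.frame(method = c("fdti_scan", "widefield_dti"),
                     resolved_peaks = c(as.integer(res$fdti_peaks),
                                        as.integer(res$widefield_peaks)))
write.csv(counts, "results/pillar_peak_counts.csv", row.names = FALSE)

cat(sprintf("\nPillar centres at %s mm, pitch %.1f mm\n",
            paste(round(res$geometry$pillar_centers * 1e3, 2), collapse = ", "),
            res$geometry$period * 1e3))
cat(sprintf("FDTI scan: %d resolved peaks at %s mm\n",
            as.integer(res$fdti_peaks),
            paste(round(attr(res$fdti_peaks, "peaks"), 2), collapse = ", ")))
cat(sprintf("Widefield decay transect: %d resolved peaks\n",
            as.integer(res$widefield_peaks)))
cat(sprintf("FDTI resolves the structure; widefield does not: %s\n",
            as.integer(res$fdti_peaks) == 3 &&
              as.integer(res$widefield_peaks) < 3))
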