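#!/usr/bin/env Rscript
# Simulated porcine fat vs muscle comparison: the two ex vivo tissue types
# differ strongly in optical absorption at 405 nm (fat 150 1/m vs muscle
# 950 1/m) and in thermal conductivity (0.24 vs 0.56 W/(m K)), so the same
# 5 mW / 10 s FDTI measurement should separate them by amplitude and FWHM.

library(fdti)

dir.create("results", showWarnings = FALSE)

cat("Simulating FDTI on porcine fat and muscle blocks ...\n")
t0 <- Sys.time()
porc <- run_porcine()
cat(sprintf("done in %.1f min\n", as.numeric(Sys.time() - t0, units = "mins")))

write.csv(porc, "results/porcine_features.csv", row.names = FALSE)

show <- c("tissue", "amplitude", "fwhm", "area", "volume", "tau_rise",
          "tau_decay")
print(porc[, show], digits = 4)

fat <- porc[porc$tissue == "fat", ]
mus <- porc[porc$tissue == "muscle", ]
cat(sprintf("\nMuscle/fat amplitude ratio: %.2f (muscle absorbs ~6x more)\n",
            mus$amplitude / fat$amplitude))
cat(sprintf("Fat/muscle FWHM ratio: %.2f\n", fat$fwhm / mus$fwhm))
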