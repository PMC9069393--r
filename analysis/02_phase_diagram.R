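#!/usr/bin/env Rscript
# Stratification phase diagram over interfacial shear stress f, adhesion
# energy Gamma and fluidity timescale tau: the 2D/3D morphogenesis
# boundary moves with the interfacial mechanics, and lowering tau
# (fluidising the tissue) suppresses stratification entirely.

library(morphomech)
dir.create("results", showWarnings = FALSE)

base <- sim_params(n_elements = 100, growth_rate = 0.05, E_eff = 1000,
                   h = 10, f = 1, Gamma = 2e-6, tau = Inf,
                   t_end = log(2.2) / 0.05, R0 = 100)
grid <- expand.grid(f = c(0, 0.5, 1, 2), Gamma = c(1e-6, 4e-6),
                    tau = c(Inf, 0.5, 0.1))
pd <- phase_diagram(grid, base)
write.csv(pd, "results/02_phase_diagram.csv", row.names = FALSE)

for (tv in unique(pd$tau)) {
  sub <- pd[pd$tau == tv, ]
  cat(sprintf("tau = %-4s: %d of %d parameter points stratify\n",
              format(tv), sum(sub$stratifies), nrow(sub)))
}
solid <- pd[is.infinite(pd$tau) & pd$f > 0 & pd$stratifies, ]
cat("In the solid limit the onset radius falls with f and rises with Gamma:\n")
print(solid[order(solid$Gamma, solid$f), c("f", "Gamma", "onset_R")],
      row.names = FALSE)
cat("wrote results/02_phase_diagram.csv\n")
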