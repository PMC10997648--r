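#!/usr/bin/env Rscript
# Stage 1 — generate the default synthetic landscape.
#
# A 270 x 180 grid of 30 m cells (8.1 x 5.4 km), 2000-2020 annual binary
# forest cover, 24 community-managed (CFM) units placed preferentially in
# accessible cells and 12 larger state-protected (MNP) units in remoter
# cells, with spatially autocorrelated confounders and known yearly CFM
# effects in 2014-2017. Writes the scenario (cover, units, covariates,
# national series, config echo) under results/scenario/.

library(defoeval)

seed <- 20240405
cfg <- sim_config(seed = derive_seed(seed, "simulate"))
scen <- generate_landscape(cfg)
print(scen)

write_scenario(scen, "results/scenario")

truth <- true_effect_schedule(cfg)
message("configured yearly CFM effects (pp of cell area):")
print(100 * truth[truth != 0])
message("scenario written to results/scenario/")
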