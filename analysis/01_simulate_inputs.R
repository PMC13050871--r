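#!/usr/bin/env Rscript
# Generate the synthetic study inputs consumed by the downstream analysis
# steps: a two-channel confocal stack with ground truth, paired 2D-STED
# frames, a GCaMP time-lapse trace and an IHC voltage trace. Everything is
# written under results/simulated/ in open formats (TIFF / CSV / JSON).

suppressPackageStartupMessages(library(ribbonquant))
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = 7)
sim <- make_confocal_stack(cfg)
write_stack_tiff(sim$stacks$ribbon, "results/simulated/ribbon.tif")
write_stack_tiff(sim$stacks$psd, "results/simulated/psd.tif")
write_manifest(sim$manifest, "results/simulated/manifest.json")
cat(sprintf("confocal stack: %d ribbons, %d engaged (ground truth)\n",
            nrow(sim$manifest$pairs_true),
            sum(sim$manifest$pairs_true$engaged)))

# frames themselves are regenerated deterministically by 02; persist truth
sted <- make_sted_pair_frames(99, rho = 0.35, seed = 7)
write.csv(sted$manifest$pairs_true, "results/simulated/sted_true_areas.csv",
          row.names = FALSE)
cat(sprintf("STED frames: %d synapse crops at target rho = %.2f\n",
            length(sted$frames), sted$manifest$rho_true))

gc_tr <- make_gcamp_trace(600, peak_times = seq(25, 575, length.out = 12),
                          noise_sd = 10, seed = 7)
write_trace_csv(gc_tr, "results/simulated/gcamp_trace.csv")
vt <- make_voltage_trace(10, spike_times = seq(0.5, 9.5, by = 1),
                         noise_sd = 0.5, seed = 7)
write_trace_csv(vt, "results/simulated/voltage_trace.csv")
cat("traces written: gcamp (12 true peaks / 10 min), voltage (10 spikes / 10 s)\n")
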