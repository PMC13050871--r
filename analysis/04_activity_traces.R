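#!/usr/bin/env Rscript
# Activity-trace analysis: GCaMP dF - F0 peak frequency and voltage
# supra-threshold event detection (threshold -35 mV) with spike-integral
# (AUC) bookkeeping.

suppressPackageStartupMessages(library(ribbonquant))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

gc_tr <- read_trace_csv("results/simulated/gcamp_trace.csv",
                        kind = "fluorescence", duration_s = 600)
bc <- baseline_correct(gc_tr)
pk <- peak_frequency(bc)
cat(sprintf("GCaMP: F0 = %.1f (%s mode), %d peaks, %.2f min^-1\n",
            attr(bc, "f0"), attr(bc, "f0_mode"), pk$peak_count,
            pk$frequency_per_min))
write.csv(data.frame(peak_time_s = pk$peak_times_s),
          "results/analysis/gcamp_peaks.csv", row.names = FALSE)

vt <- read_trace_csv("results/simulated/voltage_trace.csv",
                     kind = "voltage", duration_s = 10)
ev <- detect_events(vt)
cat(sprintf("voltage: %d supra-threshold events (> %g mV), rate %.2f s^-1,\n",
            nrow(ev$events), ev$threshold_mV, ev$rate_hz))
cat(sprintf("         baseline %.1f mV, mean AUC %.3f mV s\n",
            ev$baseline_mV, mean(ev$events$auc_mVs)))
write.csv(ev$events, "results/analysis/voltage_events.csv",
          row.names = FALSE)
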