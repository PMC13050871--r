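#!/usr/bin/env Rscript
# Statistical comparisons on pipeline outputs: an emulated stimulation
# experiment (control vs stimulated cultures, the stimulated condition
# generated with brighter ribbon puncta) analyzed the way the study
# analyzes its figures -- Shapiro-Wilk, Mann-Whitney U on integrated
# intensities, and a two-way ANOVA (class x treatment) with Holm-Sidak
# post-hoc on per-IHC ribbon counts.

suppressPackageStartupMessages(library(ribbonquant))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)

measure_condition <- function(seeds, peak_meanlog) {
  out <- lapply(seeds, function(s) {
    cfg <- synth_config(seed = s, peak_meanlog = peak_meanlog)
    sim <- make_confocal_stack(cfg)
    p <- reconstruct(sim$stacks$ribbon, recon_profile("ribbon-wt"))
    asg <- classify_ribbons(attr(p, "labels"),
                            attr(reconstruct(sim$stacks$psd,
                                             recon_profile("psd-wt")),
                                 "labels"), cfg$voxel_size_um)
    summ <- summarize_engagement(asg, cfg$n_ihc)
    list(intensity = p$integrated_intensity,
         counts = data.frame(culture = s,
                             synaptic = summ$synaptic_per_ihc,
                             cytoplasmic = summ$cytoplasmic_per_ihc))
  })
  list(intensity = unlist(lapply(out, `[[`, "intensity")),
       counts = do.call(rbind, lapply(out, `[[`, "counts")))
}

ctl <- measure_condition(101:104, peak_meanlog = log(150))
stim <- measure_condition(201:204, peak_meanlog = log(195)) # +30% brightness

nrm <- normality(ctl$intensity)
cat(sprintf("Shapiro-Wilk on control intensities: W = %.3f, p = %.2g\n",
            nrm$statistic, nrm$p))

mw <- compare_two(stim$intensity, ctl$intensity)
cat(sprintf("Mann-Whitney on integrated intensity: U = %g, p = %.2g\n",
            mw$statistic, mw$p))
cat(sprintf("  control Mdn = %.0f (IQR %.0f), stimulated Mdn = %.0f (IQR %.0f)\n",
            mw$summary_b$median, mw$summary_b$iqr, mw$summary_a$median,
            mw$summary_a$iqr))

# per-culture per-IHC counts in a class x treatment layout
long <- function(cc, treatment)
  data.frame(count = c(cc$synaptic, cc$cytoplasmic),
             class = rep(c("synaptic", "cytoplasmic"), each = nrow(cc)),
             treatment = treatment)
counts <- rbind(long(ctl$counts, "control"), long(stim$counts, "stimulated"))
an <- compare_factorial(counts$count, factor(counts$class),
                        factor(counts$treatment),
                        correction = "holm-sidak")
cat("two-way ANOVA (type II) on per-IHC ribbon counts:\n")
print(an$omnibus, row.names = FALSE)
write.csv(an$posthoc, "results/analysis/counts_posthoc.csv",
          row.names = FALSE)
write.csv(data.frame(test = c("shapiro", "mann-whitney"),
                     statistic = c(nrm$statistic, mw$statistic),
                     p = c(nrm$p, mw$p)),
          "results/analysis/statistics_summary.csv", row.names = FALSE)
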