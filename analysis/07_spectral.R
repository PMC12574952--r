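#!/usr/bin/env Rscript
# Stage 7: oscillatory profiling.
#
# Band-pass filters single trials into delta/theta/alpha/beta, repeats
# the mutual partial correlations (SD difference controlling amplitude
# and vice versa), and locates band-limited component latencies.
# Requires stage 1.

suppressMessages(library(painvar))
out <- "results/analysis"
cohort <- read_epochs(file.path(out, "cohort"))
ratings <- read_ratings(file.path(out, "ratings.tsv"))
scores <- discrim_scores(ratings)

for (b in band_definition()$name) {
  bp <- band_profile(cohort, scores, b, compute_bf = FALSE)
  utils::write.table(as.data.frame(bp$sd_given_amp),
                     file.path(out, paste0("band_", b, "_sd_given_amp.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  roi <- roi_association(bp$dvar, scores, covariate_tracks = bp$damp,
                         compute_bf = FALSE)
  avg <- colMeans(do.call(rbind, lapply(cohort, function(e) {
    bd <- band_definition(b)
    colMeans(bandpass(e, bd$lo, bd$hi)$data)
  })))
  lat <- band_amplitude_latencies(list(times = cohort[[1]]$times,
                                       values = avg), b)
  cat(sprintf(
    "%s: SD|amp %d sig points, ROI partial r = %.3f (p = %.2g); amp|SD %d sig; extrema %g / %g ms\n",
    b, sum(bp$sd_given_amp$q_sig), roi$r, roi$p,
    sum(bp$amp_given_sd$q_sig), lat[["neg_peak_ms"]], lat[["pos_peak_ms"]]))
}
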