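#!/usr/bin/env Rscript
# Stage 2: windowed variability and amplitude tracks.
#
# Computes per-subject sliding-window (100 ms, 1 ms step) temporal-SD,
# permutation-entropy and amplitude tracks, their high-minus-low
# differences, and the peak region of interest of the subject-averaged
# SD difference. Requires stage 1.

suppressMessages(library(painvar))
out <- "results/analysis"
cohort <- read_epochs(file.path(out, "cohort"))

dvar <- cohort_diff_tracks(cohort, "tempSD")
damp <- cohort_diff_tracks(cohort, "amplitude")
dpe <- cohort_diff_tracks(cohort, "PE", step_ms = 5)

long <- function(tr, metric) data.frame(
  subject_id = rep(rownames(tr$delta), times = ncol(tr$delta)),
  metric = metric, condition = "diff",
  time_ms = rep(tr$times, each = nrow(tr$delta)),
  value = as.vector(tr$delta))
utils::write.table(rbind(long(dvar, "tempSD"), long(damp, "amplitude")),
                   file.path(out, "difference_tracks.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)

roi <- peak_roi(list(times = dvar$times, values = dvar$mean))
roi_pe <- peak_roi(list(times = dpe$times, values = dpe$mean), mode = "min")
cat(sprintf("Delta-SD peaks at %g ms (ROI %g..%g ms)\n",
            attr(roi, "peak_ms"), roi[1], roi[2]))
cat(sprintf("Delta-PE trough at %g ms\n", attr(roi_pe, "peak_ms")))
cat(sprintf("subject-mean Delta-SD at the peak: %.3f uV\n",
            max(dvar$mean[dvar$times >= 0])))
utils::write.table(
  data.frame(metric = c("tempSD", "PE"),
             extremum_ms = c(attr(roi, "peak_ms"), attr(roi_pe, "peak_ms")),
             roi_lo = c(roi[1], roi_pe[1]), roi_hi = c(roi[2], roi_pe[2])),
  file.path(out, "peak_rois.tsv"), sep = "\t", row.names = FALSE,
  quote = FALSE)
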