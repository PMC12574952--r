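#!/usr/bin/env Rscript
# Stage 4: dominance decomposition.
#
# Splits the per-time-point R^2 for predicting the rating difference into
# total-dominance shares of the SD difference and the amplitude
# difference. Requires stage 1.

suppressMessages(library(painvar))
out <- "results/analysis"
cohort <- read_epochs(file.path(out, "cohort"))
ratings <- read_ratings(file.path(out, "ratings.tsv"))

scores <- discrim_scores(ratings)
dvar <- cohort_diff_tracks(cohort, "tempSD")
damp <- cohort_diff_tracks(cohort, "amplitude")

dt <- dominance_track(scores, dvar, damp)
utils::write.table(as.data.frame(dt), file.path(out, "dominance_track.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
ggplot2::ggsave(file.path(out, "dominance_track.png"),
                plot_dominance_track(dt), width = 7, height = 4, dpi = 120)

early <- dt$times >= 100 & dt$times <= 300
late <- dt$times > 300 & dt$times <= 500
cat(sprintf("early window (100-300 ms): mean td_var = %.3f, td_amp = %.3f\n",
            mean(dt$td_var[early]), mean(dt$td_amp[early])))
cat(sprintf("late window (300-500 ms): mean td_var = %.3f, td_amp = %.3f\n",
            mean(dt$td_var[late]), mean(dt$td_amp[late])))
cat(sprintf("conservation |td_var + td_amp - R2| max: %.2e\n",
            max(abs(dt$td_var + dt$td_amp - dt$r2_full))))
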