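#!/usr/bin/env Rscript
# Structure-to-function prediction: fit the order-5 rotated matrix-polynomial
# map from each subject's structural matrix (masked to all / optimal-only /
# nonoptimal-only edges) to the rest and task functional matrices, score by
# upper-triangle correlation and the Betti-0 persistence score, and compare
# conditions with a repeated-measures ANOVA (Greenhouse-Geisser corrected).

suppressPackageStartupMessages(library(navopt))

cohort_dir <- "results/cohort"
subjects <- sort(unique(sub("_.*", "", grep("^sub", basename(
  Sys.glob(file.path(cohort_dir, "sub*_coords.tsv"))), value = TRUE))))

rows <- list()
for (s in subjects) {
  coords <- read_coords_tsv(file.path(cohort_dir, paste0(s, "_coords.tsv")))
  S <- read_matrix_tsv(file.path(cohort_dir, paste0(s, "_structural.tsv")))
  cls <- classify_edges(S, build_nng(dist_from_coords(coords)))
  for (state in c("rest", "task")) {
    F_real <- read_matrix_tsv(file.path(cohort_dir,
                                        paste0(s, "_fc_", state, ".tsv")))
    for (msk in c("all", "optimal", "nonoptimal")) {
      S_in <- mask_structural(S, cls, msk)
      F_hat <- predict_fc(fit_spectral_map(S_in, F_real, k = 5), S_in)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, state = state, mask = msk,
        r = score_correlation(F_hat, F_real),
        sse_beta = sse_beta(F_real, F_hat))
    }
  }
}
scores <- do.call(rbind, rows)
write.table(scores, "results/prediction_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

agg <- aggregate(cbind(r, sse_beta) ~ state + mask, scores, mean)
cat("mean prediction scores:\n"); print(agg, row.names = FALSE)

wide <- function(state0, metric)
  sapply(c("all", "optimal", "nonoptimal"), function(m)
    scores[scores$state == state0 & scores$mask == m, metric])

st <- compare_scores(wide("rest", "r"), "repeated_anova")
cat(sprintf("\nrest, correlation: F(%.1f, %.1f) = %.2f, GG eps = %.3f, p = %.2g\n",
            st$df[1], st$df[2], st$F, st$gg_epsilon, st$p_gg))
print(round(st$posthoc, 6))

# rest vs task for the nonoptimal mask: paired t
non <- cbind(task = scores[scores$state == "task" &
                             scores$mask == "nonoptimal", "r"],
             rest = scores[scores$state == "rest" &
                             scores$mask == "nonoptimal", "r"])
pt <- compare_scores(non, "paired_t")
cat(sprintf("nonoptimal mask, task vs rest: diff = %.4f, t = %.2f, p = %.2g\n",
            mean(non[, 1] - non[, 2]), pt$t, pt$p))
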