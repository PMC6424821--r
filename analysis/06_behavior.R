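#!/usr/bin/env Rscript
# Behavioral scoring: conditioned place preference (dwell-time score between
# the two enclosures, bridge excluded) for the pre-test and test sessions,
# occupancy maps, and region-resolved counts of simulated reward-seeking
# pokes.

source("analysis/00_common.R")

day <- make_day()
out <- results_dir("behavior")

rows <- lapply(c("pretest", "test"), function(nm) {
  ps <- preference_score(day[[nm]]$position, target = "A")
  om <- occupancy_map(day[[nm]]$position, spatial_bin_cm = 4)
  write.csv(data.frame(x = rep(om$xedges[-length(om$xedges)],
                               times = ncol(om$occupancy)),
                       y = rep(om$yedges[-length(om$yedges)],
                               each = nrow(om$occupancy)),
                       dwell_s = as.vector(om$occupancy)),
            file.path(out, paste0("occupancy_", nm, ".csv")),
            row.names = FALSE)
  data.frame(session = nm, score = ps$score, t_target = ps$t_target,
             t_other = ps$t_other, t_excluded = ps$t_excluded)
})
tbl <- do.call(rbind, rows)
write.csv(tbl, file.path(out, "preference_scores.csv"), row.names = FALSE)

# simulated pokes at the (no longer baited) dispensers, biased to the
# sucrose-paired side during test
pokes <- withr::with_seed(hpcnac:::substream_seed(DAY_SEED, "pokes"), {
  n <- 40
  side <- stats::runif(n) < 2 / 3
  data.frame(x = ifelse(side, 23, 77), y = 23)
})
cnt <- count_events_by_region(pokes)
write.csv(data.frame(region = names(cnt), pokes = unname(cnt)),
          file.path(out, "poke_counts.csv"), row.names = FALSE)

message(sprintf("CPP score: pre-test %.3f, test %.3f (dwell %g s vs %g s)",
                tbl$score[1], tbl$score[2], round(tbl$t_target[2]),
                round(tbl$t_other[2])))
message(sprintf("pokes by region: A %d, B %d", cnt[["A"]], cnt[["B"]]))
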