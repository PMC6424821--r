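#!/usr/bin/env Rscript
# Simulate the synthetic recording day and write its raw data products:
# spike trains, position traces, light epochs, and ground truth. All later
# stages regenerate the same day deterministically from the shared seed, so
# these files are the inspectable record, not a hidden state.

source("analysis/00_common.R")

day <- make_day()
out <- results_dir("sessions")

for (nm in c("pretest", "test", "other")) {
  s <- day[[nm]]
  write_spikes(s$spikes, file.path(out, paste0("spikes_", nm, ".csv")))
  write_position(s$position, file.path(out, paste0("position_", nm, ".csv")))
}
write_events(
  data.frame(label = "light_on",
             start = vapply(day$light, `[[`, 0, "start"),
             end = vapply(day$light, `[[`, 0, "end")),
  file.path(out, "light_epochs_test.csv"))
jsonlite::write_json(
  list(seed = DAY_SEED, duration = DURATION,
       assembly_members = day$members,
       true_classes = as.list(day$pretest$truth$true_classes)),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

n_spk <- sum(lengths(day$pretest$spikes))
message(sprintf(
  "wrote 3 sessions of %g s under %s; pre-test holds %d spikes from %d units",
  DURATION, out, n_spk, length(day$pretest$spikes)))
message("embedded assemblies: ",
        paste(vapply(day$members, function(m)
          paste(sort(m), collapse = "+"), ""), collapse = " | "))
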