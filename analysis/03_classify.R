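#!/usr/bin/env Rscript
# Classify the accumbens units (MSN / FSI / TAN) from mean-waveform shape:
# three features per unit (first-peak duration, second-peak duration, spike
# symmetry), k-means with physiology-based cluster naming, confirmed by
# DBSCAN and Ward hierarchical clustering, and checked against the
# generator's ground-truth classes.

source("analysis/00_common.R")

day <- make_day()
out <- results_dir("classification")

wf <- day$pretest$waveforms
feats <- t(apply(wf$waveforms, 1, function(w)
  unlist(waveform_features(w, t_ms = wf$t_ms))))
colnames(feats) <- c("first_peak_ms", "second_peak_ms", "symmetry")

nac_ids <- grep("^(msn|fsi|tan)", names(day$pretest$spikes), value = TRUE)
rates <- lengths(day$pretest$spikes[nac_ids]) / DURATION

cls <- classify_units(feats, rates,
                      seed = hpcnac:::substream_seed(DAY_SEED, "classify"))
truth <- toupper(wf$labels)
acc <- mean(as.character(cls$labels) == truth)

tbl <- data.frame(neuron_id = nac_ids,
                  label = as.character(cls$labels),
                  truth = truth,
                  rate_hz = round(unname(rates), 3),
                  silhouette = round(cls$silhouette, 3),
                  feats)
write.csv(tbl, file.path(out, "labels.csv"), row.names = FALSE)
write.csv(data.frame(pair = names(cls$agreement),
                     adjusted_rand = unname(cls$agreement)),
          file.path(out, "algorithm_agreement.csv"), row.names = FALSE)

message(sprintf("classified %d NAc units; ground-truth accuracy %.1f%%",
                length(nac_ids), 100 * acc))
message(sprintf("cross-algorithm adjusted Rand: %s",
                paste(sprintf("%s %.2f", names(cls$agreement),
                              cls$agreement), collapse = ", ")))
message(sprintf("FSI mean rate %.1f Hz vs MSN %.1f Hz (FSIs discharge fastest)",
                mean(rates[cls$labels == "FSI"]),
                mean(rates[cls$labels == "MSN"])))
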