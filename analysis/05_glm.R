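#!/usr/bin/env Rscript
# Ensemble-to-ensemble prediction: for each MSN, fit a linear model of its
# per-theta-cycle spike count on the simultaneous PYR population during the
# pre-test, then score the model (Pearson correlation between observed and
# predicted counts) on the test session (same wiring) and on the unrelated
# enclosure session (no wiring). Wiring-specific prediction shows up as
# higher accuracy on the matched session.

source("analysis/00_common.R")

day <- make_day()
out <- results_dir("glm")

cc <- lapply(day[c("pretest", "test", "other")], function(s)
  bin_by_cycles(s$spikes, s$cycles))
pyr_cols <- grep("^pyr", colnames(cc$pretest$counts), value = TRUE)
msn_cols <- grep("^msn", colnames(cc$pretest$counts), value = TRUE)

tbl <- do.call(rbind, lapply(msn_cols, function(msn) {
  m <- fit_ensemble_model(cc$pretest$counts[, msn],
                          cc$pretest$counts[, pyr_cols],
                          training_id = "pretest")
  acc <- function(sess) suppressMessages(predict_and_score(
    m, cc[[sess]]$counts[, pyr_cols], cc[[sess]]$counts[, msn]))$accuracy
  data.frame(target = msn, r2_train = m$r2_train,
             r_test = acc("test"), r_other = acc("other"))
}))
write.csv(tbl, file.path(out, "accuracy_by_msn.csv"), row.names = FALSE)

message(sprintf("%d theta cycles per session; %d PYR predictors",
                nrow(cc$pretest$counts), length(pyr_cols)))
message(sprintf("mean accuracy: test %.3f vs other %.3f (coupled msn1: %.3f vs %.3f)",
                mean(tbl$r_test), mean(tbl$r_other),
                tbl$r_test[tbl$target == "msn1"],
                tbl$r_other[tbl$target == "msn1"]))
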