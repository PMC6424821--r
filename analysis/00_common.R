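# Shared setup for the analysis drivers: one deterministic synthetic "day"
# (pre-test, CPP test with light epochs, unrelated other enclosure) used by
# every downstream stage. Sourced, not run.

suppressPackageStartupMessages(library(hpcnac))

DAY_SEED <- 20260921L
DURATION <- 240

make_day <- function(seed = DAY_SEED) {
  n_pyr <- 30
  pyr_ids <- paste0("pyr", seq_len(n_pyr))
  members <- withr::with_seed(hpcnac:::substream_seed(seed, "members"), {
    lapply(1:3, function(k) sample(pyr_ids, 5))
  })
  assemblies <- lapply(members, function(m)
    list(members = m, rate = 1, participation = 0.8))
  couplings <- data.frame(
    pre = c("pyr1", "pyr2", "pyr3", "pyr4", "pyr5"),
    post = c("fsi1", "fsi2", "msn1", "msn1", "msn1"),
    latency_ms = c(4, 5, 6.5, 6.5, 6.5),
    efficacy = c(0.2, 0.2, 0.25, 0.25, 0.25))
  ffi <- data.frame(fsi = "fsi1", msn = "msn1", strength = 0.5, tau_ms = 10)
  light <- list(
    list(start = DURATION / 4, end = DURATION / 2,
         factors = c(fsi1 = 0.1, fsi2 = 0.1)),
    list(start = 3 * DURATION / 4, end = DURATION,
         factors = c(fsi1 = 0.1, fsi2 = 0.1))
  )
  mk <- function(role, asm, cpl, lgt, pref) {
    generate_session(session_config(
      duration = DURATION, n_pyr = n_pyr, n_msn = 20, n_fsi = 8, n_tan = 5,
      assemblies = asm, couplings = cpl, ffi = ffi, light_epochs = lgt,
      preference = pref,
      seed = hpcnac:::substream_seed(seed, paste0("sess-", role))))
  }
  list(
    pretest = mk("pretest", assemblies, couplings, list(), 0.5),
    test = mk("test", assemblies, couplings, light, 0.75),
    other = mk("other", list(), NULL, list(), 0.5),
    members = members,
    light = light
  )
}

pyr_only <- function(sess) sess$spikes[grep("^pyr", names(sess$spikes))]

results_dir <- function(sub) {
  d <- file.path("results", sub)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
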