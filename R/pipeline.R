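#' Configuration of the end-to-end demonstration pipeline
#'
#' Parameters for a complete synthetic day: a pre-test exploration, a
#' place-preference test (optionally with optogenetic light epochs), and an
#' unrelated "other" enclosure session sharing the same neurons but none of
#' the assembly structure. Every downstream stage (assembly detection and
#' tracking, cell-type classification, spike-timing analysis, ensemble GLM,
#' behavior scoring) runs off these three sessions.
#'
#' @param seed master integer seed; every stage draws an independent
#'   substream.
#' @param duration length of each session, seconds.
#' @param n_pyr,n_msn,n_fsi,n_tan population sizes.
#' @param n_assemblies number of embedded PYR assemblies.
#' @param assembly_size members per assembly.
#' @param assembly_rate activation events per second.
#' @param participation member participation probability per event.
#' @param light if `TRUE`, the test session contains light epochs.
#' @param light_suppression multiplicative rate factor under light for the
#'   targeted neurons.
#' @param suppress_assembly_members if `TRUE`, light targets the PYR assembly
#'   members (in addition to the coupled FSIs).
#' @param test_preference dwell preference for the sucrose-paired enclosure
#'   (A) during the test session.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, duration = 240,
                            n_pyr = 30, n_msn = 20, n_fsi = 8, n_tan = 5,
                            n_assemblies = 3, assembly_size = 5,
                            assembly_rate = 1, participation = 0.8,
                            light = TRUE, light_suppression = 0.1,
                            suppress_assembly_members = FALSE,
                            test_preference = 0.75) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic-session analysis chain
#'
#' Simulates the three sessions, then executes: assembly detection on the
#' pre-test and strength tracking/matching on test and other; waveform
#' classification of the accumbens units against ground truth; PYR-FSI
#' cross-correlogram with theta-shift surrogate band; light-driven rate
#' scores; ensemble GLM trained on the pre-test and scored on test (matched
#' wiring) versus other (uncoupled); and behavioral preference scores. All
#' outputs are deterministic given the master seed; any stage failure aborts
#' with the stage name while preserving completed stages.
#'
#' @param config a [pipeline_config].
#' @param out_dir optional directory; when given, spikes, patterns, traces
#'   and the report are written there as delimited text / JSON.
#' @return report list with a fixed key set (`sessions`, `assemblies`,
#'   `classification`, `timing`, `glm`, `behavior`, `log`); analyses that
#'   cannot run are `NULL`, never absent.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(seed = config$seed, sessions = NULL, assemblies = NULL,
                 classification = NULL, timing = NULL, glm = NULL,
                 behavior = NULL, log = character())
  logline <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, paste0(...))
    report$log <<- c(report$log, line)
    message(line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- config$seed

  ## ---- simulate ----------------------------------------------------------
  sessions <- run_stage("simulate", {
    pyr_ids <- paste0("pyr", seq_len(config$n_pyr))
    members <- withr::with_seed(substream_seed(seed, "members"), {
      lapply(seq_len(config$n_assemblies), function(k)
        sample(pyr_ids, config$assembly_size))
    })
    assemblies <- lapply(members, function(m)
      list(members = m, rate = config$assembly_rate,
           participation = config$participation))
    couplings <- data.frame(
      pre = c("pyr1", "pyr2", "pyr3"),
      post = c("fsi1", "fsi2", "msn1"),
      latency_ms = c(4, 5, 6.5),
      efficacy = c(0.2, 0.2, 0.15),
      stringsAsFactors = FALSE
    )
    ffi <- data.frame(fsi = "fsi1", msn = "msn1", strength = 0.5, tau_ms = 10)
    light_epochs <- list()
    if (config$light) {
      targets <- c(fsi1 = config$light_suppression,
                   fsi2 = config$light_suppression)
      if (config$suppress_assembly_members) {
        mem <- unique(unlist(members))
        targets <- c(targets,
                     stats::setNames(rep(config$light_suppression,
                                         length(mem)), mem))
      }
      brk <- config$duration / 4
      light_epochs <- list(
        list(start = brk, end = 2 * brk, factors = targets),
        list(start = 3 * brk, end = 4 * brk, factors = targets)
      )
    }
    mk <- function(role, assemblies_in, couplings_in, light_in, pref, sseed) {
      cfg <- session_config(
        duration = config$duration, n_pyr = config$n_pyr,
        n_msn = config$n_msn, n_fsi = config$n_fsi, n_tan = config$n_tan,
        assemblies = assemblies_in, couplings = couplings_in, ffi = ffi,
        light_epochs = light_in, preference = pref, seed = sseed
      )
      generate_session(cfg)
    }
    ses <- list(
      pretest = mk("pretest", assemblies, couplings, list(), 0.5,
                   substream_seed(seed, "sess-pretest")),
      test = mk("test", assemblies, couplings, light_epochs,
                config$test_preference, substream_seed(seed, "sess-test")),
      other = mk("other", list(), NULL, list(), 0.5,
                 substream_seed(seed, "sess-other"))
    )
    logline("simulate", sprintf(
      "3 sessions of %gs; %d PYR / %d MSN / %d FSI / %d TAN; %d assemblies; seed %d",
      config$duration, config$n_pyr, config$n_msn, config$n_fsi,
      config$n_tan, config$n_assemblies, seed))
    ses
  })
  report$sessions <- list(
    duration = config$duration,
    n_neurons = length(sessions$pretest$spikes),
    roles = names(sessions)
  )

  pyr_only <- function(s) s$spikes[grep("^pyr", names(s$spikes))]

  ## ---- assemblies --------------------------------------------------------
  report$assemblies <- run_stage("assemblies", {
    bz <- bin_and_zscore(pyr_only(sessions$pretest), c(0, config$duration))
    n_sig <- count_significant_patterns(bz)
    pats <- if (n_sig > 0)
      extract_patterns(bz, n_sig, seed = substream_seed(seed, "ica"))
    else list()
    track <- function(sess) {
      lapply(pats, function(p)
        activation_strength(p, pyr_only(sess), c(0, config$duration),
                            step = 0.002))
    }
    tr_test <- track(sessions$test)
    tr_other <- track(sessions$other)
    mean_strength <- function(traces, epochs = NULL) {
      if (!length(traces)) return(NA_real_)
      mean(vapply(traces, function(x) {
        keep <- if (is.null(epochs)) rep(TRUE, length(x$times)) else
          Reduce(`|`, lapply(epochs, function(e)
            x$times >= e$start & x$times < e$end))
        mean(x$strength[keep])
      }, 0))
    }
    on_epochs <- sessions$test$truth$light_epochs
    act_rate <- function(traces)
      if (length(traces))
        mean(vapply(traces, function(x)
          length(detect_activations(x)) / config$duration, 0))
      else NA_real_
    detect_in <- function(sess, key) {
      bz2 <- bin_and_zscore(pyr_only(sess), c(0, config$duration))
      n2 <- count_significant_patterns(bz2)
      if (n2 > 0) extract_patterns(bz2, n2, seed = substream_seed(seed, key))
      else list()
    }
    pats_test <- detect_in(sessions$test, "ica-test")
    pats_other <- detect_in(sessions$other, "ica-other")
    msim <- function(b) {
      if (!length(pats) || !length(b)) return(NA_real_)
      mean(match_patterns(pats, b)$matching$similarity)
    }
    logline("assemblies", sprintf(
      "%d significant patterns on pre-test; matched similarity test %.3f / other %.3f",
      n_sig, msim(pats_test), msim(pats_other)))
    list(n_patterns = n_sig,
         patterns = pats,
         mean_similarity_test = msim(pats_test),
         mean_similarity_other = msim(pats_other),
         mean_strength_test = mean_strength(tr_test),
         mean_strength_test_on = if (length(on_epochs))
           mean_strength(tr_test, on_epochs) else NULL,
         mean_strength_other = mean_strength(tr_other),
         activation_rate_test = act_rate(tr_test))
  })

  ## ---- classification ----------------------------------------------------
  report$classification <- run_stage("classification", {
    wf <- sessions$pretest$waveforms
    if (nrow(wf$waveforms) >= 3) {
      feats <- t(apply(wf$waveforms, 1, function(w) {
        f <- waveform_features(w, t_ms = wf$t_ms)
        c(f$first_peak_ms, f$second_peak_ms, f$symmetry)
      }))
      colnames(feats) <- c("first_peak_ms", "second_peak_ms", "symmetry")
      nac_ids <- names(sessions$pretest$spikes)[
        grep("^(msn|fsi|tan)", names(sessions$pretest$spikes))]
      rates <- vapply(sessions$pretest$spikes[nac_ids], length, 0) /
        config$duration
      cls <- classify_units(feats, rates,
                            seed = substream_seed(seed, "classify"))
      truth <- toupper(wf$labels)
      acc <- mean(as.character(cls$labels) == truth)
      logline("classification", sprintf(
        "accuracy vs ground truth %.3f; min cross-algorithm ARI %.3f",
        acc, min(cls$agreement)))
      list(accuracy = acc, agreement = as.list(cls$agreement),
           labels = as.character(cls$labels))
    } else NULL
  })

  ## ---- timing ------------------------------------------------------------
  report$timing <- run_stage("timing", {
    s <- sessions$test
    ccg <- cross_correlogram(
      s$spikes$pyr1, s$spikes$fsi1, window_s = 0.05, bin_s = 0.001,
      cycles = s$cycles, n_surrogates = 100, global_window_ms = c(3.2, 8),
      seed = substream_seed(seed, "surrogates"))
    coupling_detected <- ccg$global_exceeds
    scores <- NULL
    if (config$light) {
      on_ep <- do.call(rbind, lapply(s$truth$light_epochs, function(e)
        data.frame(start = e$start, end = e$end)))
      off_ep <- data.frame(start = c(0, config$duration / 2),
                           end = c(config$duration / 4,
                                   3 * config$duration / 4))
      scores <- vapply(names(s$spikes), function(id)
        suppressMessages(light_rate_score(s$spikes[[id]], on_ep, off_ep)),
        0)
    }
    depth <- vapply(c("pyr1", "fsi1", "msn1"), function(id)
      theta_modulation_depth(s$spikes[[id]], s$cycles), 0)
    logline("timing", sprintf(
      "short-latency coupling detected: %s; fsi1 rate score %.2f",
      coupling_detected,
      if (!is.null(scores)) scores[["fsi1"]] else NA))
    list(coupling_detected = coupling_detected,
         rate_scores = if (is.null(scores)) NULL else as.list(scores),
         rayleigh = as.list(depth))
  })

  ## ---- glm ---------------------------------------------------------------
  report$glm <- run_stage("glm", {
    cc <- lapply(sessions, function(s) bin_by_cycles(s$spikes, s$cycles))
    pyr_cols <- grep("^pyr", colnames(cc$pretest$counts), value = TRUE)
    score_on <- function(model, sess_cc, target) {
      suppressMessages(predict_and_score(
        model, sess_cc$counts[, pyr_cols, drop = FALSE],
        sess_cc$counts[, target]))$accuracy
    }
    model <- fit_ensemble_model(cc$pretest$counts[, "msn1"],
                                cc$pretest$counts[, pyr_cols, drop = FALSE],
                                training_id = "pretest")
    acc_test <- score_on(model, cc$test, "msn1")
    acc_other <- score_on(model, cc$other, "msn1")
    logline("glm", sprintf("msn1 accuracy: test %.3f, other %.3f",
                           acc_test, acc_other))
    list(target = "msn1", accuracy_test = acc_test,
         accuracy_other = acc_other, r2_train = model$r2_train)
  })

  ## ---- behavior ----------------------------------------------------------
  report$behavior <- run_stage("behavior", {
    sc_pre <- preference_score(sessions$pretest$position, target = "A")
    sc_test <- preference_score(sessions$test$position, target = "A")
    logline("behavior", sprintf("CPP score pre-test %.3f, test %.3f",
                                sc_pre$score, sc_test$score))
    list(score_pretest = sc_pre$score, score_test = sc_test$score,
         t_target_test = sc_test$t_target, t_other_test = sc_test$t_other)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(sessions))
      write_spikes(sessions[[nm]]$spikes,
                   file.path(out_dir, paste0("spikes_", nm, ".csv")))
    write_position(sessions$test$position, file.path(out_dir, "position_test.csv"))
    if (length(report$assemblies$patterns))
      write_patterns(report$assemblies$patterns,
                     file.path(out_dir, "patterns_pretest.json"))
    save_report <- report
    save_report$assemblies$patterns <- NULL
    jsonlite::write_json(save_report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}
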