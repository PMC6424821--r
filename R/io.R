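#' Read spike trains from delimited text
#'
#' Expects a two-column delimited file with a header, columns `neuron_id` and
#' `time_s`. Non-numeric time rows raise an error naming the offending line;
#' unsorted times within a neuron are sorted with a warning.
#'
#' @param path file path.
#' @param sep field separator.
#' @return data frame `neuron_id`, `time` (seconds).
#' @export
read_spikes <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE)
  if (!all(c("neuron_id", "time_s") %in% names(raw)))
    stop("expected header columns 'neuron_id' and 'time_s'")
  times <- suppressWarnings(as.numeric(raw$time_s))
  bad <- which(is.na(times) & nzchar(raw$time_s))
  bad <- union(bad, which(is.na(times)))
  if (length(bad))
    stop("non-numeric time value at line ", bad[1] + 1L,
         " of ", path)
  df <- data.frame(neuron_id = raw$neuron_id, time = times,
                   stringsAsFactors = FALSE)
  unsorted <- vapply(split(df$time, df$neuron_id), is.unsorted, TRUE)
  if (any(unsorted)) {
    warning("unsorted spike times for ",
            paste(names(unsorted)[unsorted], collapse = ", "), "; sorting")
    df <- df[order(df$neuron_id, df$time), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write spike trains as delimited text
#'
#' Times are written with microsecond precision, so a write-read round trip
#' is the identity to 1e-6 s.
#'
#' @param spikes spike trains (list or data frame).
#' @param path file path.
#' @param sep field separator.
#' @export
write_spikes <- function(spikes, path, sep = ",") {
  df <- spikes_to_df(spikes)
  out <- data.frame(neuron_id = df$neuron_id,
                    time_s = sprintf("%.6f", df$time))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write labeled event epochs
#'
#' Delimited text with header `label, start_s, end_s`.
#' @param path file path.
#' @param sep field separator.
#' @return data frame `label, start, end`.
#' @export
read_events <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("label", "start_s", "end_s") %in% names(df)))
  data.frame(label = df$label, start = df$start_s, end = df$end_s)
}

#' @rdname read_events
#' @param events data frame `label, start, end`.
#' @export
write_events <- function(events, path, sep = ",") {
  out <- data.frame(label = events$label,
                    start_s = sprintf("%.6f", events$start),
                    end_s = sprintf("%.6f", events$end))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a position trace
#'
#' Delimited text with header `t_s, x_cm, y_cm`.
#' @param path file path.
#' @param sep field separator.
#' @return data frame `t, x, y`.
#' @export
read_position <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  stopifnot(all(c("t_s", "x_cm", "y_cm") %in% names(df)))
  data.frame(t = df$t_s, x = df$x_cm, y = df$y_cm)
}

#' @rdname read_position
#' @param position data frame `t, x, y`.
#' @export
write_position <- function(position, path, sep = ",") {
  out <- data.frame(t_s = sprintf("%.6f", position$t),
                    x_cm = sprintf("%.4f", position$x),
                    y_cm = sprintf("%.4f", position$y))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize assembly patterns to JSON
#'
#' @param patterns list of `assembly_pattern` objects.
#' @param path file path.
#' @export
write_patterns <- function(patterns, path) {
  payload <- lapply(patterns, function(p)
    list(neuron_ids = names(p$w), weights = unname(p$w), members = p$members))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patterns
#' @return `read_patterns` returns a list of `assembly_pattern` objects.
#' @export
read_patterns <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i) {
    w <- as.numeric(payload$weights[[i]])
    names(w) <- payload$neuron_ids[[i]]
    new_assembly_pattern(w / sqrt(sum(w^2)))
  })
}
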