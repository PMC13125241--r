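# Plain-text persistence for LFP datasets.
#
# A dataset directory contains: meta.json (dimensions, fs, time axis
# origin), channels.csv, events.csv, and one signal_<channel>.csv per
# channel (samples x trials). Entirely text-based so datasets survive
# any transport that handles CSV/JSON.

#' Write / read an LFP dataset as a plain-text directory
#'
#' @param dataset An `lfp_dataset`.
#' @param path Directory to create (must not already contain a dataset
#'   unless `overwrite = TRUE`).
#' @param overwrite Whether to replace an existing directory.
#' @return `write_lfp_dataset` returns `path` invisibly;
#'   `read_lfp_dataset` returns the reconstructed `lfp_dataset`
#'   (without ground truth, which is an in-memory simulation object).
#' @export
write_lfp_dataset <- function(dataset, path, overwrite = FALSE) {
  stopifnot(inherits(dataset, "lfp_dataset"))
  if (dir.exists(path)) {
    if (!overwrite) stop_bad("`%s` exists; use overwrite = TRUE", path)
  } else {
    dir.create(path, recursive = TRUE)
  }
  d <- dim(dataset$signal)
  meta <- list(n_channels = d[1], n_trials = d[2], n_samples = d[3],
               fs = dataset$fs, t0_ms = dataset$times[1])
  writeLines(to_json(meta), file.path(path, "meta.json"))
  utils::write.csv(dataset$channels, file.path(path, "channels.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$events, file.path(path, "events.csv"),
                   row.names = FALSE)
  for (ch in seq_len(d[1])) {
    m <- t(dataset$signal[ch, , , drop = TRUE])   # samples x trials
    if (d[2] == 1) m <- matrix(dataset$signal[ch, 1, ], ncol = 1)
    utils::write.csv(as.data.frame(m),
                     file.path(path, sprintf("signal_%03d.csv", ch)),
                     row.names = FALSE)
  }
  invisible(path)
}

# minimal JSON writer for flat named lists of scalars
to_json <- function(x) {
  fields <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    val <- if (is.character(v)) sprintf("\"%s\"", v) else
      format(v, digits = 15, scientific = FALSE)
    sprintf("\"%s\": %s", nm, val)
  }, character(1))
  paste0("{", paste(fields, collapse = ", "), "}")
}

from_json_flat <- function(line) {
  line <- gsub("^\\{|\\}$", "", trimws(line))
  parts <- strsplit(line, ",(?=\\s*\")", perl = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    key <- gsub("\"|\\s", "", kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    out[[key]] <- if (grepl("^\"", val)) gsub("\"", "", val) else as.numeric(val)
  }
  out
}

#' @rdname write_lfp_dataset
#' @export
read_lfp_dataset <- function(path) {
  meta <- from_json_flat(readLines(file.path(path, "meta.json"))[1])
  channels <- as_tibble(utils::read.csv(file.path(path, "channels.csv")))
  events <- as_tibble(utils::read.csv(file.path(path, "events.csv")))
  sig <- array(NA_real_,
               dim = c(meta$n_channels, meta$n_trials, meta$n_samples))
  for (ch in seq_len(meta$n_channels)) {
    m <- as.matrix(utils::read.csv(file.path(path,
                                             sprintf("signal_%03d.csv", ch))))
    sig[ch, , ] <- t(m)
  }
  structure(
    list(signal = sig, fs = meta$fs,
         times = meta$t0_ms + (seq_len(meta$n_samples) - 1) * 1000 / meta$fs,
         channels = channels, events = events, ground_truth = NULL,
         components = NULL),
    class = "lfp_dataset"
  )
}
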