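#' On-disk trial archive
#'
#' A trial archive is a directory with a `meta.json` file and one plain-text
#' numeric matrix per trial. `meta.json` holds the sampling rate, the number
#' of classes, channel names with 2-D scalp positions and, per trial, its
#' file name, label (`null` when unlabeled) and 0-based cue index. Each
#' `trial_####.csv` stores the channels x time matrix, one row per channel,
#' comma-separated, no header. Values round-trip to within 1e-8 relative
#' precision.
#'
#' @param set A [trial_set()].
#' @param path Directory to create/populate.
#' @param extra Optional named list of additional metadata (e.g. simulator
#'   ground truth) stored verbatim under `"extra"`.
#' @return `path`, invisibly.
#' @seealso [read_trial_archive()]
#' @export
write_trial_archive <- function(set, path, extra = NULL) {
  if (!inherits(set, "TrialSet")) stop("set must be a TrialSet")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("trial_%04d.csv", seq_along(set$trials))
  meta <- list(
    format = "eeg-trial-archive-v1",
    rate = set_rate(set),
    n_classes = set$n_classes,
    channels = lapply(seq_along(set$layout$names), function(i) {
      list(name = set$layout$names[i],
           x = set$layout$positions[i, 1],
           y = set$layout$positions[i, 2])
    }),
    trials = lapply(seq_along(set$trials), function(i) {
      tr <- set$trials[[i]]
      list(file = files[i],
           label = if (is.na(tr$label)) NULL else tr$label,
           cue_index = tr$cue_index)
    })
  )
  if (!is.null(extra)) meta$extra <- extra
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(set$trials)) {
    data.table::fwrite(data.table::as.data.table(set$trials[[i]]$data),
                       file.path(path, files[i]),
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a trial archive directory
#'
#' Validates the archive against its own metadata: every trial matrix must
#' have exactly one row per declared channel, labels must lie in
#' `1..n_classes`, and cue indices must fall inside the trial. Errors name
#' the offending trial file.
#'
#' @param path Archive directory written by [write_trial_archive()] (or any
#'   tool emitting the documented layout).
#' @return A [trial_set()]; simulator metadata (if present) is attached as
#'   attribute `"extra"`.
#' @export
read_trial_archive <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    stop("no meta.json found in archive directory: ", path)
  }
  meta <- jsonlite::read_json(meta_file)
  if (is.null(meta$rate) || is.null(meta$n_classes) || is.null(meta$channels)) {
    stop("meta.json is missing one of: rate, n_classes, channels")
  }
  ch_names <- vapply(meta$channels, function(ch) ch$name, character(1))
  pos <- cbind(vapply(meta$channels, function(ch) as.numeric(ch$x), numeric(1)),
               vapply(meta$channels, function(ch) as.numeric(ch$y), numeric(1)))
  layout <- channel_layout(ch_names, pos)
  n_classes <- as.integer(meta$n_classes)
  trials <- lapply(meta$trials, function(entry) {
    f <- file.path(path, entry$file)
    if (!file.exists(f)) stop("trial file listed in meta.json is missing: ", entry$file)
    mat <- as.matrix(data.table::fread(f, header = FALSE))
    dimnames(mat) <- NULL
    if (nrow(mat) != length(ch_names)) {
      stop("trial file ", entry$file, " has ", nrow(mat),
           " rows but the layout declares ", length(ch_names), " channels")
    }
    if (!is.numeric(mat) || !all(is.finite(mat))) {
      stop("trial file ", entry$file, " contains non-numeric or non-finite values")
    }
    label <- if (is.null(entry$label)) NA_integer_ else as.integer(entry$label)
    if (!is.na(label) && (label < 1 || label > n_classes)) {
      stop("trial file ", entry$file, " carries unknown label ", label,
           " (n_classes = ", n_classes, ")")
    }
    eeg_trial(mat, rate = as.numeric(meta$rate),
              cue_index = as.integer(entry$cue_index), label = label)
  })
  out <- trial_set(trials, layout, n_classes)
  if (!is.null(meta$extra)) attr(out, "extra") <- meta$extra
  out
}
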