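#' Read an event sequence from a BIDS-style events TSV
#'
#' The file must have columns `onset` (s), `duration` (s) and `trial_type`
#' with values `A` (auditory) or `V` (visual); one file describes one
#' stimulus.
#'
#' @param path TSV file path.
#' @param duration sequence duration (s); defaults to 1 s.
#' @param label sequence label; defaults to the file name.
#' @return An `event_sequence`.
#' @export
read_event_sequence <- function(path, duration = 1, label = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(tab))) {
    stop("events TSV must have columns onset, duration, trial_type",
         call. = FALSE)
  }
  if (!all(tab$trial_type %in% c("A", "V"))) {
    stop("trial_type must be 'A' or 'V'", call. = FALSE)
  }
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  event_sequence(tab$onset[tab$trial_type == "A"],
                 tab$onset[tab$trial_type == "V"],
                 duration = duration, label = label)
}

#' Write an event sequence to a BIDS-style events TSV
#'
#' @param seq an `event_sequence`.
#' @param path output TSV path.
#' @param event_duration per-event duration column value (s); the physical
#'   clicks and flashes last 10 ms.
#' @return `path`, invisibly.
#' @export
write_event_sequence <- function(seq, path, event_duration = 0.01) {
  stopifnot(inherits(seq, "event_sequence"))
  tab <- data.frame(
    onset = c(seq$auditory_onsets, seq$visual_onsets),
    duration = event_duration,
    trial_type = rep(c("A", "V"),
                     c(length(seq$auditory_onsets), length(seq$visual_onsets)))
  )
  tab <- tab[order(tab$onset), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export detector traces to CSV
#'
#' @param resp an `mcd_response`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mcd_response <- function(resp, path) {
  utils::write.csv(as.data.frame(resp), path, row.names = FALSE)
  invisible(path)
}

#' Read / write behavioral trial tables
#'
#' Trial tables are plain CSV with columns `participant`, `task`
#' (`causality` or `temporal_order`, plus `localizer_A` / `localizer_V` for
#' passive blocks), `block`, `stimulus` and `response` (0/1, `NA` for
#' passive blocks).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "task", "stimulus")
  if (!all(need %in% names(tab))) {
    stop("trial table must have columns participant, task, stimulus",
         call. = FALSE)
  }
  tab
}

#' @rdname read_trial_table
#' @param trials trial table data.frame.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a sensor adjacency matrix as an edge list CSV
#'
#' @param adjacency symmetric logical/0-1 matrix with zero diagonal.
#' @param path CSV path (columns `from`, `to`, one row per undirected edge).
#' @param sensor_names character vector naming the sensors; defaults to the
#'   matrix dimnames.
#' @return `write_adjacency` returns `path`; `read_adjacency` the matrix.
#' @export
write_adjacency <- function(adjacency, path, sensor_names = NULL) {
  if (is.null(sensor_names)) sensor_names <- rownames(adjacency)
  if (is.null(sensor_names)) sensor_names <- as.character(seq_len(nrow(adjacency)))
  e <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)
  utils::write.csv(data.frame(from = sensor_names[e[, 1]],
                              to = sensor_names[e[, 2]]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path, sensor_names = NULL) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(sensor_names)) sensor_names <- sort(unique(c(e$from, e$to)))
  n <- length(sensor_names)
  adj <- matrix(FALSE, n, n, dimnames = list(sensor_names, sensor_names))
  i <- match(e$from, sensor_names)
  j <- match(e$to, sensor_names)
  adj[cbind(i, j)] <- TRUE
  adj[cbind(j, i)] <- TRUE
  adj
}

#' Write / read an epoch set as a flat binary array plus JSON sidecar
#'
#' The sample array is stored as little-endian float64 in
#' `<prefix>.dat` (trial-major, then sensor, then time) and the metadata
#' (dimensions, sensor names, rate, window, units) in `<prefix>.json`;
#' trial metadata go to `<prefix>_trials.csv`.
#'
#' @param epochs an `epoch_set`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "epoch_set"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(epochs$data), con, size = 8, endian = "little")
  meta <- list(dim = dim(epochs$data), rate = epochs$rate,
               window = epochs$window, sensor_names = epochs$sensor_names,
               units = "tesla")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(epochs$trial_meta)) {
    utils::write.csv(epochs$trial_meta, paste0(prefix, "_trials.csv"),
                     row.names = FALSE)
  }
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  trials_path <- paste0(prefix, "_trials.csv")
  meta_df <- if (file.exists(trials_path)) {
    utils::read.csv(trials_path, stringsAsFactors = FALSE)
  } else NULL
  epoch_set(array(x, dim = meta$dim), rate = meta$rate, window = meta$window,
            trial_meta = meta_df, sensor_names = meta$sensor_names)
}
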