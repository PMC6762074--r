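#' Trial-structured spike data for one neuron
#'
#' A `spike_train_set` holds the spike times of a single neuron in response to
#' repeated presentations of a set of discrete stimuli, each stimulus carrying
#' a category label (e.g. a call-type).  Times are in milliseconds from
#' stimulus onset and must lie in the half-open response window
#' `[0, window_ms)`.
#'
#' @param stimuli A named list, one element per stimulus.  Each element is a
#'   list with components `category` (single character label) and `trials`
#'   (a list of numeric vectors of spike times in ms; an empty vector is a
#'   trial with no spikes).  Names are the stimulus ids and must be unique.
#' @param window_ms Response-window duration in ms (default 600).
#' @param neuron_id Character label for the neuron.
#'
#' @return An object of class `spike_train_set` with components `neuron_id`,
#'   `window_ms` and `stimuli`.
#'
#' @details Every stimulus must have at least 2 trials (delete-one jackknife
#'   resampling requires it).  Trial counts may differ between stimuli; all
#'   per-stimulus computations use that stimulus's own trial count.
#'
#' @seealso [read_spike_table()], [bin_counts()], [sample_spikes()]
#' @export
spike_train_set <- function(stimuli, window_ms = 600, neuron_id = "neuron") {
  if (!is.list(stimuli) || length(stimuli) == 0L)
    stop("'stimuli' must be a non-empty list")
  ids <- names(stimuli)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("stimulus ids (names of 'stimuli') must be unique non-empty strings")
  if (!is.numeric(window_ms) || length(window_ms) != 1L || window_ms <= 0)
    stop("'window_ms' must be a positive scalar")
  for (id in ids) {
    st <- stimuli[[id]]
    if (is.null(st$category) || length(st$category) != 1L)
      stop("stimulus '", id, "': missing single category label")
    if (!is.list(st$trials) || length(st$trials) < 2L)
      stop("stimulus '", id, "': at least 2 trials are required")
    for (j in seq_along(st$trials)) {
      tt <- st$trials[[j]]
      if (length(tt) && (!is.numeric(tt) || any(!is.finite(tt))))
        stop("stimulus '", id, "', trial ", j, ": non-finite spike times")
      if (length(tt) && (any(tt < 0) || any(tt >= window_ms)))
        stop("stimulus '", id, "', trial ", j,
             ": spike times must satisfy 0 <= t < window_ms")
      stimuli[[id]]$trials[[j]] <- as.numeric(sort(tt))
    }
    stimuli[[id]]$category <- as.character(st$category)
  }
  structure(list(neuron_id = as.character(neuron_id),
                 window_ms = as.numeric(window_ms),
                 stimuli = stimuli),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  m <- vapply(x$stimuli, function(s) length(s$trials), 0L)
  n <- vapply(x$stimuli, function(s) sum(lengths(s$trials)), 0L)
  cat("spike_train_set '", x$neuron_id, "': ", length(x$stimuli),
      " stimuli, window ", x$window_ms, " ms\n", sep = "")
  cat("  trials per stimulus: ", paste(range(m), collapse = "-"),
      "; total spikes: ", sum(n), "\n", sep = "")
  cat("  categories: ", paste(unique(category_map(x)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Stimulus-to-category mapping of a spike train set
#'
#' @param x A `spike_train_set` (or a named character vector which is passed
#'   through after validation).
#' @return A named character vector mapping stimulus id to category label.
#' @export
category_map <- function(x) {
  if (inherits(x, "spike_train_set"))
    return(vapply(x$stimuli, function(s) s$category, ""))
  if (is.character(x) && !is.null(names(x))) return(x)
  stop("cannot derive a category map from this object")
}

#' Number of trials per stimulus
#' @param x A `spike_train_set`.
#' @return Named integer vector of trial counts.
#' @export
n_trials <- function(x) {
  stopifnot(inherits(x, "spike_train_set"))
  vapply(x$stimuli, function(s) length(s$trials), 0L)
}

.sniff_sep <- function(line) if (grepl("\t", line)) "\t" else ","

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a spike table
#'
#' Reads the package's flat long-format spike table: delimiter-separated text
#' (comma or tab, sniffed from the header) with columns `neuron_id`,
#' `stimulus_id`, `category`, `trial`, `spike_time_ms`; one spike per row.
#' A trial with no spikes is declared by a single row whose `spike_time_ms`
#' field is empty.  Trial indices need not be contiguous; they are remapped
#' to consecutive order per stimulus.
#'
#' @param path Path to the file.
#' @param window_ms Response-window duration in ms used for validation
#'   (default 600).
#' @return A [spike_train_set()].
#' @examples
#' path <- system.file("extdata", "example_spikes.csv", package = "tvinfo")
#' spk <- read_spike_table(path, window_ms = 200)
#' spk
#' @export
read_spike_table <- function(path, window_ms = 600) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("spike table '", path, "' has no data rows")
  sep <- .sniff_sep(lines[1L])
  hdr <- trimws(strsplit(lines[1L], sep, fixed = TRUE)[[1L]])
  need <- c("neuron_id", "stimulus_id", "category", "trial", "spike_time_ms")
  pos <- match(need, hdr)
  if (anyNA(pos))
    stop("spike table header must contain columns: ",
         paste(need[is.na(pos)], collapse = ", "))
  recs <- vector("list", length(lines) - 1L)
  for (k in 2:length(lines)) {
    if (!nzchar(trimws(lines[k]))) next
    f <- strsplit(lines[k], sep, fixed = TRUE)[[1L]]
    length(f) <- max(length(f), max(pos))  # pad trailing empty fields
    f <- trimws(ifelse(is.na(f), "", f))
    if (!all(nzchar(f[pos[1:4]])))
      stop("malformed row at line ", k, " of '", path, "'")
    tr <- suppressWarnings(as.integer(f[pos[4L]]))
    if (is.na(tr)) stop("malformed trial index at line ", k, " of '", path, "'")
    tm <- f[pos[5L]]
    if (nzchar(tm)) {
      tm <- suppressWarnings(as.numeric(tm))
      if (is.na(tm)) stop("malformed spike time at line ", k, " of '", path, "'")
    } else tm <- NA_real_
    recs[[k - 1L]] <- list(neuron = f[pos[1L]], stim = f[pos[2L]],
                           cat = f[pos[3L]], trial = tr, time = tm)
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (!length(recs)) stop("spike table '", path, "' has no data rows")
  neuron <- recs[[1L]]$neuron
  stim_ids <- unique(vapply(recs, `[[`, "", "stim"))
  stimuli <- list()
  for (id in stim_ids) {
    rr <- recs[vapply(recs, function(r) r$stim == id, TRUE)]
    cats <- unique(vapply(rr, `[[`, "", "cat"))
    if (length(cats) != 1L)
      stop("stimulus '", id, "' has inconsistent category labels")
    tr_ids <- sort(unique(vapply(rr, `[[`, 0L, "trial")))
    trials <- lapply(tr_ids, function(j) {
      tt <- vapply(rr[vapply(rr, function(r) r$trial == j, TRUE)],
                   `[[`, 0, "time")
      as.numeric(sort(tt[!is.na(tt)]))
    })
    stimuli[[id]] <- list(category = cats, trials = trials)
  }
  spike_train_set(stimuli, window_ms = window_ms, neuron_id = neuron)
}

#' Write a spike table
#'
#' Writes the long-format table read back by [read_spike_table()]; empty
#' trials are kept as rows with an empty `spike_time_ms` field so that
#' `read_spike_table(write_spike_table(x))` round-trips exactly.
#'
#' @param x A `spike_train_set`.
#' @param path Output path.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return Invisibly, `path`.
#' @export
write_spike_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "spike_train_set"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- paste(c("neuron_id", "stimulus_id", "category", "trial",
                 "spike_time_ms"), collapse = sep)
  writeLines(hdr, con)
  for (id in names(x$stimuli)) {
    st <- x$stimuli[[id]]
    for (j in seq_along(st$trials)) {
      tt <- st$trials[[j]]
      times <- if (length(tt)) format(tt, digits = 15, trim = TRUE,
                                      scientific = FALSE) else ""
      writeLines(paste(x$neuron_id, id, st$category, j - 1L, times,
                       sep = sep), con)
    }
  }
  invisible(path)
}

#' Bin spike trains into spike counts
#'
#' Counts spikes in consecutive half-open bins `[b*bin_ms, (b+1)*bin_ms)`.
#' The default 10 ms bin matches a 50 Hz Nyquist limit for the time-varying
#' rate; a 600 ms window then gives 60 bins.
#'
#' @param x A `spike_train_set`.
#' @param bin_ms Bin width in ms; must divide `window_ms`.
#' @return A `binned_counts` object: list with `bin_ms`, `n_bins`,
#'   `categories`, and `counts`, a named list of trial-by-bin integer
#'   matrices (one per stimulus).
#' @export
bin_counts <- function(x, bin_ms = 10) {
  stopifnot(inherits(x, "spike_train_set"))
  nb <- x$window_ms / bin_ms
  if (abs(nb - round(nb)) > 1e-9)
    stop("'bin_ms' must divide the response window (", x$window_ms, " ms)")
  nb <- as.integer(round(nb))
  counts <- lapply(x$stimuli, function(st) {
    v <- vapply(st$trials, function(tt) {
      tabulate(pmin(floor(tt / bin_ms), nb - 1L) + 1L, nbins = nb)
    }, integer(nb))
    m <- if (is.matrix(v)) t(v) else matrix(v, ncol = 1L)
    storage.mode(m) <- "integer"
    m
  })
  structure(list(bin_ms = bin_ms, n_bins = nb,
                 categories = category_map(x), counts = counts),
            class = "binned_counts")
}

#' Write an information series to a tab-delimited file
#'
#' One row per analysis bin with columns `time_ms` (bin end), `info_bits`,
#' `se_bits` and `significant` (the 3-SE rule).  Bins after an estimation
#' abort carry empty cells.
#'
#' @param series An `info_series` (see [instantaneous_info()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_info_series <- function(series, path) {
  stopifnot(inherits(series, "info_series"))
  fmt <- function(v) ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE))
  sig <- significance_mask(series)$significant
  df <- data.frame(time_ms = fmt(series$time_ms),
                   info_bits = fmt(series$info),
                   se_bits = fmt(series$se),
                   significant = ifelse(is.na(sig), "", as.character(sig)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an information series written by [write_info_series()]
#' @param path Path to the file.
#' @return An `info_series` data frame.
#' @export
read_info_series <- function(path) {
  df <- utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE)
  out <- info_series(time_ms = as.numeric(df$time_ms),
                     info = as.numeric(df$info_bits),
                     se = as.numeric(df$se_bits),
                     kind = "unknown")
  out
}

#' Construct an information series
#'
#' Container for per-bin information values in bits with standard errors.
#' Mostly built internally by [instantaneous_info()], [cumulative_info()] and
#' [exact_window_info()].
#'
#' @param time_ms Bin end times in ms.
#' @param info Information per bin (bits).
#' @param se Standard error per bin (bits); `NA` when unavailable.
#' @param kind One of `"instantaneous_stim"`, `"instantaneous_cat"`,
#'   `"cumulative_stim"`, `"cumulative_cat"`, `"window_stim"`,
#'   `"window_cat"`, `"unknown"`.
#' @param abort_bin Optional index of the first unreliable bin; values from
#'   this bin on are `NA`.
#' @return A data frame of class `info_series` with attributes `kind` and
#'   `abort_bin`.
#' @export
info_series <- function(time_ms, info, se = rep(NA_real_, length(info)),
                        kind = "unknown", abort_bin = NA_integer_) {
  stopifnot(length(time_ms) == length(info), length(se) == length(info))
  if (any(se < 0, na.rm = TRUE)) stop("standard errors must be >= 0")
  df <- data.frame(time_ms = as.numeric(time_ms), info = as.numeric(info),
                   se = as.numeric(se))
  structure(df, kind = kind, abort_bin = as.integer(abort_bin),
            class = c("info_series", "data.frame"))
}

#' @export
print.info_series <- function(x, ...) {
  cat("info_series (", attr(x, "kind"), "), ", nrow(x), " bins\n", sep = "")
  if (!is.na(attr(x, "abort_bin")))
    cat("  estimation aborted at bin ", attr(x, "abort_bin"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}
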