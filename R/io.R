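#' Read and write the plain-text epochs store
#'
#' A cohort lives in one directory: \code{times.tsv} (one column
#' \code{time_ms}), \code{trials.tsv} (per-trial metadata: subject_id,
#' trial_index, condition, modality), \code{subjects.tsv} (subject_id,
#' channel, sfreq, n_trials, data_file) and, under \code{data/}, one
#' whitespace-separated numeric matrix per subject (trials x time, written
#' with 17 significant digits so float64 round-trips losslessly).
#'
#' @param cohort list of \code{epoch_set} objects (one per subject).
#' @param path cohort directory (created if missing on write).
#' @return \code{read_epochs} returns a named list of \code{epoch_set}s;
#'   \code{write_epochs} returns \code{path} invisibly.
#' @seealso [read_ratings()], [write_ratings()]
#' @export
write_epochs <- function(cohort, path) {
  if (inherits(cohort, "epoch_set")) cohort <- list(cohort)
  dir.create(file.path(path, "data"), recursive = TRUE, showWarnings = FALSE)
  times <- cohort[[1L]]$times
  for (e in cohort)
    if (!isTRUE(all.equal(e$times, times, tolerance = 1e-12)))
      stop("all subjects in one store must share a time axis")
  data.table::fwrite(data.table::data.table(time_ms = times),
                     file.path(path, "times.tsv"), sep = "\t")
  subj <- data.table::rbindlist(lapply(cohort, function(e)
    data.table::data.table(subject_id = e$subject_id, channel = e$channel,
                           sfreq = e$sfreq, n_trials = nrow(e$data),
                           data_file = file.path("data", paste0(e$subject_id, ".tsv")))))
  if (anyDuplicated(subj$subject_id)) stop("duplicate subject_id in cohort")
  data.table::fwrite(subj, file.path(path, "subjects.tsv"), sep = "\t")
  trials <- data.table::rbindlist(lapply(cohort, function(e)
    data.table::data.table(subject_id = e$subject_id,
                           trial_index = seq_len(nrow(e$data)),
                           condition = e$condition, modality = e$modality)))
  data.table::fwrite(trials, file.path(path, "trials.tsv"), sep = "\t")
  for (e in cohort) {
    con <- file(file.path(path, "data", paste0(e$subject_id, ".tsv")), "w")
    utils::write.table(format(e$data, digits = 17, scientific = TRUE, trim = TRUE),
                       con, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    close(con)
  }
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  for (f in c("times.tsv", "subjects.tsv", "trials.tsv"))
    if (!file.exists(file.path(path, f)))
      stop("malformed epochs store: missing ", f)
  times <- data.table::fread(file.path(path, "times.tsv"), data.table = FALSE)$time_ms
  subjects <- data.table::fread(file.path(path, "subjects.tsv"),
                                data.table = FALSE)
  trials <- data.table::fread(file.path(path, "trials.tsv"), data.table = FALSE,
                              colClasses = list(character = "subject_id"))
  cohort <- vector("list", nrow(subjects))
  names(cohort) <- subjects$subject_id
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    f <- file.path(path, s$data_file)
    if (!file.exists(f)) stop("malformed epochs store: missing ", s$data_file)
    mat <- as.matrix(data.table::fread(f, header = FALSE, data.table = FALSE))
    dimnames(mat) <- NULL
    meta <- trials[trials$subject_id == as.character(s$subject_id), ]
    if (nrow(meta) != nrow(mat) || nrow(mat) != s$n_trials)
      stop("malformed epochs store: trial metadata rows (", nrow(meta),
           ") do not match data rows (", nrow(mat), ") for subject ",
           s$subject_id)
    cohort[[i]] <- epoch_set(mat, times, meta$condition,
                             subject_id = as.character(s$subject_id),
                             sfreq = s$sfreq, channel = s$channel,
                             modality = meta$modality)
  }
  cohort
}

#' Read or write a per-trial ratings table
#'
#' Ratings are kept in a TSV with header
#' \code{subject_id / modality / condition / trial_index / rating}; ratings
#' are perceived intensities on the 0-10 numerical rating scale (NRS).
#'
#' @param ratings data.frame with the columns above.
#' @param path TSV file path.
#' @return \code{read_ratings} returns a validated data.frame.
#' @export
write_ratings <- function(ratings, path) {
  ratings <- validate_ratings(ratings)
  data.table::fwrite(ratings, path, sep = "\t")
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("ratings file not found: ", path)
  validate_ratings(as.data.frame(data.table::fread(path, data.table = FALSE,
    colClasses = list(character = c("subject_id", "modality", "condition")))))
}

#' Validate a ratings table
#'
#' Checks columns, the 0-10 NRS range, and uniqueness of
#' (subject, modality, condition, trial).
#'
#' @param ratings data.frame.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_ratings <- function(ratings) {
  need <- c("subject_id", "modality", "condition", "trial_index", "rating")
  miss <- setdiff(need, names(ratings))
  if (length(miss)) stop("ratings table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(ratings$rating)))
    stop("ratings must be finite")
  if (any(ratings$rating < 0 | ratings$rating > 10))
    stop("ratings must lie within the 0-10 NRS range")
  key <- paste(ratings$subject_id, ratings$modality, ratings$condition,
               ratings$trial_index)
  if (anyDuplicated(key))
    stop("duplicate (subject, modality, condition, trial) rows in ratings")
  as.data.frame(ratings)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every trial with a 4th-order Butterworth band-pass applied
#' forward and backward, so component latencies are not shifted. The
#' forward-backward (squared-magnitude) response of the bilinear-designed
#' Butterworth is evaluated in closed form from the prewarped analog
#' prototype and applied spectrally. This realises the zero-phase cascade
#' exactly: no recursive-filter rounding or start-up transients, linearity
#' to machine precision, and numerical stability even for narrow low bands
#' (the epoch is treated as circular, so the outermost few samples should
#' not be over-interpreted). The DC component is removed by the pass band.
#'
#' @param e an \code{epoch_set}.
#' @param lo,hi band edges in Hz; \code{0 < lo < hi < sfreq / 2}.
#' @param order filter order (default 4).
#' @return The filtered \code{epoch_set}.
#' @export
bandpass <- function(e, lo = 1, hi = 30, order = 4) {
  stopifnot(inherits(e, "epoch_set"))
  nyq <- e$sfreq / 2
  if (!(lo > 0 && lo < hi && hi < nyq))
    stop("invalid band: need 0 < lo < hi < sfreq/2 (Nyquist ", nyq, " Hz)")
  n <- ncol(e$data)
  freqs <- (0:(n - 1)) * e$sfreq / n
  freqs <- pmin(freqs, e$sfreq - freqs)      # fold to [0, Nyquist]
  # prewarped analog frequencies of the bilinear transform
  W <- tan(pi * freqs / e$sfreq)
  W1 <- tan(pi * lo / e$sfreq); W2 <- tan(pi * hi / e$sfreq)
  x <- ifelse(W > 0, (W^2 - W1 * W2) / (W * (W2 - W1)), Inf)
  mag2 <- 1 / (1 + x^(2 * order))            # |H|^2: forward + backward
  mag2[!is.finite(x)] <- 0
  spec <- stats::mvfft(t(e$data)) * mag2
  e$data <- t(Re(stats::mvfft(spec, inverse = TRUE)) / n)
  e
}

#' Read a BrainVision recording (adapter)
#'
#' Minimal read-only import of BrainVision (.vhdr/.eeg) continuous data for
#' one channel, supporting VECTORIZED/MULTIPLEXED ASCII and MULTIPLEXED
#' binary IEEE_FLOAT_32 / INT_16 data. Returned as a one-"trial" matrix to
#' be epoched by the caller; the documented plain-text store remains the
#' core format.
#'
#' @param vhdr path to the .vhdr header file.
#' @param channel channel name to extract.
#' @return list with \code{data} (numeric vector, microvolts), \code{sfreq},
#'   \code{channel}.
#' @export
read_brainvision <- function(vhdr, channel = "Cz") {
  if (!file.exists(vhdr)) stop("header file not found: ", vhdr)
  lines <- readLines(vhdr, warn = FALSE)
  getval <- function(key) {
    m <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(m)) stop("malformed .vhdr: missing ", key)
    sub(paste0("^", key, "="), "", m[1L])
  }
  datafile <- getval("DataFile")
  fmt <- toupper(getval("DataFormat"))
  orient <- toupper(getval("DataOrientation"))
  nchan <- as.integer(getval("NumberOfChannels"))
  sfreq <- 1e6 / as.numeric(getval("SamplingInterval"))
  chinfo <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", chinfo), ",")
  names_ch <- vapply(parts, `[`, "", 1L)
  res_ch <- vapply(parts, function(p)
    if (length(p) >= 3L && nzchar(p[3L])) as.numeric(p[3L]) else 1, 0)
  ci <- match(channel, names_ch)
  if (is.na(ci)) stop("channel '", channel, "' not in recording (",
                      paste(names_ch, collapse = ", "), ")")
  path <- file.path(dirname(vhdr), datafile)
  if (!file.exists(path)) stop("data file not found: ", path)
  if (fmt == "ASCII") {
    vals <- scan(path, quiet = TRUE)
    mat <- if (orient == "VECTORIZED")
      matrix(vals, nrow = nchan, byrow = TRUE)
    else matrix(vals, nrow = nchan)
    x <- mat[ci, ]
  } else {
    bintype <- toupper(getval("BinaryFormat"))
    sz <- if (bintype == "IEEE_FLOAT_32") 4L else 2L
    n <- file.size(path) / sz
    raw <- if (bintype == "IEEE_FLOAT_32")
      readBin(path, "double", n = n, size = 4L, endian = "little")
    else readBin(path, "integer", n = n, size = 2L, signed = TRUE,
                 endian = "little")
    if (orient != "MULTIPLEXED")
      stop("only MULTIPLEXED binary orientation is supported")
    x <- raw[seq(ci, length(raw), by = nchan)]
  }
  list(data = x * res_ch[ci], sfreq = sfreq, channel = channel)
}
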