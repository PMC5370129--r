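#' Write an EEG dataset as an EEGLAB .set file
#'
#' Serialises the dataset as a MAT v5 file holding the standard `EEG`
#' structure (setname, nbchan, trials, pnts, srate, xmin, xmax, the
#' `data` matrix in single precision, `chanlocs` with channel labels). The dataset's kind
#' tag, seed and scenario hash are embedded under `EEG.etc`. Output is
#' deterministic: identical datasets re-export byte-identically.
#'
#' @param ds An [eeg_dataset()].
#' @param path Output path (conventionally `.set`).
#' @param setname Dataset name stored in the file (default: the kind tag).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(ds, path, setname = NULL) {
  stopifnot(inherits(ds, "eeg_dataset"))
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop_assrmix(sprintf("Directory does not exist: %s", dirname(path)))
  n <- ncol(ds$data)
  eeg <- list(
    setname = setname %||% paste0("assrmix_", ds$kind),
    nbchan = nrow(ds$data),
    trials = 1,
    pnts = n,
    srate = ds$sampling_rate_hz,
    xmin = 0,
    xmax = (n - 1) / ds$sampling_rate_hz,
    data = ds$data,
    chanlocs = lapply(ds$labels, function(lb) list(labels = lb)),
    ref = "common",
    etc = list(
      kind = ds$kind,
      seed = as.numeric(ds$meta$seed %||% NA_real_),
      scenario_hash = as.character(ds$meta$scenario_hash %||% "")
    )
  )
  mat5_write(list(EEG = eeg), path, single_fields = "data")
  invisible(path)
}

#' Read an EEG recording
#'
#' Reads multichannel EEG from EEGLAB `.set` (MAT v5) or BrainVision
#' (`.vhdr` + `.eeg`, optional `.vmrk`) files into an [eeg_dataset()].
#'
#' @param path Path to the `.set` or `.vhdr` file.
#' @param format `"auto"` (by extension), `"eeglab_set"` or `"brainvision"`.
#' @return An [eeg_dataset()]; BrainVision markers, reference and ground
#'   metadata (when present) are carried in `$meta`.
#' @export
read_eeg <- function(path, format = c("auto", "eeglab_set", "brainvision")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.set$", path, ignore.case = TRUE)) "eeglab_set"
      else if (grepl("\\.vhdr$", path, ignore.case = TRUE)) "brainvision"
      else stop_assrmix("Cannot infer format; pass `format` explicitly.")
  }
  if (!file.exists(path)) stop_assrmix(sprintf("No such file: %s", path))
  switch(format,
    eeglab_set = read_eeglab_set(path),
    brainvision = read_brainvision(path)
  )
}

read_eeglab_set <- function(path) {
  vars <- mat5_read(path)
  eeg <- vars$EEG
  if (is.null(eeg)) stop_assrmix("No `EEG` structure found in .set file.")
  for (f in c("nbchan", "pnts", "srate", "data")) {
    if (is.null(eeg[[f]])) {
      stop_assrmix(sprintf(".set file missing required field `%s`.", f))
    }
  }
  data <- eeg$data
  if (!is.matrix(data)) data <- matrix(data, nrow = eeg$nbchan)
  if (nrow(data) != eeg$nbchan || ncol(data) != eeg$pnts) {
    stop_assrmix(sprintf(
      "`data` is %d x %d but header says nbchan=%d, pnts=%d.",
      nrow(data), ncol(data), eeg$nbchan, eeg$pnts))
  }
  labels <- if (!is.null(eeg$chanlocs)) {
    ch <- eeg$chanlocs
    if (!is.null(names(ch))) ch <- list(ch) # 1 x 1 struct
    vapply(ch, function(c1) as.character(c1$labels), character(1))
  } else {
    paste0("ch", seq_len(nrow(data)))
  }
  kind <- tryCatch(as.character(eeg$etc$kind), error = function(e) "raw")
  if (!length(kind) || !nzchar(kind)) kind <- "raw"
  meta <- list(setname = eeg$setname %||% "",
               seed = tryCatch(eeg$etc$seed, error = function(e) NULL),
               scenario_hash = tryCatch(eeg$etc$scenario_hash,
                                        error = function(e) NULL))
  eeg_dataset(data, eeg$srate, labels, kind, meta)
}

# safe lookup in a named character vector (NULL when absent)
bv_get <- function(v, key) {
  if (is.null(v) || !key %in% names(v)) NULL else unname(v[[key]])
}

# parse a BrainVision INI-style section file into a list of named sections
parse_bv_ini <- function(lines) {
  sections <- list()
  current <- NULL
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      current <- gsub("^\\[|\\]$", "", ln)
      sections[[current]] <- character(0)
    } else if (!is.null(current) && grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      sections[[current]][key] <- val
    }
  }
  sections
}

read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE, encoding = "latin1")
  ini <- parse_bv_ini(lines)
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) stop_assrmix("BrainVision header missing [Common Infos].")
  need <- c("DataFile", "NumberOfChannels", "SamplingInterval")
  for (f in need) {
    if (is.null(bv_get(ci, f))) {
      stop_assrmix(sprintf("BrainVision header missing field `%s`.", f))
    }
  }
  orientation <- bv_get(ci, "DataOrientation")
  if (!is.null(orientation) && toupper(orientation) != "MULTIPLEXED") {
    stop_assrmix("Only MULTIPLEXED BrainVision data orientation is supported.")
  }
  nch <- as.integer(bv_get(ci, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(bv_get(ci, "SamplingInterval")) # interval in us
  fmt <- toupper(bv_get(ini[["Binary Infos"]], "BinaryFormat") %||%
                   "IEEE_FLOAT_32")
  chan <- ini[["Channel Infos"]]
  labels <- paste0("ch", seq_len(nch))
  resolution <- rep(1, nch)
  if (!is.null(chan)) {
    for (i in seq_len(nch)) {
      entry <- bv_get(chan, paste0("Ch", i))
      if (!is.null(entry)) {
        parts <- strsplit(entry, ",")[[1]]
        labels[i] <- trimws(parts[1])
        if (length(parts) >= 3 && nzchar(trimws(parts[3]))) {
          resolution[i] <- as.numeric(parts[3])
        }
      }
    }
  }
  data_path <- file.path(dirname(vhdr_path), bv_get(ci, "DataFile"))
  if (!file.exists(data_path)) {
    stop_assrmix(sprintf("BrainVision data file not found: %s", data_path))
  }
  sz <- file.info(data_path)$size
  raw_n <- switch(fmt,
    IEEE_FLOAT_32 = sz / 4,
    INT_16 = sz / 2,
    stop_assrmix(sprintf("Unsupported BinaryFormat `%s`.", fmt))
  )
  if (raw_n %% nch != 0) {
    stop_assrmix(sprintf(
      "Binary size (%d values) is not a multiple of the channel count (%d).",
      raw_n, nch))
  }
  con <- file(data_path, "rb")
  on.exit(close(con))
  vals <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = raw_n, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = raw_n, size = 2, signed = TRUE,
            endian = "little")
  }
  data <- matrix(vals, nrow = nch) * resolution
  markers <- NULL
  mf <- bv_get(ci, "MarkerFile")
  if (!is.null(mf)) {
    mpath <- file.path(dirname(vhdr_path), mf)
    if (file.exists(mpath)) {
      mk <- parse_bv_ini(readLines(mpath, warn = FALSE, encoding = "latin1"))
      mi <- mk[["Marker Infos"]]
      if (!is.null(mi)) {
        markers <- purrr::map_dfr(mi, function(v) {
          p <- strsplit(v, ",")[[1]]
          tibble::tibble(type = p[1], description = p[2],
                         position = as.integer(p[3]))
        })
      }
    } else {
      rlang::warn("BrainVision marker file listed but not found; markers empty.")
    }
  }
  meta <- list(reference = bv_get(ci, "Reference"),
               ground = bv_get(ci, "Ground"), markers = markers)
  eeg_dataset(data, fs, make.unique(labels), "raw", meta)
}
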