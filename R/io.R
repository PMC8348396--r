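# Readers/writers for the formats the toolkit exchanges: signal CSV,
# annotation CSV, feature tables, WFDB records (native minimal reader:
# header + format 16/212 signals + MIT annotations), model JSON, and
# the YAML run configuration.

#' Write / read a signal CSV
#'
#' Two columns (\code{time_s}, \code{mv}) preceded by a comment header
#' carrying the sampling rate and lead, e.g. \code{# fs=250 lead=II}.
#'
#' @param sig an [ECGSignal-class].
#' @param path file path.
#' @return \code{writeSignalCSV}: \code{path} invisibly;
#'   \code{readSignalCSV}: an [ECGSignal-class] with
#'   \code{source = "csv"}.
#' @export
writeSignalCSV <- function(sig, path) {
  stopIfNot(is(sig, "ECGSignal"), "'sig' must be an ECGSignal")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g lead=%s", fs(sig), sig@leadId), con)
  utils::write.csv(
    data.frame(time_s = (seq_along(samples(sig)) - 1) / fs(sig),
               mv = samples(sig)),
    con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSignalCSV
#' @export
readSignalCSV <- function(path) {
  first <- readLines(path, n = 1)
  hasMeta <- startsWith(first, "#")
  df <- utils::read.csv(path, comment.char = "#")
  stopIfNot(all(c("time_s", "mv") %in% names(df)),
            "signal CSV needs columns time_s, mv")
  lead <- "II"
  if (hasMeta) {
    fsm <- regmatches(first, regexec("fs=([0-9.eE+-]+)", first))[[1]]
    lm <- regmatches(first, regexec("lead=(\\S+)", first))[[1]]
    f <- as.numeric(fsm[2])
    if (length(lm) == 2) lead <- lm[2]
  } else {
    f <- 1 / stats::median(diff(df$time_s))
  }
  ecgSignal(df$mv, f, leadId = lead, source = "csv")
}

#' Write / read a fiducial annotation CSV
#'
#' Long format with one row per fiducial: \code{sample_idx} (0-based),
#' \code{fiducial_type} (\code{R}, \code{QRS_on}, \code{P_peak},
#' \code{P_on}) and \code{beat_type}.
#'
#' @param bs a [BeatSet-class].
#' @param path file path.
#' @param fs,nSamples context needed to rebuild the [BeatSet-class]
#'   when reading.
#' @return \code{writeAnnotationsCSV}: \code{path} invisibly;
#'   \code{readAnnotationsCSV}: a [BeatSet-class].
#' @export
writeAnnotationsCSV <- function(bs, path) {
  stopIfNot(is(bs, "BeatSet"), "'bs' must be a BeatSet")
  b <- beats(bs)
  rows <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) {
    out <- data.frame(sample_idx = b$r_idx[i], fiducial_type = "R",
                      beat_type = b$beat_type[i], beat = i)
    add <- function(out, idx, ty)
      if (!is.na(idx)) rbind(out, data.frame(sample_idx = idx,
                                             fiducial_type = ty,
                                             beat_type = b$beat_type[i],
                                             beat = i)) else out
    out <- add(out, b$qrs_on_idx[i], "QRS_on")
    out <- add(out, b$p_peak_idx[i], "P_peak")
    add(out, b$p_on_idx[i], "P_on")
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotationsCSV
#' @export
readAnnotationsCSV <- function(path, fs, nSamples) {
  df <- utils::read.csv(path)
  beatsIdx <- sort(unique(df$beat))
  b <- do.call(rbind, lapply(beatsIdx, function(i) {
    sub <- df[df$beat == i, ]
    pick <- function(ty) {
      v <- sub$sample_idx[sub$fiducial_type == ty]
      if (length(v)) v[1] else NA_real_
    }
    data.frame(r_idx = pick("R"), qrs_on_idx = pick("QRS_on"),
               p_peak_idx = pick("P_peak"), p_on_idx = pick("P_on"),
               p_absent = is.na(pick("P_peak")),
               beat_type = sub$beat_type[1])
  }))
  beatSet(b, fs, nSamples)
}

#' Write / read a segment feature table CSV
#'
#' Fixed 15-column layout: the 14 features of [featureColumns()] plus
#' \code{label}.
#'
#' @param df feature data.frame ([segmentFeatures()] rows).
#' @param path file path.
#' @return \code{writeFeatures}: \code{path} invisibly;
#'   \code{readFeatures}: the data.frame.
#' @export
writeFeatures <- function(df, path) {
  cols <- c(featureColumns()$all, "label")
  stopIfNot(all(cols %in% names(df)),
            "feature table must carry the 14 features plus label")
  utils::write.csv(df[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopIfNot(all(featureColumns()$all %in% names(df)),
            "not a feature table CSV")
  df
}

#' Cut a record into fixed, non-overlapping analysis windows
#'
#' Windows are half-open \code{[start, start + L)} in samples, 0-based;
#' a trailing partial window is dropped. When a rhythm annotation table
#' is supplied each window is labeled via [labelSegmentAF()].
#'
#' @param sig an [ECGSignal-class].
#' @param ann optional rhythm annotation data.frame (columns
#'   \code{sample}, \code{rhythm}).
#' @param segLength window length in seconds (default 300, the 5-minute
#'   convention).
#' @return data.frame with \code{start_idx}, \code{end_idx} (half-open,
#'   0-based), \code{start_s} and, when \code{ann} is given,
#'   \code{label}.
#' @examples
#' sig <- generateECG(nsrSpec(seed = 1), 600, 100)$signal
#' nrow(segmentECG(sig, segLength = 300))   # 2
#' @export
segmentECG <- function(sig, ann = NULL, segLength = 300) {
  stopIfNot(is(sig, "ECGSignal"), "'sig' must be an ECGSignal")
  stopIfNot(segLength > 0, "'segLength' must be positive")
  L <- round(segLength * fs(sig))
  n <- length(samples(sig))
  k <- floor(n / L)
  if (k == 0L)
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      start_s = numeric()))
  out <- data.frame(start_idx = (seq_len(k) - 1L) * L,
                    end_idx = seq_len(k) * L,
                    start_s = (seq_len(k) - 1L) * L / fs(sig))
  if (!is.null(ann))
    out$label <- vapply(seq_len(k), function(i)
      labelSegmentAF(ann, out$start_idx[i], out$end_idx[i],
                     recordEnd = n), character(1))
  out
}

#' Segment-count arithmetic for a set of records
#'
#' @param recordSeconds vector of record durations in seconds.
#' @param segLength window length in seconds.
#' @return Total number of full non-overlapping windows.
#' @examples
#' countSegments(rep(10 * 3600, 21))    # 2520
#' countSegments(rep(30 * 60, 100))     # 600
#' @export
countSegments <- function(recordSeconds, segLength = 300) {
  sum(floor(recordSeconds / segLength))
}

#' Extract one window of a signal as an ECGSignal
#'
#' @param sig an [ECGSignal-class].
#' @param startIdx,endIdx half-open 0-based sample bounds.
#' @return An [ECGSignal-class].
#' @export
windowECG <- function(sig, startIdx, endIdx) {
  ecgSignal(samples(sig)[(startIdx + 1):endIdx], fs(sig), sig@leadId,
            sig@source)
}

## ---------------------------------------------------------------------
## WFDB (PhysioNet) records: native minimal reader/writer

parseWFDBHeader <- function(heaPath) {
  ln <- readLines(heaPath)
  ln <- ln[!startsWith(ln, "#") & nzchar(trimws(ln))]
  rec <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  nsig <- as.integer(rec[2])
  f <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  nsamp <- if (length(rec) >= 4) as.numeric(rec[4]) else NA_real_
  sigs <- lapply(seq_len(nsig), function(i) {
    tok <- strsplit(trimws(ln[1 + i]), "\\s+")[[1]]
    gainTok <- tok[3]
    units <- sub(".*/", "", gainTok)
    gainPart <- sub("/.*", "", gainTok)
    baseline <- if (grepl("\\(", gainPart))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gainPart)) else NA
    gain <- as.numeric(sub("\\(.*", "", gainPart))
    if (is.na(gain) || gain == 0) gain <- 200
    adcZero <- if (length(tok) >= 5) as.numeric(tok[5]) else 0
    if (is.na(baseline)) baseline <- adcZero
    list(file = tok[1], format = as.integer(sub("x.*|:.*|\\+.*", "", tok[2])),
         gain = gain, baseline = baseline,
         units = if (identical(units, gainPart)) "mV" else units)
  })
  list(record = rec[1], nsig = nsig, fs = f, nSamples = nsamp,
       signals = sigs)
}

#' Read a WFDB record (formats 16 and 212)
#'
#' Minimal native reader for PhysioNet-style records: parses the
#' \code{.hea} header, decodes the interleaved \code{.dat} samples
#' (16-bit little-endian or packed 12-bit "212"), and converts to
#' millivolts via \code{(adc - baseline) / gain}.
#'
#' @param record path to the record without extension (or the
#'   \code{.hea} file).
#' @param channel which signal to return (1-based; default the first).
#' @return An [ECGSignal-class] with \code{source = "wfdb"}.
#' @export
readWFDB <- function(record, channel = 1L) {
  record <- sub("\\.hea$", "", record)
  hdr <- parseWFDBHeader(paste0(record, ".hea"))
  stopIfNot(channel >= 1 && channel <= hdr$nsig, "channel out of range")
  datPath <- file.path(dirname(record), hdr$signals[[channel]]$file)
  raw <- readBin(datPath, "raw", file.info(datPath)$size)
  fmt <- hdr$signals[[channel]]$format
  if (fmt == 16) {
    vals <- readBin(raw, "integer", n = length(raw) / 2, size = 2,
                    endian = "little", signed = TRUE)
  } else if (fmt == 212) {
    b <- as.integer(raw)
    nTriple <- floor(length(b) / 3)
    b1 <- b[seq(1, by = 3, length.out = nTriple)]
    b2 <- b[seq(2, by = 3, length.out = nTriple)]
    b3 <- b[seq(3, by = 3, length.out = nTriple)]
    s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0F), 8)
    s2 <- b3 + bitwShiftL(bitwAnd(bitwShiftR(b2, 4), 0x0F), 8)
    tw <- function(v) ifelse(v > 2047, v - 4096, v)   # 12-bit two's compl.
    vals <- as.numeric(rbind(tw(s1), tw(s2)))
  } else stop("unsupported WFDB format: ", fmt, call. = FALSE)
  # de-interleave channels
  ch <- vals[seq(channel, length(vals), by = hdr$nsig)]
  if (!is.na(hdr$nSamples)) ch <- ch[seq_len(min(length(ch), hdr$nSamples))]
  sg <- hdr$signals[[channel]]
  ecgSignal((ch - sg$baseline) / sg$gain, hdr$fs,
            leadId = paste0("ch", channel), source = "wfdb")
}

#' Write an ECGSignal as a single-channel WFDB record (format 16)
#'
#' @param sig an [ECGSignal-class].
#' @param record output path without extension.
#' @param gain ADC units per millivolt.
#' @return \code{record}, invisibly.
#' @export
writeWFDB <- function(sig, record, gain = 200) {
  stopIfNot(is(sig, "ECGSignal"), "'sig' must be an ECGSignal")
  x <- round(samples(sig) * gain)
  stopIfNot(all(abs(x) < 32768), "signal exceeds 16-bit range at this gain")
  name <- basename(record)
  writeLines(c(sprintf("%s 1 %.10g %d", name, fs(sig), length(x)),
               sprintf("%s.dat 16 %g(0)/mV 16 0 %d %d 0 %s",
                       name, gain, x[1],
                       sum(x) %% 65536, sig@leadId)),
             paste0(record, ".hea"))
  writeBin(as.integer(x), paste0(record, ".dat"), size = 2,
           endian = "little")
  invisible(record)
}

## MIT annotation format: 2-byte words, code in the top 6 bits, time
## increment in the lower 10; SKIP (59) carries a 4-byte long interval,
## AUX (63) carries a string (padded to even length).

.annCodes <- c(NORMAL = 1L, PREMATURE = 8L, RHYTHM = 28L)

#' Read / write MIT-format WFDB annotations
#'
#' Supports the core of the format: annotation codes with 10-bit time
#' increments, SKIP pseudo-annotations for long intervals, and AUX
#' strings (used for rhythm labels such as \code{"(AFIB"} /
#' \code{"(N"}).
#'
#' @param path annotation file path (e.g. \code{record.atr}).
#' @param ann data.frame with columns \code{sample} (0-based,
#'   non-decreasing), \code{code} (integer annotation code) and
#'   optionally \code{aux} (string, \code{NA} for none).
#' @return \code{readWFDBAnnotations}: data.frame with \code{sample},
#'   \code{code}, \code{aux} and \code{rhythm} (the aux string of
#'   rhythm annotations, \code{NA} elsewhere);
#'   \code{writeWFDBAnnotations}: \code{path} invisibly.
#' @export
readWFDBAnnotations <- function(path) {
  raw <- as.integer(readBin(path, "raw", file.info(path)$size))
  i <- 1L
  tCur <- 0
  out <- list()
  while (i + 1L <= length(raw)) {
    w <- raw[i] + 256L * raw[i + 1L]
    i <- i + 2L
    code <- bitwShiftR(w, 10)
    delta <- bitwAnd(w, 1023L)
    if (code == 0L && delta == 0L) break
    if (code == 59L && delta == 0L) {          # SKIP: 4-byte interval
      hi <- raw[i] + 256L * raw[i + 1L]
      lo <- raw[i + 2L] + 256L * raw[i + 3L]
      i <- i + 4L
      iv <- hi * 65536 + lo
      if (iv > 2^31) iv <- iv - 2^32
      tCur <- tCur + iv
    } else if (code == 63L) {                  # AUX attached to previous
      nBytes <- delta
      chars <- raw[seq(i, length.out = nBytes)]
      i <- i + nBytes + (nBytes %% 2L)
      s <- rawToChar(as.raw(chars[chars != 0L]))
      if (length(out)) out[[length(out)]]$aux <- s
    } else if (code %in% c(60L, 61L, 62L)) {   # NUM/SUB/CHN: ignore
    } else {
      tCur <- tCur + delta
      out[[length(out) + 1L]] <- list(sample = tCur, code = code,
                                      aux = NA_character_)
    }
  }
  df <- do.call(rbind, lapply(out, function(a)
    data.frame(sample = a$sample, code = a$code, aux = a$aux)))
  if (is.null(df))
    df <- data.frame(sample = numeric(), code = integer(),
                     aux = character())
  df$rhythm <- ifelse(df$code == .annCodes[["RHYTHM"]], df$aux,
                      NA_character_)
  df
}

#' @rdname readWFDBAnnotations
#' @export
writeWFDBAnnotations <- function(ann, path) {
  stopIfNot(all(diff(ann$sample) >= 0), "samples must be non-decreasing")
  con <- file(path, "wb")
  on.exit(close(con))
  word <- function(w) writeBin(as.integer(c(w %% 256, w %/% 256)), con,
                               size = 1)
  tPrev <- 0
  for (i in seq_len(nrow(ann))) {
    delta <- ann$sample[i] - tPrev
    if (delta > 1023) {
      word(bitwShiftL(59L, 10))                # SKIP
      word(delta %/% 65536)
      word(delta %% 65536)
      delta <- 0
    }
    word(bitwShiftL(as.integer(ann$code[i]), 10) + delta)
    aux <- if ("aux" %in% names(ann)) ann$aux[i] else NA
    if (!is.na(aux)) {
      bytes <- utf8ToInt(aux)
      if (length(bytes) %% 2L == 1L) bytes <- c(bytes, 0L)
      word(bitwShiftL(63L, 10) + length(bytes))
      writeBin(as.integer(bytes), con, size = 1)
    }
    tPrev <- ann$sample[i]
  }
  word(0L)
  invisible(path)
}

## ---------------------------------------------------------------------
## Model serialization (JSON)

svmFitToList <- function(m) {
  list(type = "SVMFit",
       support_vectors = lapply(seq_len(nrow(m@supportVectors)),
                                function(i) as.numeric(m@supportVectors[i, ])),
       dual_coefs = m@dualCoefs, bias = m@bias, gamma = m@gamma,
       cost = m@cost,
       scaler = list(center = as.list(m@scaler$center),
                     spread = as.list(m@scaler$spread),
                     features = m@scaler$features),
       classes = m@classes, features = m@features)
}

svmFitFromList <- function(l) {
  sv <- do.call(rbind, lapply(l$support_vectors, unlist))
  new("SVMFit", supportVectors = sv,
      dualCoefs = unlist(l$dual_coefs), bias = unlist(l$bias),
      gamma = unlist(l$gamma), cost = unlist(l$cost),
      scaler = list(center = unlist(l$scaler$center),
                    spread = unlist(l$scaler$spread),
                    features = unlist(l$scaler$features)),
      classes = unlist(l$classes), features = unlist(l$features))
}

#' Serialize / restore fitted models as JSON
#'
#' Stores an [SVMFit-class] or [HybridModel-class] (support vectors,
#' dual coefficients, bias, kernel parameters, scaler and class order)
#' in a portable JSON file.
#'
#' @param model an [SVMFit-class] or [HybridModel-class].
#' @param path JSON file path.
#' @return \code{writeModelJSON}: \code{path} invisibly;
#'   \code{readModelJSON}: the restored model object.
#' @export
writeModelJSON <- function(model, path) {
  l <- if (is(model, "HybridModel"))
    list(type = "HybridModel",
         diagnosis = svmFitToList(model@diagnosis),
         prediction = svmFitToList(model@prediction),
         impute_means = as.list(model@imputeMeans))
  else if (is(model, "SVMFit")) svmFitToList(model)
  else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  l <- jsonlite::read_json(path)
  if (identical(l$type, "HybridModel"))
    new("HybridModel", diagnosis = svmFitFromList(l$diagnosis),
        prediction = svmFitFromList(l$prediction),
        imputeMeans = unlist(l$impute_means))
  else svmFitFromList(l)
}

## ---------------------------------------------------------------------
## Run configuration (YAML)

#' Load and validate the run configuration
#'
#' Reads the YAML configuration shipped at
#' \code{system.file("extdata", "default-config.yaml", package =
#' "afwaterfall")}, overlays user overrides, and validates every block
#' against its module's preconditions.
#'
#' @param path optional user YAML whose values override the defaults.
#' @param overrides optional named list applied last (CLI flags).
#' @return A validated nested list of configuration blocks.
#' @export
readRunConfig <- function(path = NULL, overrides = NULL) {
  cfg <- yaml::read_yaml(system.file("extdata", "default-config.yaml",
                                     package = "afwaterfall"))
  if (!is.null(path))
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  if (!is.null(overrides))
    cfg <- utils::modifyList(cfg, overrides)
  stopIfNot(cfg$segment_length > 0, "segment_length must be positive")
  stopIfNot(cfg$fs >= 100, "fs must be at least 100 Hz")
  stopIfNot(cfg$filter$highpass > 0 &&
              cfg$filter$lowpass > cfg$filter$highpass &&
              cfg$filter$lowpass < cfg$fs / 2,
            "need 0 < highpass < lowpass < fs/2")
  stopIfNot(cfg$detector$refractory > 0 &&
              cfg$detector$searchback_factor > 1,
            "invalid detector block")
  stopIfNot(cfg$optimizer$particles >= 2 &&
              cfg$optimizer$iterations >= 1,
            "invalid optimizer block")
  stopIfNot(cfg$digitizer$gamma > 0, "digitizer gamma must be positive")
  cfg
}
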