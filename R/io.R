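#' Read and write ECG records
#'
#' Two on-disk formats are supported.
#'
#' **CSV**: a two-column table (`time_s`, `mv`) preceded by a comment line
#' `# fs=<Hz> subject=<id> condition=<label>` carrying the metadata; R-peak
#' annotations, when present, go to a sidecar `<path>.ann.csv` with a
#' single `r_sample` column. A CSV without the `fs` metadata line is
#' rejected.
#'
#' **WFDB**: a compact reader/writer for WFDB-style records — a text
#' header (`.hea`), a format-16 (16-bit little-endian) signal file
#' (`.dat`, samples quantized at `gain` units per mV), and, when
#' annotations are present, an MIT-format annotation file (`.atr`) of beat
#' ("N") annotations. `path` is the record name without extension.
#'
#' @param record an [ecg_record].
#' @param path file path (for WFDB: the record name, no extension).
#' @param format `"csv"` or `"wfdb"`.
#' @param gain WFDB quantization, integer units per mV (default 4000, i.e.
#'   0.25 microvolt resolution, range about +/- 8 mV).
#' @return `write_record` returns `path` invisibly; `read_record` returns
#'   an [ecg_record].
#' @export
write_record <- function(record, path, format = c("csv", "wfdb"),
                         gain = 4000) {
  format <- match.arg(format)
  if (format == "csv") write_record_csv(record, path)
  else write_record_wfdb(record, path, gain)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") read_record_csv(path) else read_record_wfdb(path)
}

write_record_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g subject=%s condition=%s", record$fs,
                     record$subject_id, record$condition), con)
  tt <- (seq_along(record$samples) - 1) / record$fs
  utils::write.csv(data.frame(time_s = tt, mv = record$samples), con,
                   row.names = FALSE)
  if (!is.null(record$annotations))
    utils::write.csv(data.frame(r_sample = record$annotations),
                     paste0(path, ".ann.csv"), row.names = FALSE)
}

read_record_csv <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*fs=([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2L)
    stop(sprintf("%s: missing '# fs=' metadata line", path), call. = FALSE)
  fs <- as.numeric(m[2])
  subj <- sub(".*subject=(\\S+).*", "\\1", first)
  cond <- sub(".*condition=(\\S+).*", "\\1", first)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "mv") %in% names(df)))
    stop(sprintf("%s: expected columns time_s, mv", path), call. = FALSE)
  ann <- NULL
  ann_path <- paste0(path, ".ann.csv")
  if (file.exists(ann_path)) ann <- utils::read.csv(ann_path)$r_sample
  ecg_record(df$mv, fs, subject_id = subj, condition = cond,
             annotations = ann)
}

write_record_wfdb <- function(record, path, gain = 4000) {
  base <- basename(path)
  n <- length(record$samples)
  dig <- as.integer(round(record$samples * gain))
  if (any(abs(dig) > 32767))
    stop("signal exceeds the 16-bit range at this gain; lower `gain`",
         call. = FALSE)
  writeLines(c(
    sprintf("%s 1 %.10g %d", base, record$fs, n),
    sprintf("%s.dat 16 %d/mV 16 0 %d 0 0 ECG", base, as.integer(gain),
            dig[1]),
    sprintf("# subject=%s condition=%s", record$subject_id,
            record$condition)
  ), paste0(path, ".hea"))
  writeBin(dig, paste0(path, ".dat"), size = 2L, endian = "little")
  if (!is.null(record$annotations))
    write_wfdb_annotations(record$annotations, paste0(path, ".atr"))
}

read_record_wfdb <- function(path) {
  hea <- readLines(paste0(path, ".hea"))
  top <- strsplit(hea[1], "\\s+")[[1]]
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  sig <- strsplit(hea[2], "\\s+")[[1]]
  gain <- as.numeric(sub("/mV$", "", sig[3]))
  subj <- NA_character_; cond <- NA_character_
  meta <- grep("^# subject=", hea, value = TRUE)
  if (length(meta)) {
    subj <- sub(".*subject=(\\S+).*", "\\1", meta[1])
    cond <- sub(".*condition=(\\S+).*", "\\1", meta[1])
  }
  dig <- readBin(paste0(path, ".dat"), integer(), n = n, size = 2L,
                 endian = "little")
  ann <- NULL
  if (file.exists(paste0(path, ".atr")))
    ann <- read_wfdb_annotations(paste0(path, ".atr"))
  ecg_record(dig / gain, fs, subject_id = subj, condition = cond,
             annotations = ann)
}

# MIT annotation format: 2-byte words, little-endian; annotation type in
# the high 6 bits, inter-annotation interval in the low 10 bits. Intervals
# above 1023 use the SKIP pseudo-annotation (59) followed by a 4-byte
# interval (high word first, each word little-endian). Beat annotations are
# written as type N (1); the stream ends with a zero word.
write_wfdb_annotations <- function(indices, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  # WFDB annotation times are 0-based sample numbers
  times <- as.integer(indices) - 1L
  prev <- 0L
  for (t in times) {
    iv <- t - prev
    if (iv > 1023L) {
      writeBin(as.integer(59L * 1024L), con, size = 2L, endian = "little")
      writeBin(c(iv %/% 65536L, iv %% 65536L), con, size = 2L,
               endian = "little")
      writeBin(as.integer(1L * 1024L), con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(1L * 1024L + iv), con, size = 2L,
               endian = "little")
    }
    prev <- t
  }
  writeBin(0L, con, size = 2L, endian = "little")
}

read_wfdb_annotations <- function(path) {
  raw <- readBin(path, integer(), n = file.size(path) %/% 2L, size = 2L,
                 signed = FALSE, endian = "little")
  times <- integer(0)
  cur <- 0L
  i <- 1L
  while (i <= length(raw)) {
    w <- raw[i]
    if (w == 0L) break
    code <- w %/% 1024L
    iv <- w %% 1024L
    if (code == 59L) {
      cur <- cur + raw[i + 1L] * 65536L + raw[i + 2L]
      i <- i + 3L
      next
    }
    cur <- cur + iv
    if (code == 1L) times <- c(times, cur)
    i <- i + 1L
  }
  times + 1L # back to 1-based indices
}
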