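## PTB-dialect WFDB input/output.
##
## Covers the subset of the WFDB format the PTB diagnostic ECG database
## uses: a text header (<record>.hea) plus one 16-bit little-endian signal
## file (<record>.dat, format 16, samples interleaved across signals), at
## gain 2000 ADU/mV, i.e. 0.5 microvolt per LSB. Frank leads (vx, vy, vz)
## are read past and dropped. Multi-segment records and other storage
## formats are out of scope.

ADU_PER_UV <- 2         # gain 2000 ADU/mV = 2 ADU per microvolt
UV_MAX <- 16383.5       # +32767 ADU; 16-bit two's complement upper edge
UV_MIN <- -16384        # -32768 ADU

## Localization synonym table. Keys are normalized (lower case, hyphens and
## spaces removed) header localization strings; anything absent is excluded,
## never guessed.
LOCALIZATION_MAP <- c(
  "anterior"       = "AMI",
  "anteroseptal"   = "ASMI",
  "anterolateral"  = "ALMI",
  "inferior"       = "IMI",
  "inferolateral"  = "ILMI")

normalize_diag <- function(x) gsub("[-_ ]", "", tolower(trimws(x)))

#' Map header diagnosis text to a study class
#'
#' Total, deterministic and case-insensitive mapping from the header's
#' reason-for-admission / localization text to one of the six study classes.
#' `"healthy control"` maps to HC; MI localizations map through an explicit
#' synonym table (anterior = AMI, antero-septal = ASMI, antero-lateral =
#' ALMI, inferior = IMI, infero-lateral = ILMI). Every other string —
#' including compound localizations such as "infero-postero-lateral" —
#' yields `"excluded"`, with the raw text retained as an attribute for audit.
#'
#' @param header_text Character vector of header comment lines (or a single
#'   string).
#' @return A class label or `"excluded"` (attribute `raw` carries the
#'   original diagnosis text).
#' @export
classify_header <- function(header_text) {
  txt <- paste(header_text, collapse = "\n")
  lines <- strsplit(txt, "\n")[[1]]
  reason <- sub(".*reason for admission:", "",
                grep("reason for admission", tolower(lines), value = TRUE))
  loc <- sub(".*\\(localization\\):", "",
             grep("localization", tolower(lines), value = TRUE))
  raw <- trimws(paste(c(reason, loc), collapse = " / "))
  label <- "excluded"
  if (length(reason) && normalize_diag(reason[1]) == "healthycontrol") {
    label <- "HC"
  } else if (length(loc)) {
    key <- normalize_diag(loc[1])
    if (key %in% names(LOCALIZATION_MAP)) label <- unname(LOCALIZATION_MAP[key])
  }
  structure(label, raw = raw)
}

#' Write a record as a WFDB (PTB dialect) header/signal pair
#'
#' Stores the 12 leads as format 16 (16-bit two's complement, little-endian,
#' interleaved) at 0.5 microvolt per LSB. Values must already lie within the
#' representable range \[-16384, +16383.5\] microvolt; out-of-range values
#' are rejected so clipping stays an explicit upstream decision.
#'
#' @param record An `ecg_record`.
#' @param path Path prefix (without extension); `.hea` and `.dat` are added.
#' @return Invisibly, the two file paths.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  sig <- record$signals
  if (nrow(sig) != 12) stop_ecgmi("record must have exactly 12 leads")
  if (any(sig > UV_MAX) || any(sig < UV_MIN))
    stop_ecgmi("signal outside the representable range [%g, %g] microvolt", UV_MIN, UV_MAX)
  adu <- matrix(as.integer(round(sig * ADU_PER_UV)), nrow = 12)
  n <- ncol(adu)
  rec_name <- basename(path)
  hea <- c(sprintf("%s 12 %g %d", rec_name, record$fs, n),
           sprintf("%s.dat 16 2000/mV 16 0 %d %d 0 %s",
                   rec_name, adu[, 1], 0L, record$lead_names),
           sprintf("# patient id: %s", record$patient_id),
           header_diagnosis_lines(record$class_label))
  if (length(record$r_peaks))
    hea <- c(hea, sprintf("# r peaks: %s", paste(record$r_peaks, collapse = " ")))
  writeLines(hea, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(adu), con, size = 2, endian = "little")  # column-major = interleaved
  invisible(c(paste0(path, ".hea"), paste0(path, ".dat")))
}

header_diagnosis_lines <- function(class_label) {
  if (identical(class_label, "HC"))
    return("# Reason for admission: Healthy control")
  loc <- c(AMI = "anterior", ASMI = "antero-septal", ALMI = "antero-lateral",
           IMI = "inferior", ILMI = "infero-lateral")[class_label]
  if (is.na(loc)) return(sprintf("# Reason for admission: %s", class_label))
  c("# Reason for admission: Myocardial infarction",
    sprintf("# Acute infarction (localization): %s", loc))
}

#' Read a WFDB (PTB dialect) record
#'
#' Parses the header, reads the 16-bit signal file, converts to microvolt at
#' the header-declared gain, drops Frank leads if present, and classifies
#' the header diagnosis text. All 12 standard leads must be present.
#'
#' @param path Path prefix (without extension) of the `.hea`/`.dat` pair.
#' @return An `ecg_record`.
#' @export
read_record <- function(path) {
  hea_path <- paste0(path, ".hea")
  dat_dir <- dirname(path)
  if (!file.exists(hea_path)) stop_ecgmi("header file not found: %s", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); n <- as.integer(top[4])
  if (is.na(nsig) || is.na(fs) || is.na(n)) stop_ecgmi("malformed header line: %s", lines[1])
  sig_lines <- lines[2:(1 + nsig)]
  comments <- grep("^#", lines, value = TRUE)
  fields <- lapply(sig_lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  fmt <- vapply(fields, `[`, "", 2)
  if (any(fmt != "16")) stop_ecgmi("unsupported signal format(s): %s",
                                   paste(unique(fmt[fmt != "16"]), collapse = ", "))
  gain <- vapply(fields, function(f) as.numeric(sub("/mV.*", "", f[3])), 0)
  if (any(is.na(gain) | gain <= 0)) stop_ecgmi("bad gain specification in header")
  dat_file <- vapply(fields, `[`, "", 1)
  if (length(unique(dat_file)) != 1)
    stop_ecgmi("multi-file records are not supported")
  desc <- vapply(fields, function(f) f[length(f)], "")
  con <- file(file.path(dat_dir, dat_file[1]), "rb")
  on.exit(close(con))
  adu <- readBin(con, integer(), n = nsig * n, size = 2, endian = "little", signed = TRUE)
  adu <- matrix(adu, nrow = nsig)             # interleaved -> signals in rows
  norm_desc <- ifelse(toupper(desc) %in% toupper(ECG_LEADS),
                      ECG_LEADS[match(toupper(desc), toupper(ECG_LEADS))], desc)
  keep <- match(ECG_LEADS, norm_desc)
  if (anyNA(keep))
    stop_ecgmi("missing standard lead(s): %s", paste(ECG_LEADS[is.na(keep)], collapse = ", "))
  sig <- adu[keep, , drop = FALSE] / (gain[keep] / 1000)   # ADU -> microvolt
  rownames(sig) <- ECG_LEADS
  label <- classify_header(comments)
  pid_line <- grep("# patient id:", comments, value = TRUE)
  pid <- if (length(pid_line)) trimws(sub(".*patient id:", "", pid_line[1]))
         else basename(dirname(path))
  r_line <- grep("# r peaks:", comments, value = TRUE)
  r_peaks <- if (length(r_line))
    as.integer(strsplit(trimws(sub(".*r peaks:", "", r_line[1])), "\\s+")[[1]])
  else integer(0)
  structure(list(patient_id = pid, record_id = basename(path),
                 signals = sig, fs = fs, lead_names = ECG_LEADS,
                 class_label = as.character(label), r_peaks = r_peaks,
                 diagnosis_raw = attr(label, "raw")), class = "ecg_record")
}

#' Write a cohort to a directory
#'
#' Writes every record as a WFDB pair plus a `manifest.csv` with columns
#' patient_id, record_id, class.
#'
#' @param cohort Output of [generate_cohort()] (list of records + manifest).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in cohort$records) write_record(r, file.path(dir, r$record_id))
  man <- cohort$manifest[, c("patient_id", "record_id", "class")]
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}
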