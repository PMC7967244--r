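#' @keywords internal
#' @useDynLib ecgmi, .registration = TRUE
"_PACKAGE"

## Standard 12-lead order used everywhere in the package.
ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

## Diagnostic classes: healthy control plus the five MI territories.
ECG_CLASSES <- c("HC", "ALMI", "AMI", "ASMI", "ILMI", "IMI")

#' Standard lead and class labels
#'
#' `ecg_leads()` returns the fixed 12-lead order (I, II, III, aVR, aVL, aVF,
#' V1-V6) used by every signal matrix in the package; `ecg_classes()` returns
#' the six diagnostic classes: healthy control (HC) and the five myocardial
#' infarction territories (ALMI, AMI, ASMI, ILMI, IMI).
#'
#' @return A character vector.
#' @export
ecg_leads <- function() ECG_LEADS

#' @rdname ecg_leads
#' @export
ecg_classes <- function() ECG_CLASSES

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards. Keeps every seeded operation pure.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a master seed and a stream label, staying within
## the 32-bit signed integer range.
derive_seed <- function(seed, ...) {
  parts <- c(as.integer(seed), vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.integer(p)
  }, integer(1)))
  s <- 0
  for (p in parts) s <- (s * 69069 + as.double(p)) %% 2147483647
  as.integer(s)
}

stop_ecgmi <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
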