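## ICD-10 F-code grouping into HiTOP internalizing / externalizing spectra.
##
## Patterns are either single codes ("F41", "F50.1") or stem ranges
## ("F10-F25", expanded to every 3-character stem in the inclusive range).
## A code inherits the spectrum of the longest pattern that prefixes it, so
## the most specific claim wins: F60.31 is internalizing even though F60.3
## is externalizing. Note the externalizing range F10-F25 includes the
## psychotic-disorder stems F20-F25, as grouped here.

HITOP_INTERNALIZING <- c("F32-F34", "F38", "F41", "F43", "F40-F42",
                         "F50.1", "F50.3", "F51", "F60.31",
                         "F93.3", "F93.8", "F93")
HITOP_EXTERNALIZING <- c("F10-F25", "F60.2", "F60.3", "F60.4", "F60.81",
                         "F60.0", "F63.2", "F90-F92", "F94")

## expand "F10-F25" to c("F10", ..., "F25"); single patterns pass through
expand_patterns <- function(patterns) {
  out <- lapply(patterns, function(p) {
    p <- toupper(gsub("\\s", "", p))
    if (grepl("^F\\d{2}[-–]F\\d{2}$", p)) {
      nums <- as.integer(regmatches(p, gregexpr("\\d{2}", p))[[1]])
      if (nums[1] > nums[2]) stop("invalid code range: ", p, call. = FALSE)
      sprintf("F%02d", nums[1]:nums[2])
    } else if (grepl("^F\\d{2}(\\.\\d+)?$", p)) {
      p
    } else {
      stop("unparseable ICD-10 pattern: ", p, call. = FALSE)
    }
  })
  unique(unlist(out))
}

#' HiTOP spectrum mapping for ICD-10 F-codes
#'
#' @param internalizing,externalizing character vectors of ICD-10 code
#'   patterns (single codes or `Fxx-Fyy` stem ranges). Defaults are the
#'   internalizing / externalizing groupings used by this pipeline.
#' @return object of class `hitop_map` holding the expanded pattern sets.
#' @export
hitop_map <- function(internalizing = HITOP_INTERNALIZING,
                      externalizing = HITOP_EXTERNALIZING) {
  structure(list(internalizing = expand_patterns(internalizing),
                 externalizing = expand_patterns(externalizing)),
            class = "hitop_map")
}

#' Read a HiTOP code map from a YAML config file
#'
#' @param path YAML file with keys `internalizing` and `externalizing`.
#' @return a [hitop_map()].
#' @export
read_hitop_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  hitop_map(internalizing = unlist(cfg$internalizing),
            externalizing = unlist(cfg$externalizing))
}

## spectrum of one code: "internalizing", "externalizing", or NA
classify_code <- function(code, map) {
  code <- toupper(gsub("\\s", "", code))
  if (!grepl("^F\\d{2}(\\.\\d+)?$", code)) return(NA_character_)
  matches_of <- function(patterns) {
    hit <- patterns[vapply(patterns, function(p) {
      code == p || startsWith(code, paste0(p, ".")) ||
        (nchar(p) > 4 && startsWith(code, p))
    }, logical(1))]
    if (length(hit) == 0) return(-1L)
    max(nchar(hit))
  }
  li <- matches_of(map$internalizing)
  le <- matches_of(map$externalizing)
  if (li < 0 && le < 0) return(NA_character_)
  ## longest (most specific) pattern wins; equal length -> both spectra claim
  ## the code, resolved deterministically in favor of internalizing
  if (li >= le) "internalizing" else "externalizing"
}

#' Map a subject's ICD-10 diagnosis codes to HiTOP indicators
#'
#' @param codes character vector of ICD-10 F-codes (possibly empty).
#'   Unparseable codes are dropped with a warning.
#' @param map a [hitop_map()].
#' @return named integer vector `dx_any`, `dx_internalizing`,
#'   `dx_externalizing` (1 = at least one current diagnosis in the spectrum;
#'   `dx_any` = at least one diagnosis of either spectrum).
#' @export
map_diagnoses <- function(codes, map = hitop_map()) {
  codes <- codes[!is.na(codes) & nzchar(codes)]
  if (length(codes) > 0) {
    ok <- grepl("^F\\d{2}(\\.\\d+)?$", toupper(gsub("\\s", "", codes)))
    if (any(!ok)) {
      warning("dropping unparseable ICD-10 code(s): ",
              paste(codes[!ok], collapse = ", "), call. = FALSE)
      codes <- codes[ok]
    }
  }
  spectra <- vapply(codes, classify_code, character(1), map = map)
  dx_int <- as.integer(any(spectra == "internalizing", na.rm = TRUE))
  dx_ext <- as.integer(any(spectra == "externalizing", na.rm = TRUE))
  c(dx_any = as.integer(dx_int == 1L || dx_ext == 1L),
    dx_internalizing = dx_int, dx_externalizing = dx_ext)
}
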