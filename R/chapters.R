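# ICD-10 code syntax and WHO chapter structure.
#
# Codes are stored undotted and uppercase: one letter, one digit, then one to
# five alphanumerics (length 3-7). Chapters follow the WHO layout for
# ICD-10-CM: 21 disease chapters plus the U00-U99 emergency-use block.

# Chapter lookup keyed on the leading 3-character category. Ranges are
# lexicographic on the category string, which is valid because categories are
# fixed-width [A-Z][0-9][0-9A-Z].
.chapter_table <- data.frame(
  abbrev = c("INF", "NEO", "BLD", "END", "MBD", "NVS", "EYE", "EAR", "CIR",
             "RSP", "DIG", "SKN", "MSK", "GEN", "PRG", "PNL", "MAL", "SYM",
             "INJ", "SPL", "EXT", "FAC"),
  lo = c("A00", "C00", "D50", "E00", "F01", "G00", "H00", "H60", "I00",
         "J00", "K00", "L00", "M00", "N00", "O00", "P00", "Q00", "R00",
         "S00", "U00", "V00", "Z00"),
  hi = c("B99", "D49", "D89", "E89", "F99", "G99", "H59", "H95", "I99",
         "J99", "K99", "L99", "M99", "N99", "O9A", "P96", "Q99", "R99",
         "T88", "U99", "Y99", "Z99"),
  label = c(
    "Certain infectious and parasitic diseases",
    "Neoplasms",
    "Diseases of the blood and blood-forming organs and certain disorders involving the immune mechanism",
    "Endocrine, nutritional, and metabolic diseases",
    "Mental, behavioral, and neurodevelopmental disorders",
    "Diseases of the nervous system",
    "Diseases of the eye and adnexa",
    "Diseases of the ear and mastoid process",
    "Diseases of the circulatory system",
    "Diseases of the respiratory system",
    "Diseases of the digestive system",
    "Diseases of the skin and subcutaneous tissue",
    "Diseases of the musculoskeletal system and connective tissue",
    "Diseases of the genitourinary system",
    "Pregnancy, childbirth, and the puerperium",
    "Certain conditions originating in the perinatal period",
    "Congenital malformations, deformations, and chromosomal abnormalities",
    "Symptoms, signs, and abnormal clinical and laboratory findings, not elsewhere classified",
    "Injury, poisoning, and certain other consequences of external causes",
    "Emergency code additions",
    "External causes of morbidity",
    "Factors influencing health status and contact with health services"
  ),
  stringsAsFactors = FALSE
)

#' Chapter labels used by the package
#'
#' @return A data.frame with one row per chapter: `abbrev`, the leading
#'   3-character category range (`lo`, `hi`) and the full `label`. The
#'   "cross-cutting" pseudo-chapter used for items that span chapters is not
#'   listed; it is accepted anywhere a chapter label is.
#' @export
chapter_table <- function() .chapter_table

#' Normalize diagnosis code spellings
#'
#' Uppercases, removes dots, and validates syntax. Both dotted ("I21.4") and
#' undotted ("I214") spellings are accepted; the canonical form is undotted.
#'
#' @param code character vector of diagnosis codes.
#' @param error if `TRUE` (default), invalid codes raise an error naming the
#'   offenders; if `FALSE`, invalid entries are returned as `NA`.
#' @return Character vector of canonical codes.
#' @export
normalize_icd <- function(code, error = TRUE) {
  x <- toupper(gsub(".", "", as.character(code), fixed = TRUE))
  ok <- grepl("^[A-Z][0-9][0-9A-Z]{1,5}$", x)
  if (any(!ok)) {
    if (error) {
      bad <- unique(code[!ok])
      stop("invalid diagnosis code(s): ", paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L) else "")
    }
    x[!ok] <- NA_character_
  }
  x
}

#' Derive the WHO chapter of a diagnosis code
#'
#' The chapter is determined by the code's leading 3-character category range
#' (e.g. codes in A00-B99 belong to the infectious-disease chapter, U-codes
#' to the emergency-use block).
#'
#' @param code character vector of (possibly dotted) diagnosis codes.
#' @return Character vector of chapter abbreviations (see [chapter_table()]).
#' @export
icd_chapter <- function(code) {
  x <- normalize_icd(code)
  cat3 <- substr(x, 1L, 3L)
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(.chapter_table))) {
    sel <- is.na(out) & cat3 >= .chapter_table$lo[i] & cat3 <= .chapter_table$hi[i]
    out[sel] <- .chapter_table$abbrev[i]
  }
  # F00, H96-H99, T89-T99 etc. fall between published ranges; attach them to
  # the chapter of their letter block so every syntactically valid code has a
  # chapter.
  if (anyNA(out)) {
    first <- substr(x[is.na(out)], 1L, 1L)
    fallback <- c(F = "MBD", H = "EAR", T = "INJ", E = "END", D = "BLD",
                  O = "PRG", P = "PNL", B = "INF", C = "NEO", W = "EXT",
                  X = "EXT", Y = "EXT")
    out[is.na(out)] <- unname(fallback[first])
  }
  out
}

.valid_chapters <- function() c(.chapter_table$abbrev, "cross-cutting")
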