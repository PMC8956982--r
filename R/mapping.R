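# Multi-membership diagnosis mapping tables.
#
# A mapping table relates diagnosis codes to diagnostic items of three kinds:
#   main     - binary main-effect items; a code may carry up to 4, and items
#              may overlap (broad supersets alongside narrow subsets);
#   modifier - cross-cutting binary modifiers (severity, laterality, ...);
#   scale    - numeric scaled variables (e.g. BMI bands), where the code
#              itself encodes the value.
# Comparator systems reuse the same container: "ccsr_like" tables are flat
# single-membership (exactly one main item per code), "hcc_like" tables add
# dominance hierarchies that suppress less-severe items.

MAX_MAIN_ITEMS <- 4L

#' Construct a validated diagnosis-to-item mapping table
#'
#' @param entries data.frame/data.table with columns `code`, `item_id`,
#'   `kind` (one of `"main"`, `"modifier"`, `"scale"`), `scale_value`
#'   (numeric, `NA` unless `kind == "scale"`), `label`, `chapter`. One row per
#'   (code, item) pair; duplicate pairs are collapsed.
#' @param system_name one of `"dxi"`, `"ccsr_like"`, `"hcc_like"`, `"custom"`.
#' @param hierarchy optional data.frame with columns `dominant`, `suppressed`
#'   (item ids); only meaningful for `hcc_like` systems.
#' @param scale_ranges optional data.frame with columns `item_id`, `min`,
#'   `max` declaring the admissible range of each scale item (e.g. BMI in
#'   \[18.5, 70\]).
#' @return An object of class `dxi_mapping`.
#' @seealso [read_mapping()], [assign_items()], [apply_hierarchies()]
#' @export
dxi_mapping <- function(entries, system_name = c("dxi", "ccsr_like", "hcc_like", "custom"),
                        hierarchy = NULL, scale_ranges = NULL) {
  system_name <- match.arg(system_name)
  entries <- as.data.table(entries)
  required <- c("code", "item_id", "kind")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols)) {
    stop("mapping entries lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"scale_value" %in% names(entries)) entries[, scale_value := NA_real_]
  if (!"label" %in% names(entries)) entries[, label := ""]
  if (!"chapter" %in% names(entries)) entries[, chapter := NA_character_]

  if (nrow(entries)) {
    entries[, code := normalize_icd(code)]
    entries[, scale_value := as.numeric(scale_value)]
    entries[, label := as.character(label)]
    entries[, chapter := as.character(chapter)]
    bad_kind <- setdiff(unique(entries$kind), c("main", "modifier", "scale"))
    if (length(bad_kind)) stop("unknown item kind(s): ", paste(bad_kind, collapse = ", "))
    entries <- unique(entries, by = c("code", "item_id"))
    entries[is.na(chapter) | chapter == "", chapter := icd_chapter(code)]
    bad_ch <- setdiff(unique(entries$chapter), .valid_chapters())
    if (length(bad_ch)) stop("unknown chapter label(s): ", paste(bad_ch, collapse = ", "))

    # an item must have a single kind across all of its codes
    kinds <- entries[, .(n = uniqueN(kind)), by = item_id]
    if (any(kinds$n > 1L)) {
      stop("item(s) mapped with conflicting kinds: ",
           paste(kinds[n > 1L, item_id], collapse = ", "))
    }
    n_main <- entries[kind == "main", .N, by = code]
    if (any(n_main$N > MAX_MAIN_ITEMS)) {
      stop("code(s) with more than ", MAX_MAIN_ITEMS, " main items: ",
           paste(utils::head(n_main[N > MAX_MAIN_ITEMS, code], 5L), collapse = ", "))
    }
    if (system_name == "ccsr_like") {
      per_code <- entries[, .(n_main = sum(kind == "main")), by = code]
      if (any(per_code$n_main != 1L)) {
        stop("ccsr_like mappings are flat single-membership: every code needs exactly 1 main item")
      }
    }
    if (anyNA(entries[kind == "scale", scale_value])) {
      stop("scale entries must carry a numeric scale_value")
    }
    if (any(!is.na(entries[kind != "scale", scale_value]))) {
      stop("scale_value may only be set for kind == 'scale'")
    }
  }

  items <- if (nrow(entries)) {
    entries[, .(kind = kind[1L], label = label[1L], chapter = chapter[1L]), by = item_id]
  } else {
    data.table(item_id = character(), kind = character(),
               label = character(), chapter = character())
  }

  if (!is.null(scale_ranges)) {
    scale_ranges <- as.data.table(scale_ranges)[, .(item_id, min = as.numeric(min), max = as.numeric(max))]
    unknown <- setdiff(scale_ranges$item_id, items[kind == "scale", item_id])
    if (length(unknown)) stop("scale range declared for unknown scale item(s): ",
                              paste(unknown, collapse = ", "))
    chk <- merge(entries[kind == "scale"], scale_ranges, by = "item_id")
    off <- chk[scale_value < min | scale_value > max]
    if (nrow(off)) {
      stop("scale value outside declared range for: ",
           paste(sprintf("%s=%g on %s", off$item_id, off$scale_value, off$code), collapse = ", "))
    }
  } else {
    scale_ranges <- data.table(item_id = character(), min = numeric(), max = numeric())
  }

  if (!is.null(hierarchy) && nrow(as.data.table(hierarchy))) {
    hierarchy <- as.data.table(hierarchy)[, .(dominant = as.character(dominant),
                                              suppressed = as.character(suppressed))]
    unknown <- setdiff(c(hierarchy$dominant, hierarchy$suppressed), items$item_id)
    if (length(unknown)) {
      stop("hierarchy rule references unknown item(s): ", paste(unknown, collapse = ", "))
    }
    if (.has_cycle(hierarchy)) stop("hierarchy rules must form an acyclic relation")
  } else {
    hierarchy <- data.table(dominant = character(), suppressed = character())
  }

  setkey(entries, code)
  structure(list(system_name = system_name, entries = entries, items = items,
                 scale_ranges = scale_ranges, hierarchy = hierarchy),
            class = "dxi_mapping")
}

# cycle check via repeated leaf stripping (Kahn); rule sets are small
.has_cycle <- function(rules) {
  edges <- unique(rules)
  repeat {
    if (!nrow(edges)) return(FALSE)
    sinks <- setdiff(edges$suppressed, edges$dominant)
    keep <- !(edges$suppressed %in% sinks)
    if (all(keep)) return(TRUE)
    edges <- edges[keep]
  }
}

#' @export
print.dxi_mapping <- function(x, ...) {
  cat(sprintf("<dxi_mapping> system=%s: %d codes, %d items (%d main / %d modifier / %d scale), %d hierarchy rules\n",
              x$system_name, uniqueN(x$entries$code), nrow(x$items),
              sum(x$items$kind == "main"), sum(x$items$kind == "modifier"),
              sum(x$items$kind == "scale"), nrow(x$hierarchy)))
  invisible(x)
}

#' Read a mapping table from a TSV file
#'
#' The file format is one row per (code, item) pair with a header and columns
#' `code`, `item_id`, `kind`, `scale_value`, `label`, `chapter` (UTF-8,
#' tab-separated; `scale_value`, `label` and `chapter` may be empty).
#' Validation failures report 1-based file line numbers (header = line 1).
#'
#' @param path path to the mapping TSV.
#' @param system_name classification system, see [dxi_mapping()].
#' @param hierarchy_path optional TSV with columns `dominant`, `suppressed`.
#' @param scale_ranges optional data.frame of declared scale ranges.
#' @return A `dxi_mapping`.
#' @export
read_mapping <- function(path, system_name = "dxi", hierarchy_path = NULL,
                         scale_ranges = NULL) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = list(character = 1:6),
               fill = TRUE, na.strings = NULL)
  expected <- c("code", "item_id", "kind", "scale_value", "label", "chapter")
  if (!all(expected %in% names(raw))) {
    stop("mapping file must have header columns: ", paste(expected, collapse = ", "))
  }
  if (nrow(raw)) {
    raw[, line := .I + 1L]  # header occupies line 1
    codes <- normalize_icd(raw$code, error = FALSE)
    if (anyNA(codes)) {
      bad <- raw[is.na(codes)]
      stop(sprintf("malformed diagnosis code at line %d: '%s'", bad$line[1L], bad$code[1L]))
    }
    raw[, code := codes]
    sv <- suppressWarnings(as.numeric(raw$scale_value))
    bad_sv <- which(!is.na(raw$scale_value) & raw$scale_value != "" & is.na(sv))
    if (length(bad_sv)) {
      stop(sprintf("non-numeric scale_value at line %d: '%s'",
                   raw$line[bad_sv[1L]], raw$scale_value[bad_sv[1L]]))
    }
    raw[, scale_value := sv]
    raw[, line := NULL]
  } else {
    raw <- data.table(code = character(), item_id = character(), kind = character(),
                      scale_value = numeric(), label = character(), chapter = character())
  }
  hierarchy <- NULL
  if (!is.null(hierarchy_path)) {
    hierarchy <- fread(hierarchy_path, sep = "\t", header = TRUE,
                       colClasses = "character")
    setnames(hierarchy, tolower(names(hierarchy)))
    if (!all(c("dominant", "suppressed") %in% names(hierarchy))) {
      stop("hierarchy file must have columns: dominant, suppressed")
    }
  }
  dxi_mapping(raw, system_name = system_name, hierarchy = hierarchy,
              scale_ranges = scale_ranges)
}

#' Write a mapping table to TSV
#'
#' Inverse of [read_mapping()]: `read_mapping(write_mapping(m, f))` reproduces
#' the same entry set (order-insensitive).
#'
#' @param mapping a `dxi_mapping`.
#' @param path output path.
#' @param hierarchy_path optional output path for hierarchy rules.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path, hierarchy_path = NULL) {
  stopifnot(inherits(mapping, "dxi_mapping"))
  out <- mapping$entries[, .(code, item_id, kind, scale_value, label, chapter)]
  setorder(out, code, item_id)
  fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  if (!is.null(hierarchy_path)) {
    fwrite(mapping$hierarchy, hierarchy_path, sep = "\t", quote = FALSE)
  }
  invisible(path)
}

#' Assign diagnostic items to a single diagnosis code
#'
#' Exact matches are used when present. Otherwise the longest proper prefix of
#' at least 3 characters present in the table is used ("root-stem" fallback,
#' mirroring the ICD structure in which the first three characters form the
#' category). Codes matching nothing are returned with `source = "unmapped"`.
#'
#' @param mapping a `dxi_mapping`.
#' @param code a single diagnosis code (dotted or undotted).
#' @return A list with elements `code` (canonical form), `main_items`,
#'   `modifier_items` (character vectors), `scale_values` (named numeric) and
#'   `source` (`"exact"`, `"root_stem"` or `"unmapped"`).
#' @export
assign_items <- function(mapping, code) {
  stopifnot(inherits(mapping, "dxi_mapping"), length(code) == 1L)
  tab <- assignment_table(mapping, code)
  canon <- normalize_icd(code)
  rows <- tab[code == canon]
  src <- if (nrow(rows)) rows$source[1L] else "unmapped"
  sv <- rows[kind == "scale"]
  list(code = canon,
       main_items = rows[kind == "main", item_id],
       modifier_items = rows[kind == "modifier", item_id],
       scale_values = setNames(sv$scale_value, sv$item_id),
       source = src)
}

#' Vectorized item assignment with root-stem fallback
#'
#' Resolves many codes at once; used by the design-matrix builder. Unmapped
#' codes produce no item rows but are counted in the `unmapped` attribute so
#' run reports can surface them (user data may contain codes newer than the
#' mapping).
#'
#' @param mapping a `dxi_mapping`.
#' @param codes character vector of diagnosis codes (duplicates fine).
#' @return data.table with one row per (code, item): columns `code`,
#'   `item_id`, `kind`, `scale_value`, `source`. Attribute `unmapped` holds
#'   the distinct codes that matched nothing.
#' @export
assignment_table <- function(mapping, codes) {
  stopifnot(inherits(mapping, "dxi_mapping"))
  canon <- unique(normalize_icd(codes))
  if (!length(canon)) {
    out <- data.table(code = character(), item_id = character(), kind = character(),
                      scale_value = numeric(), source = character())
    setattr(out, "unmapped", character())
    return(out)
  }
  known <- unique(mapping$entries$code)
  exact <- canon[canon %in% known]
  pending <- setdiff(canon, exact)

  resolved <- data.table(code = exact, match = exact,
                         source = rep("exact", length(exact)))
  # longest proper prefix of length >= 3; fallback never fires for exact hits
  if (length(pending) && max(nchar(pending)) > 3L) {
    maxlen <- max(nchar(pending))
    for (len in seq(maxlen - 1L, 3L, by = -1L)) {
      if (!length(pending)) break
      cand <- pending[nchar(pending) > len]
      if (!length(cand)) next
      pref <- substr(cand, 1L, len)
      hit <- pref %in% known
      if (any(hit)) {
        resolved <- rbind(resolved,
                          data.table(code = cand[hit], match = pref[hit],
                                     source = "root_stem"))
        pending <- setdiff(pending, cand[hit])
      }
    }
  }
  ent <- mapping$entries[, .(match = code, item_id, kind, scale_value)]
  out <- merge(resolved, ent, by = "match", allow.cartesian = TRUE)[
    , .(code, item_id, kind, scale_value, source)]
  setorder(out, code, item_id)
  setattr(out, "unmapped", pending)
  out
}

#' Apply dominance hierarchies to a person's item set
#'
#' For every rule (dominant, suppressed) whose dominant item is present in the
#' *input* set, the suppressed item is removed; all rules are evaluated
#' against the original set, so chains collapse in a single application and
#' the operation is idempotent. Non-hierarchical systems return the input
#' unchanged.
#'
#' @param mapping a `dxi_mapping`.
#' @param items character vector (treated as a set) of item ids.
#' @return Character vector: the surviving items, original order preserved.
#' @export
apply_hierarchies <- function(mapping, items) {
  stopifnot(inherits(mapping, "dxi_mapping"))
  items <- unique(items)
  rules <- mapping$hierarchy
  if (mapping$system_name != "hcc_like" || !nrow(rules) || !length(items)) {
    return(items)
  }
  suppressed <- rules[dominant %in% items, suppressed]
  setdiff(items, suppressed)
}

#' Summarize a mapping by WHO chapter
#'
#' Per-chapter counts of distinct diagnosis codes, distinct main-effect items
#' and, optionally, items belonging to a significance set (e.g. columns whose
#' fitted coefficients pass a Bonferroni-corrected threshold). Codes are
#' counted under the chapter derived from their leading category; items under
#' their declared chapter (so an item spanning several chapters' codes is
#' counted once).
#'
#' @param mapping a `dxi_mapping`.
#' @param significant_items optional character vector of item ids.
#' @return data.table with columns `chapter`, `code_range`, `n_codes`,
#'   `n_main_items` and (when requested) `n_significant`, one row per chapter
#'   in canonical order; chapters absent from the mapping show zero counts.
#' @export
summarize_by_chapter <- function(mapping, significant_items = NULL) {
  stopifnot(inherits(mapping, "dxi_mapping"))
  ch <- as.data.table(chapter_table())[, .(chapter = abbrev,
                                           code_range = paste0(lo, "-", hi))]
  codes <- unique(mapping$entries[, .(code)])
  codes[, chapter := icd_chapter(code)]
  code_n <- codes[, .(n_codes = .N), by = chapter]
  mains <- mapping$items[kind == "main"]
  item_n <- mains[, .(n_main_items = .N), by = chapter]
  out <- merge(ch, code_n, by = "chapter", all.x = TRUE, sort = FALSE)
  out <- merge(out, item_n, by = "chapter", all.x = TRUE, sort = FALSE)
  if (!is.null(significant_items)) {
    sig <- mains[item_id %in% significant_items, .(n_significant = .N), by = chapter]
    out <- merge(out, sig, by = "chapter", all.x = TRUE, sort = FALSE)
  }
  for (col in setdiff(names(out), c("chapter", "code_range"))) {
    set(out, which(is.na(out[[col]])), col, 0L)
  }
  out[]
}
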