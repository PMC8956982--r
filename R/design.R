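# Sparse design matrices: age-sex cells, item indicators, scaled variables.

#' Default age band lower edges
#'
#' Infants (age 0) get their own band, then 1-4 and 5-year bands up to 60-64;
#' crossed with sex this yields 28 cells. The exact banding is configurable
#' via `age_band_edges` in [model_spec()].
#'
#' @return Integer vector of band lower edges.
#' @export
default_age_bands <- function() c(0L, 1L, seq(5L, 60L, by = 5L))

#' Describe a model specification
#'
#' A model spec names the outcome, the ordered list of classification
#' systems whose indicators enter the design (age-sex cells are always
#' included and always first), and the optional feature groups. The default
#' rich model is `c("age_sex", "ccsr_like", "dxi")`: main-effect items are
#' layered on top of the flat comparator categories, so the rich column set
#' strictly contains the comparator's.
#'
#' @param outcome outcome name (must exist in the cohort's outcome columns).
#' @param systems character vector of system names; `"age_sex"` is prepended
#'   if absent. Other entries must name mappings supplied to
#'   [build_design()].
#' @param include_modifiers include binary modifier-item indicators.
#' @param include_scales include numeric scale columns (value = maximum
#'   observed over the year, plus a companion observed indicator).
#' @param include_newborn include a newborn-flag indicator (birth-episode
#'   spending adjuster).
#' @param age_band_edges lower edges of the age bands.
#' @return A list of class `dxi_model_spec`.
#' @export
model_spec <- function(outcome, systems = c("age_sex", "ccsr_like", "dxi"),
                       include_modifiers = FALSE, include_scales = FALSE,
                       include_newborn = FALSE,
                       age_band_edges = default_age_bands()) {
  systems <- unique(c("age_sex", systems))
  structure(list(outcome = outcome, systems = systems,
                 include_modifiers = include_modifiers,
                 include_scales = include_scales,
                 include_newborn = include_newborn,
                 age_band_edges = sort(unique(as.integer(age_band_edges)))),
            class = "dxi_model_spec")
}

age_band_labels <- function(edges, max_age = 64L) {
  hi <- c(edges[-1L] - 1L, max_age)
  sprintf("%02d_%02d", edges, hi)
}

#' Age-sex cell indicators
#'
#' Cell-means coding: the full set of sex-by-age-band indicators with no
#' intercept, so each enrollee-year activates exactly one cell and negative
#' predictions can only arise from the net effect of diagnostic coefficients.
#'
#' @param age integer ages in `[0, 64]`.
#' @param sex `"F"`/`"M"` vector.
#' @param band_edges lower band edges (see [default_age_bands()]).
#' @return Sparse indicator matrix with columns `as_<sex>_<lo>_<hi>`.
#' @export
age_sex_cells <- function(age, sex, band_edges = default_age_bands()) {
  if (any(age < 0 | age > 64)) stop("age outside [0, 64]")
  if (!all(sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  edges <- sort(unique(as.integer(band_edges)))
  labs <- age_band_labels(edges)
  band <- findInterval(age, edges)
  cells <- as.vector(outer(labs, c("F", "M"), function(b, s) paste0("as_", s, "_", b)))
  j <- match(paste0("as_", sex, "_", labs[band]), cells)
  Matrix::sparseMatrix(i = seq_along(age), j = j, x = 1,
                       dims = c(length(age), length(cells)),
                       dimnames = list(NULL, cells))
}

# (person-year x item) indicator block for one mapping system.
# Returns a sparse matrix aligned to `index` (person_id, year), with column
# names prefixed "<system>:". Hierarchies are applied per person-year for
# hcc_like systems.
indicator_block <- function(index, diagnoses, mapping, system,
                            include_modifiers = FALSE) {
  kinds <- if (include_modifiers) c("main", "modifier") else "main"
  amap <- assignment_table(mapping, unique(diagnoses$code))
  amap <- amap[kind %in% kinds, .(code, item_id)]
  pairs <- unique(merge(diagnoses, amap, by = "code",
                        allow.cartesian = TRUE)[, .(person_id, year, item_id)])
  if (mapping$system_name == "hcc_like" && nrow(mapping$hierarchy) && nrow(pairs)) {
    # dominance judged on the pre-hierarchy set of each person-year
    for (r in seq_len(nrow(mapping$hierarchy))) {
      dom <- mapping$hierarchy$dominant[r]
      sup <- mapping$hierarchy$suppressed[r]
      has_dom <- unique(pairs[item_id == dom, .(person_id, year)])
      if (nrow(has_dom)) {
        drop <- pairs[item_id == sup][has_dom, on = c("person_id", "year"), nomatch = NULL]
        if (nrow(drop)) {
          pairs <- pairs[!drop, on = c("person_id", "year", "item_id")]
        }
      }
    }
  }
  items <- sort(unique(mapping$items[kind %in% kinds, item_id]))
  key <- paste(index$person_id, index$year)
  i <- match(paste(pairs$person_id, pairs$year), key)
  j <- match(pairs$item_id, items)
  keep <- !is.na(i)
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                       dims = c(nrow(index), length(items)),
                       dimnames = list(NULL, paste0(system, ":", items)))
}

# numeric scale columns: per person-year maximum observed value per scale
# item plus an observed-flag indicator (absence = 0 with flag 0).
scale_block <- function(index, diagnoses, mapping, system) {
  amap <- assignment_table(mapping, unique(diagnoses$code))
  amap <- amap[kind == "scale", .(code, item_id, scale_value)]
  items <- sort(unique(mapping$items[kind == "scale", item_id]))
  if (!length(items)) return(NULL)
  obs <- merge(diagnoses, amap, by = "code", allow.cartesian = TRUE)[
    , .(value = max(scale_value)), by = .(person_id, year, item_id)]
  key <- paste(index$person_id, index$year)
  i <- match(paste(obs$person_id, obs$year), key)
  keep <- !is.na(i)
  j <- match(obs$item_id, items)
  val <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = obs$value[keep],
                              dims = c(nrow(index), length(items)),
                              dimnames = list(NULL, paste0(system, ":", items)))
  flag <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                               dims = c(nrow(index), length(items)),
                               dimnames = list(NULL, paste0(system, ":", items, ":observed")))
  cbind(val, flag)
}

#' Build the sparse design matrix for a model spec
#'
#' Assembles age-sex cells and, per classification system, binary item
#' indicators (an item is 1 iff any of the year's distinct filtered
#' diagnoses maps to it; dominance hierarchies applied for `hcc_like`
#' systems), plus optional modifier and scale blocks. Columns with zero
#' prevalence are pruned when `columns` is `NULL` (development behaviour) and
#' recorded; passing the development column set conforms the matrix to it
#' (validation behaviour: missing columns become all-zero).
#'
#' @param cohort a `dxi_cohort` (or development/validation part).
#' @param mappings named list of `dxi_mapping` objects; names are the system
#'   names referenced by the model spec.
#' @param spec a [model_spec()].
#' @param columns optional character vector: exact column set to produce.
#' @return A `dxi_design`: list with sparse matrix `X`, outcome `y`, weights
#'   `w`, row `index` (person_id, year), `outcome`, `spec` and `pruned`.
#' @export
build_design <- function(cohort, mappings, spec, columns = NULL) {
  stopifnot(inherits(cohort, "dxi_cohort"), inherits(spec, "dxi_model_spec"))
  index <- cohort$years[, .(person_id, year)]
  blocks <- list(age_sex_cells(cohort$years$age, cohort$years$sex, spec$age_band_edges))
  if (spec$include_newborn) {
    nb <- Matrix::Matrix(matrix(as.numeric(cohort$years$newborn), ncol = 1,
                                dimnames = list(NULL, "newborn")), sparse = TRUE)
    blocks <- c(blocks, list(nb))
  }
  for (system in setdiff(spec$systems, "age_sex")) {
    mapping <- mappings[[system]]
    if (is.null(mapping)) stop("no mapping supplied for system '", system, "'")
    blocks <- c(blocks, list(indicator_block(index, cohort$diagnoses, mapping,
                                             system, spec$include_modifiers)))
    if (spec$include_scales) {
      sb <- scale_block(index, cohort$diagnoses, mapping, system)
      if (!is.null(sb)) blocks <- c(blocks, list(sb))
    }
  }
  X <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(X))) stop("duplicate design column names")
  pruned <- character()
  if (is.null(columns)) {
    prevalence <- Matrix::colSums(X != 0)
    pruned <- colnames(X)[prevalence == 0]
    if (length(pruned)) X <- X[, prevalence > 0, drop = FALSE]
  } else {
    missing_cols <- setdiff(columns, colnames(X))
    if (length(missing_cols)) {
      Z <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(nrow(X), length(missing_cols)),
                                dimnames = list(NULL, missing_cols))
      X <- cbind(X, Z)
    }
    X <- X[, columns, drop = FALSE]
  }
  if (!spec$outcome %in% names(cohort$years)) {
    stop("outcome '", spec$outcome, "' not found in cohort")
  }
  structure(list(X = X, y = cohort$years[[spec$outcome]],
                 w = cohort$years$weight, index = index,
                 outcome = spec$outcome, spec = spec, pruned = pruned),
            class = "dxi_design")
}

#' @export
print.dxi_design <- function(x, ...) {
  cat(sprintf("<dxi_design> %d rows x %d columns, outcome '%s' (%d pruned)\n",
              nrow(x$X), ncol(x$X), x$outcome, length(x$pruned)))
  invisible(x)
}

#' Export a design matrix as sparse triplets
#'
#' Writes a MatrixMarket coordinate file plus a one-column sidecar of column
#' names, so the matrix can be consumed outside R.
#'
#' @param design a `dxi_design`.
#' @param path output path for the MatrixMarket file; the sidecar is written
#'   to `<path>.colnames`.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  Matrix::writeMM(methods::as(design$X, "CsparseMatrix"), path)
  writeLines(colnames(design$X), paste0(path, ".colnames"))
  invisible(path)
}
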