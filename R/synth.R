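# Seeded synthetic claims generator with known ground truth.
#
# The generator emulates the statistical structure the framework assumes,
# not any real population: ICD-shaped codes with a power-law frequency
# spectrum spanning ~1 per million to ~1 in 10 enrollee-years;
# multi-membership mappings with overlapping broad/narrow main items,
# cross-cutting modifiers, a BMI-style scaled item and root-stem entries;
# coarsened single-membership (ccsr_like) and partial-coverage hierarchical
# (hcc_like) comparator mappings on the same code universe; partial-year
# enrollment and newborns; and spending from a known linear model in age-sex
# cells and main-effect items with heavy-tailed noise, rare extreme
# episodes, negative billing reversals and claim lines that exercise the
# professional-type filter.

#' Simulation configuration
#'
#' Returns the default study conditions, overridable via `...`. Defaults are
#' chosen once to mirror a commercial under-65 claims population at desk
#' scale; the methods vignette discusses each choice.
#'
#' @param seed integer master seed; every stream derives from it.
#' @param ... named overrides of the defaults (unknown names are an error).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_persons = 20000L,
    n_years = 3L,
    start_year = 2016L,
    p_full_year = 0.7,          # remainder uniform over 1-11 months
    newborn_rate = 0.008,       # share of persons entering as newborns
    n_codes = 500L,
    n_main_items = 120L,        # narrow main-effect items
    broad_share = 0.15,         # broad overlapping items per narrow item
    n_axis_items = 8L,          # cross-cutting extra main items
    n_modifier_items = 6L,
    modifier_code_rate = 0.10,
    vz_share = 0.06,            # V-/Z-codes carrying only modifiers
    overlap_rate = 0.35,        # share of codes with 2-4 main items
    root_stem_rate = 0.05,      # codes entered at the 3-character root
    n_ccsr = 40L,
    n_hcc = 18L,
    hcc_coverage = 0.25,        # share of codes the hcc_like system sees
    freq = list(exponent = 1, min_per_million = 1, max_per_million = 1e5),
    beta = list(meanlog = log(800), sdlog = 1, rare_boost = 2),
    newborn_effect = 6000,
    noise = list(family = "lognormal", scale = 1500, sdlog = 1, shape = 1),
    extreme_rate = 0.001,
    extreme = list(scale = 4e5, sdlog = 0.25),
    negative_adjustment_rate = 0.003,
    misfiled_rate = 0.05,
    deflators = c("2016" = 1.05, "2017" = 1.02, "2018" = 1.00)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      utils::modifyList(cfg[[nm]], dots[[nm]])
    } else dots[[nm]]
  }
  rates <- c(cfg$p_full_year, cfg$newborn_rate, cfg$overlap_rate, cfg$broad_share,
             cfg$modifier_code_rate, cfg$vz_share, cfg$root_stem_rate,
             cfg$hcc_coverage, cfg$extreme_rate, cfg$negative_adjustment_rate,
             cfg$misfiled_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$n_main_items > cfg$n_codes) stop("n_main_items must not exceed n_codes")
  yrs <- as.character(seq(cfg$start_year, length.out = cfg$n_years))
  if (!all(yrs %in% names(cfg$deflators))) {
    stop("deflators must cover every simulated year: ", paste(yrs, collapse = ", "))
  }
  structure(cfg, class = "sim_config")
}

# truncated power-law draw of per-million frequencies
.draw_frequencies <- function(n, freq) {
  a <- freq$exponent
  u <- runif(n)
  lo <- freq$min_per_million
  hi <- freq$max_per_million
  if (abs(a - 1) < 1e-12) {
    10^(log10(lo) + u * (log10(hi) - log10(lo)))
  } else {
    (lo^(1 - a) + u * (hi^(1 - a) - lo^(1 - a)))^(1 / (1 - a))
  }
}

.random_codes <- function(n, letters_pool) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    suf_len <- sample(0:2, need, replace = TRUE, prob = c(0.25, 0.45, 0.30))
    suffix <- vapply(suf_len, function(k) {
      if (k == 0L) "" else paste(sample(c(0:9, LETTERS), k, replace = TRUE), collapse = "")
    }, character(1))
    cand <- paste0(sample(letters_pool, need, replace = TRUE),
                   sprintf("%02d", sample(0:99, need, replace = TRUE)), suffix)
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Generate mapping tables with known structure
#'
#' Builds the fine multi-membership mapping plus the two comparators on the
#' same code universe, and draws the true spending effect of every main item.
#' Narrow items pool codes of similar population frequency (as a clinical
#' grouper pools similar conditions); comparator categories mix frequencies
#' at random, so the cost signal of rare codes is invisible to the flat
#' system's category means. True effects are heavy-tailed and inflated for
#' rare items, reflecting that rare conditions are disproportionately
#' expensive.
#'
#' @param config a [sim_config()].
#' @return List: `mappings` (named `dxi_mapping` list: `dxi`, `ccsr_like`,
#'   `hcc_like`), `codes` (data.table: `code`, `per_million`,
#'   `emit_variant`), `true_beta` (named vector over main items),
#'   `filter_rules` (default acceptable-source table).
#' @export
gen_mapping <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1L), {
    n_vz <- round(config$vz_share * config$n_codes)
    n_bmi <- 8L
    n_normal <- config$n_codes - n_vz - n_bmi
    if (n_normal < config$n_main_items) stop("n_codes too small for n_main_items")

    normal_codes <- .random_codes(n_normal, c(LETTERS[1:20]))
    vz_codes <- .random_codes(n_vz, c("V", "Z"))
    bmi_codes <- sprintf("Z68%02d", seq(20L, 62L, by = 6L))
    vz_codes <- setdiff(vz_codes, c(bmi_codes, normal_codes))
    bmi_vals <- seq(20, 62, by = 6)

    # convert a share of normal codes to 3-character root-stem entries whose
    # claims will partly arrive as longer unmapped child codes
    is_rootish <- nchar(normal_codes) > 3L & runif(n_normal) < config$root_stem_rate
    roots <- substr(normal_codes, 1L, 3L)
    ok_root <- is_rootish & !duplicated(roots) & !roots %in% normal_codes
    normal_codes[ok_root] <- roots[ok_root]
    normal_codes <- unique(normal_codes)
    n_normal <- length(normal_codes)
    emit_variant <- ok_root[seq_len(n_normal)]

    pm <- .draw_frequencies(n_normal, config$freq)
    # narrow items pool codes of neighboring frequency (jittered rank blocks)
    rk <- rank(-pm + rnorm(n_normal, sd = stats::sd(pm) * 0.02), ties.method = "first")
    item_of <- ceiling(rk / (n_normal / config$n_main_items))
    item_of <- pmin(pmax(item_of, 1L), config$n_main_items)
    narrow <- sprintf("DXI%03d", item_of)

    n_broad <- max(1L, round(config$broad_share * config$n_main_items))
    broad_of <- sprintf("BRD%02d", ceiling(item_of / (config$n_main_items / n_broad)))
    axis_pool <- sprintf("AXI%02d", seq_len(config$n_axis_items))

    rows <- list(data.table(code = normal_codes, item_id = narrow, kind = "main"))
    over <- runif(n_normal) < config$overlap_rate
    rows[[2]] <- data.table(code = normal_codes[over], item_id = broad_of[over], kind = "main")
    ax1 <- over & runif(n_normal) < 0.4
    rows[[3]] <- data.table(code = normal_codes[ax1],
                            item_id = sample(axis_pool, sum(ax1), replace = TRUE),
                            kind = "main")
    ax2 <- ax1 & runif(n_normal) < 0.3
    rows[[4]] <- data.table(code = normal_codes[ax2],
                            item_id = sample(axis_pool, sum(ax2), replace = TRUE),
                            kind = "main")
    mods <- sprintf("MOD%02d", seq_len(config$n_modifier_items))
    with_mod <- runif(n_normal) < config$modifier_code_rate
    rows[[5]] <- data.table(code = normal_codes[with_mod],
                            item_id = sample(mods, sum(with_mod), replace = TRUE),
                            kind = "modifier")
    rows[[6]] <- data.table(code = vz_codes,
                            item_id = sample(mods, length(vz_codes), replace = TRUE),
                            kind = "modifier")
    rows[[7]] <- data.table(code = bmi_codes, item_id = "BMI", kind = "scale")
    entries <- rbindlist(rows)
    entries[, scale_value := fifelse(kind == "scale",
                                     bmi_vals[match(code, bmi_codes)], NA_real_)]
    entries <- unique(entries, by = c("code", "item_id"))
    # enforce the <=4 main-item cap deterministically (axis items yield first)
    entries[, kind_rank := match(kind, c("main", "modifier", "scale"))]
    setorder(entries, code, kind_rank, item_id)
    entries[kind == "main", main_rank := seq_len(.N), by = code]
    entries <- entries[is.na(main_rank) | main_rank <= MAX_MAIN_ITEMS]
    entries[, c("kind_rank", "main_rank") := NULL]
    entries[, label := item_id]
    entries[, chapter := NA_character_]

    dxi <- dxi_mapping(entries, system_name = "dxi",
                       scale_ranges = data.table(item_id = "BMI", min = 18.5, max = 70))

    all_codes <- c(normal_codes, vz_codes, bmi_codes)
    ccsr <- dxi_mapping(data.table(
      code = all_codes,
      item_id = sprintf("CCSR%02d", sample(config$n_ccsr, length(all_codes), replace = TRUE)),
      kind = "main", scale_value = NA_real_, label = "", chapter = NA_character_
    ), system_name = "ccsr_like")

    sev_codes <- normal_codes[order(-pm)][seq(20L, length.out = 3L)]
    hcc_pool <- setdiff(normal_codes, sev_codes)
    covered <- sample(hcc_pool, round(config$hcc_coverage * length(hcc_pool)))
    hcc_entries <- rbind(
      data.table(code = covered,
                 item_id = sprintf("HCC%02d", sample(config$n_hcc, length(covered), replace = TRUE)),
                 kind = "main"),
      data.table(code = sev_codes, item_id = c("SEV1", "SEV2", "SEV3"), kind = "main")
    )
    hcc_entries[, `:=`(scale_value = NA_real_, label = "", chapter = NA_character_)]
    hcc <- dxi_mapping(hcc_entries, system_name = "hcc_like",
                       hierarchy = data.table(dominant = c("SEV3", "SEV2"),
                                              suppressed = c("SEV2", "SEV1")))

    # true dollar effects of every fine-system main item, heavier for rarer
    # items (aggregate per-million frequency over the item's codes)
    mains <- dxi$items[kind == "main", item_id]
    code_pm <- data.table(code = normal_codes, per_million = pm)
    item_pm <- merge(dxi$entries[kind == "main", .(code, item_id)], code_pm,
                     by = "code")[, .(pm = sum(per_million)), by = item_id]
    pm_of <- setNames(item_pm$pm, item_pm$item_id)[mains]
    pm_of[is.na(pm_of)] <- config$freq$min_per_million
    span <- log10(config$freq$max_per_million) - log10(config$freq$min_per_million)
    boost <- 1 + config$beta$rare_boost *
      pmax(0, (log10(config$freq$max_per_million) - log10(pmax(pm_of, 1))) / span)
    true_beta <- setNames(
      rlnorm(length(mains), config$beta$meanlog, config$beta$sdlog) * boost, mains)

    codes <- rbind(code_pm[, .(code, per_million)],
                   data.table(code = c(vz_codes, bmi_codes),
                              per_million = .draw_frequencies(length(vz_codes) + length(bmi_codes),
                                                              list(exponent = 1,
                                                                   min_per_million = 100,
                                                                   max_per_million = 2e4))))
    codes[, emit_variant := code %in% normal_codes[emit_variant]]

    filter_rules <- data.table(
      setting = c("inpatient", "outpatient", "professional", "professional"),
      professional_type = c("*", "*", "md", "np"))

    list(mappings = list(dxi = dxi, ccsr_like = ccsr, hcc_like = hcc),
         codes = codes, true_beta = true_beta, filter_rules = filter_rules)
  })
}

# per-cell deterministic base cost (band midpoint gradient plus a
# reproductive-age female bump); exported indirectly through ground truth
.cell_base <- function(sex, lo, hi) {
  mid <- (lo + hi) / 2
  900 + 18 * mid + 600 * (sex == "F" & mid >= 20 & mid < 45)
}

.expected_shock <- function(config) {
  ns <- config$noise
  base <- switch(ns$family,
                 lognormal = ns$scale * exp(ns$sdlog^2 / 2),
                 gamma = ns$shape * ns$scale,
                 stop("unknown noise family: ", ns$family))
  base + config$extreme_rate * config$extreme$scale * exp(config$extreme$sdlog^2 / 2)
}

#' Generate an enrolled population and claim-line skeleton
#'
#' Persons get ages, sexes, enrollment fractions and newborn flags; each
#' enrollee-year draws diagnoses by the per-code population frequencies
#' (scaled by the enrolled fraction); claim lines carry settings,
#' professional types and service types so that source filtering and
#' service-type outcomes are exercisable. A `misfiled_rate` share of
#' diagnoses is additionally duplicated onto disallowed lines, which the
#' filter should remove without losing the diagnosis.
#'
#' @param config a [sim_config()].
#' @param mapping output of [gen_mapping()].
#' @return List: `spans`, `claims` (skeleton without paid amounts), `pairs`
#'   (one row per (person-year, emitted diagnosis)).
#' @export
gen_population_claims <- function(config, mapping) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 2L), {
    years <- seq(config$start_year, length.out = config$n_years)
    n <- config$n_persons
    person_id <- sprintf("P%07d", seq_len(n))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    is_nb <- runif(n) < config$newborn_rate
    birth_year <- ifelse(is_nb, years[sample.int(length(years), n, replace = TRUE)],
                         NA_integer_)
    age0 <- ifelse(is_nb, 0L, sample(0:(64 - config$n_years + 1L), n, replace = TRUE))

    spans <- CJ(person_id = person_id, year = years)[order(person_id, year)]
    spans[, idx := match(person_id, sprintf("P%07d", seq_len(n)))]
    spans[, sex := sex[idx]]
    spans[, newborn := FALSE]
    nbsel <- is_nb[spans$idx]
    spans[, birth := birth_year[idx]]
    spans <- spans[!nbsel | year >= birth]
    spans[, age := fifelse(is.na(birth), age0[idx] + year - years[1L],
                           year - birth)]
    spans[!is.na(birth) & year == birth, newborn := TRUE]
    full <- runif(nrow(spans)) < config$p_full_year
    spans[, months_enrolled := fifelse(full, 12L,
                                       sample(1:11, nrow(spans), replace = TRUE))]
    spans[newborn == TRUE, months_enrolled := sample(1:12, .N, replace = TRUE)]
    spans[, c("idx", "birth") := NULL]
    spans[, fraction := months_enrolled / 12]

    # diagnosis draws: per-code Bernoulli with probability scaled by the
    # enrolled fraction, drawn per months-class to stay vectorized
    classes <- split(seq_len(nrow(spans)), spans$months_enrolled)
    pair_rows <- vector("list", nrow(mapping$codes))
    for (ci in seq_len(nrow(mapping$codes))) {
      p0 <- mapping$codes$per_million[ci] / 1e6
      hits <- lapply(names(classes), function(m) {
        rows <- classes[[m]]
        k <- rbinom(1L, length(rows), min(p0 * as.integer(m) / 12, 1))
        if (k > 0L) rows[sample.int(length(rows), k)] else integer(0)
      })
      hits <- unlist(hits)
      if (length(hits)) {
        pair_rows[[ci]] <- data.table(row = hits, code = mapping$codes$code[ci],
                                      variant = mapping$codes$emit_variant[ci])
      }
    }
    pairs <- rbindlist(pair_rows[!vapply(pair_rows, is.null, TRUE)])
    if (nrow(pairs)) {
      mutate <- pairs$variant & runif(nrow(pairs)) < 0.6
      pairs[mutate, code := paste0(code, sample(c("0", "1", "A"), sum(mutate), replace = TRUE))]
      pairs[, `:=`(person_id = spans$person_id[row], year = spans$year[row], variant = NULL)]
    } else {
      pairs <- data.table(row = integer(), code = character(),
                          person_id = character(), year = integer())
    }

    service_pool <- c("other", "lab", "imaging", "retail_rx", "op_facility_rx",
                      "preventive", "ip_facility_rx")
    base_lines <- spans[, .(person_id, year, setting = "professional",
                            professional_type = "md",
                            service_type = sample(c("preventive", "other", "lab"),
                                                  .N, replace = TRUE, prob = c(0.6, 0.25, 0.15)),
                            diagnosis_codes = "", is_base = TRUE)]
    if (nrow(pairs)) {
      dx_setting <- sample(c("inpatient", "outpatient", "professional"),
                           nrow(pairs), replace = TRUE, prob = c(0.08, 0.32, 0.60))
      dx_lines <- data.table(
        person_id = pairs$person_id, year = pairs$year, setting = dx_setting,
        professional_type = fifelse(dx_setting == "professional",
                                    sample(c("md", "np"), nrow(pairs), replace = TRUE,
                                           prob = c(0.8, 0.2)), "*"),
        service_type = fifelse(dx_setting == "inpatient", "ip_facility_rx",
                               sample(service_pool, nrow(pairs), replace = TRUE,
                                      prob = c(0.38, 0.16, 0.13, 0.16, 0.08, 0.06, 0.03))),
        diagnosis_codes = pairs$code, is_base = FALSE)
      dx_lines[professional_type == "*", professional_type := "hospital"]
      misfiled <- runif(nrow(pairs)) < config$misfiled_rate
      mis_lines <- data.table(
        person_id = pairs$person_id[misfiled], year = pairs$year[misfiled],
        setting = sample(c("other", "professional"), sum(misfiled), replace = TRUE),
        professional_type = "chiro", service_type = "other",
        diagnosis_codes = pairs$code[misfiled], is_base = FALSE)
      claims <- rbindlist(list(base_lines, dx_lines, mis_lines))
    } else {
      claims <- base_lines
    }
    setorder(claims, person_id, year, -is_base, diagnosis_codes)
    claims[, line_id := seq_len(.N)]

    list(spans = spans[], claims = claims[], pairs = pairs[])
  })
}

#' Generate spending and utilization with known ground truth
#'
#' Annualized spending for each enrollee-year is a linear model in age-sex
#' cells, the distinct fine-system main items implied by the year's emitted
#' diagnoses, and a newborn birth-episode effect, plus a positive
#' heavy-tailed shock and (rarely) an extreme episode; the observed raw
#' total scales everything by the enrolled fraction for non-newborns, is
#' expressed in nominal dollars (so that deflation is exercised) and is
#' spread across the year's claim lines. Recorded ground-truth coefficients
#' are the exact conditional means: cell base plus the expected shock (and
#' expected extreme contribution).
#'
#' @param config a [sim_config()].
#' @param population output of [gen_population_claims()].
#' @param mapping output of [gen_mapping()].
#' @return List: `claims` (with paid amounts and count fields),
#'   `ground_truth` (`true_beta`, `cell_coefficients`, `newborn_effect`,
#'   `codes`, `expected_shock`, the per-enrollee-year `item_sets`, and the
#'   row ids of negative billing reversals).
#' @export
gen_spending <- function(config, population, mapping) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 3L), {
    spans <- population$spans
    pairs <- population$pairs
    n <- nrow(spans)

    amap <- assignment_table(mapping$mappings$dxi, unique(pairs$code))
    amap <- amap[kind == "main", .(code, item_id)]
    ey_items <- unique(merge(pairs, amap, by = "code",
                             allow.cartesian = TRUE)[, .(row, item_id)])
    item_sum <- ey_items[, .(s = sum(mapping$true_beta[item_id]),
                             n_items = .N), by = row]
    sum_beta <- rep(0, n)
    n_items <- rep(0L, n)
    sum_beta[item_sum$row] <- item_sum$s
    n_items[item_sum$row] <- item_sum$n_items

    edges <- default_age_bands()
    labs <- age_band_labels(edges)
    band <- findInterval(spans$age, edges)
    lo <- edges[band]
    hi <- c(edges[-1L] - 1L, 64L)[band]
    base0 <- .cell_base(spans$sex, lo, hi)

    mu <- base0 + sum_beta + config$newborn_effect * spans$newborn
    shock <- switch(config$noise$family,
                    lognormal = config$noise$scale * rlnorm(n, 0, config$noise$sdlog),
                    gamma = rgamma(n, shape = config$noise$shape,
                                   scale = config$noise$scale),
                    stop("unknown noise family"))
    extreme <- (runif(n) < config$extreme_rate) *
      config$extreme$scale * rlnorm(n, 0, config$extreme$sdlog)
    annualized <- mu + shock + extreme
    raw_real <- fifelse(spans$newborn, annualized, annualized * spans$fraction)
    defl <- unname(config$deflators[as.character(spans$year)])
    raw_nominal <- raw_real / defl

    reversal <- which(runif(n) < config$negative_adjustment_rate)

    claims <- copy(population$claims)
    claims[, row := match(paste(person_id, year), paste(spans$person_id, spans$year))]
    claims[, share := rexp(.N)]
    claims[, share := share / sum(share), by = row]
    claims[, paid_total := raw_nominal[row] * share]
    claims[, paid_plan := paid_total * runif(.N, 0.75, 0.95)]
    claims[, paid_oop := paid_total - paid_plan]
    claims[, share := NULL]

    # utilization counts ride on the guaranteed base line of each year
    lambda_adm <- spans$fraction * (0.02 + 0.015 * n_items) + 0.3 * spans$newborn
    adm_v <- rpois(n, lambda_adm)
    ipd_v <- adm_v + rpois(n, 2 * adm_v)
    edv_v <- rpois(n, spans$fraction * (0.06 + 0.01 * n_items))
    claims[, `:=`(admissions = 0L, ip_days = 0L, ed_visits = 0L)]
    claims[is_base == TRUE, `:=`(admissions = adm_v[row],
                                 ip_days = ipd_v[row],
                                 ed_visits = edv_v[row])]

    if (length(reversal)) {
      rev_lines <- data.table(
        person_id = spans$person_id[reversal], year = spans$year[reversal],
        setting = "professional", professional_type = "md",
        service_type = "other", diagnosis_codes = "", is_base = FALSE,
        line_id = max(claims$line_id) + seq_along(reversal), row = reversal,
        paid_total = -(raw_nominal[reversal] + runif(length(reversal), 10, 500)),
        paid_plan = 0, paid_oop = 0, admissions = 0L, ip_days = 0L, ed_visits = 0L)
      rev_lines[, paid_plan := paid_total]
      claims <- rbind(claims, rev_lines)
    }
    claims[, c("row", "is_base") := NULL]

    cells <- as.vector(outer(labs, c("F", "M"), function(b, s) paste0("as_", s, "_", b)))
    cell_lo <- rep(edges, 2L)
    cell_hi <- rep(c(edges[-1L] - 1L, 64L), 2L)
    cell_sex <- rep(c("F", "M"), each = length(edges))
    cell_coefficients <- setNames(
      .cell_base(cell_sex, cell_lo, cell_hi) + .expected_shock(config), cells)

    list(claims = claims[],
         ground_truth = list(
           true_beta = mapping$true_beta,
           cell_coefficients = cell_coefficients,
           newborn_effect = config$newborn_effect,
           expected_shock = .expected_shock(config),
           codes = mapping$codes,
           item_sets = ey_items,
           reversal_rows = reversal))
  })
}

#' One-call synthetic study
#'
#' Runs [gen_mapping()], [gen_population_claims()] and [gen_spending()] and
#' returns everything the pipeline consumes.
#'
#' @param config a [sim_config()] (or arguments forwarded to it via `...`).
#' @param ... overrides forwarded to [sim_config()] when `config` is NULL.
#' @return List: `config`, `mappings`, `codes`, `true_beta`, `filter_rules`,
#'   `spans`, `claims`, `pairs`, `ground_truth`.
#' @export
simulate_claims <- function(config = NULL, ...) {
  if (is.null(config)) config <- sim_config(...)
  stopifnot(inherits(config, "sim_config"))
  mp <- gen_mapping(config)
  pop <- gen_population_claims(config, mp)
  sp <- gen_spending(config, pop, mp)
  list(config = config, mappings = mp$mappings, codes = mp$codes,
       true_beta = mp$true_beta, filter_rules = mp$filter_rules,
       spans = pop$spans, claims = sp$claims, pairs = pop$pairs,
       ground_truth = sp$ground_truth)
}
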