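#' Derivation rules for analysis variables
#'
#' Bundles every scoring and dichotomization rule used to turn raw
#' questionnaire items into analysis variables, with the field-standard
#' defaults: AUDIT-based excessive drinking (21+ weekly units for men, 14+
#' for women, or 6+ units per occasion at least weekly), CAGE-based
#' excessive drinking (2+ of 4 problem-drinking items), daily smoking (with
#' an any-smoking sensitivity variant), a single unhealthy-diet category,
#' physical inactivity as exercising very little or never (with an
#' irregular-activity sensitivity variant), demand/support composites on the
#' 1-4 scale and the 6-item depressive-symptom sum on 0-24.
#'
#' @param audit_units_male,audit_units_female inclusive weekly-unit
#'   thresholds by sex.
#' @param cage_min_positive minimum number of positive CAGE items.
#' @param diet_unhealthy,diet_healthy response-category lists for the diet
#'   item (must be disjoint).
#' @param inactive_categories exercise-frequency categories counted as
#'   inactive under the main definition.
#' @param irregular_categories categories counted as inactive under the
#'   irregular-activity sensitivity definition.
#' @param max_missing_frac scale scores are missing when more than this
#'   fraction of items is missing (default 0.5: at least half observed).
#' @param scl_allow_missing if `TRUE`, the depressive sum is prorated from
#'   observed items under the same fraction rule; default `FALSE` (missing
#'   if any item missing).
#' @param alcohol_instrument per-wave instrument selection, a character
#'   vector like `c("audit", "audit", "cage", "cage")` (the survey switched
#'   instrument between the first two and last two analysis waves).
#' @return An object of class `clp_rules`.
#' @export
derivation_rules <- function(audit_units_male = 21,
                             audit_units_female = 14,
                             cage_min_positive = 2,
                             diet_unhealthy = "a lot of fat, sugar or fast food",
                             diet_healthy = c("varying/average diet",
                                              "avoid fat and sugar",
                                              "special diet"),
                             inactive_categories = c("never", "very little"),
                             irregular_categories = c("never", "very little",
                                                      "now and then"),
                             max_missing_frac = 0.5,
                             scl_allow_missing = FALSE,
                             alcohol_instrument = c("audit", "audit",
                                                    "cage", "cage")) {
  if (length(intersect(diet_unhealthy, diet_healthy))) {
    stop("diet category lists must be disjoint")
  }
  stopifnot(audit_units_male > 0, audit_units_female > 0,
            cage_min_positive > 0)
  structure(
    list(
      audit_units_male = audit_units_male,
      audit_units_female = audit_units_female,
      audit_binge_units = 6,
      cage_min_positive = cage_min_positive,
      diet_unhealthy = diet_unhealthy,
      diet_healthy = diet_healthy,
      inactive_categories = inactive_categories,
      irregular_categories = irregular_categories,
      max_missing_frac = max_missing_frac,
      scl_allow_missing = scl_allow_missing,
      alcohol_instrument = alcohol_instrument
    ),
    class = "clp_rules"
  )
}

#' Write derivation rules as YAML for audit
#' @param rules a [derivation_rules()] object.
#' @param path file path.
#' @export
write_rules <- function(rules, path) {
  yaml::write_yaml(unclass(rules), path)
  invisible(path)
}

#' Score a demand or support composite scale
#'
#' Mean of the non-missing items on the 1-4 response scale (4 demand items
#' or 5 support items). The score is missing when more than
#' `max_missing_frac` of the items is missing.
#'
#' @param items numeric vector (or matrix, one row per subject) of item
#'   codes in 1-4; `NA` allowed.
#' @param scale `"demands"` or `"support"` (determines the expected item
#'   count).
#' @param rules a [derivation_rules()].
#' @return Numeric score(s) in [1, 4], `NA` where too many items missing.
#' @examples
#' score_scale(c(2, 3, 2, 3), "demands") # 2.5
#' @export
score_scale <- function(items, scale = c("demands", "support"),
                        rules = derivation_rules()) {
  scale <- match.arg(scale)
  k <- if (scale == "demands") 4L else 5L
  m <- as_item_matrix(items, k)
  rng <- range(m, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 1 || rng[2] > 4)) {
    stop(scale, " items must be coded 1-4")
  }
  n_miss <- rowSums(is.na(m))
  out <- rowMeans(m, na.rm = TRUE)
  out[n_miss / k > rules$max_missing_frac] <- NA_real_
  out[is.nan(out)] <- NA_real_
  out
}

#' Score the six-item depressive-symptom sum
#'
#' Sum of six items each coded 0-4, giving a 0-24 severity score. By default
#' the score is missing when any item is missing; with
#' `rules$scl_allow_missing` the score is prorated (mean of observed items
#' times 6) when at least half the items are observed.
#'
#' @inheritParams score_scale
#' @return Integer-valued score(s) in [0, 24].
#' @examples
#' score_scl_cd6(c(1, 2, 0, 3, 4, 2)) # 12
#' @export
score_scl_cd6 <- function(items, rules = derivation_rules()) {
  m <- as_item_matrix(items, 6L)
  rng <- range(m, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 4)) {
    stop("depressive items must be coded 0-4")
  }
  if (rules$scl_allow_missing) {
    n_miss <- rowSums(is.na(m))
    out <- rowMeans(m, na.rm = TRUE) * 6
    out[n_miss / 6 > rules$max_missing_frac] <- NA_real_
    out[is.nan(out)] <- NA_real_
  } else {
    out <- rowSums(m)
  }
  out
}

#' Dichotomize smoking status
#'
#' Main definition: daily smoking versus occasional ("sometimes") or no
#' smoking. Sensitivity variant `"any"`: daily or occasional smoking versus
#' no smoking.
#'
#' @param status character vector in `c("daily", "sometimes", "never")`.
#' @param variant `"daily"` (main) or `"any"` (sensitivity).
#' @return Integer 0/1 (`NA` propagated).
#' @export
derive_smoking <- function(status, variant = c("daily", "any")) {
  variant <- match.arg(variant)
  known <- c("daily", "sometimes", "never")
  bad <- !is.na(status) & !status %in% known
  if (any(bad)) {
    stop("unknown smoking category: ", paste(unique(status[bad]),
                                             collapse = ", "))
  }
  pos <- if (variant == "daily") "daily" else c("daily", "sometimes")
  ifelse(is.na(status), NA_integer_, as.integer(status %in% pos))
}

#' Dichotomize excessive drinking from AUDIT consumption items
#'
#' Positive when a man reports 21 or more (a woman 14 or more) units weekly,
#' or when six or more units per occasion are consumed at least weekly
#' (binge flag), matching the AUDIT-based rule used in the first two
#' analysis waves.
#'
#' @param sex `"male"`/`"female"` (or 0/1 with 1 = female).
#' @param weekly_units non-negative weekly alcohol units.
#' @param binge_weekly logical/0-1: six or more units per occasion at least
#'   weekly.
#' @param rules a [derivation_rules()].
#' @return Integer 0/1 (`NA` when any needed input is missing).
#' @export
derive_alcohol_audit <- function(sex, weekly_units, binge_weekly,
                                 rules = derivation_rules()) {
  sex <- normalize_sex(sex)
  if (any(!is.na(weekly_units) & weekly_units < 0)) {
    stop("weekly_units must be non-negative")
  }
  thr <- ifelse(sex == "female", rules$audit_units_female,
                rules$audit_units_male)
  heavy <- weekly_units >= thr
  # three-valued logic: a known positive component decides even when the
  # other is missing
  as.integer(heavy | as.logical(binge_weekly))
}

#' Dichotomize excessive drinking from CAGE items
#'
#' Positive when at least `rules$cage_min_positive` (default two) of the
#' four problem-drinking items are endorsed, matching the CAGE-based rule
#' used in the later analysis waves.
#'
#' @param cage_items four 0/1 flags per subject (vector of 4, or matrix with
#'   4 columns).
#' @param rules a [derivation_rules()].
#' @return Integer 0/1.
#' @export
derive_alcohol_cage <- function(cage_items, rules = derivation_rules()) {
  m <- as_item_matrix(cage_items, 4L)
  if (any(!is.na(m) & !m %in% c(0, 1))) stop("CAGE items must be 0/1")
  s <- rowSums(m)
  out <- as.integer(s >= rules$cage_min_positive)
  # enough endorsed items can decide despite missing ones
  s_obs <- rowSums(m, na.rm = TRUE)
  out[is.na(out) & s_obs >= rules$cage_min_positive] <- 1L
  out
}

#' Dichotomize diet quality
#'
#' Positive for the unhealthy response category ("a lot of fat, sugar or
#' fast food"); the healthy categories (varying/average diet, avoiding fat
#' and sugar, special diet) are the reference.
#'
#' @param category character vector of diet responses.
#' @param rules a [derivation_rules()].
#' @return Integer 0/1.
#' @export
derive_diet <- function(category, rules = derivation_rules()) {
  known <- c(rules$diet_unhealthy, rules$diet_healthy)
  bad <- !is.na(category) & !category %in% known
  if (any(bad)) {
    stop("unknown diet category: ", paste(unique(category[bad]),
                                          collapse = ", "))
  }
  ifelse(is.na(category), NA_integer_,
         as.integer(category %in% rules$diet_unhealthy))
}

#' Dichotomize physical inactivity
#'
#' Main definition: inactive when exercising very little or never, active
#' when exercising now and then or regularly. Sensitivity variant
#' `"irregular"`: inactive also when exercising only now and then.
#'
#' @param category exercise-frequency responses in `c("never",
#'   "very little", "now and then", "regularly")`.
#' @param variant `"main"` or `"irregular"`.
#' @param rules a [derivation_rules()].
#' @return Integer 0/1.
#' @export
derive_inactivity <- function(category, variant = c("main", "irregular"),
                              rules = derivation_rules()) {
  variant <- match.arg(variant)
  known <- c("never", "very little", "now and then", "regularly")
  bad <- !is.na(category) & !category %in% known
  if (any(bad)) {
    stop("unknown exercise category: ", paste(unique(category[bad]),
                                              collapse = ", "))
  }
  pos <- if (variant == "main") rules$inactive_categories else
    rules$irregular_categories
  ifelse(is.na(category), NA_integer_, as.integer(category %in% pos))
}

#' Count unhealthy behaviors
#'
#' Sum of the four binary indicators (smoking, excessive alcohol, unhealthy
#' diet, physical inactivity), a 0-4 count. Missing when any component is
#' missing unless `allow_missing`.
#'
#' @param behaviors four 0/1 values per subject (vector of 4 or a 4-column
#'   matrix/data.frame).
#' @param allow_missing if `TRUE`, sum observed components only.
#' @return Integer count(s) in 0-4.
#' @export
count_unhealthy <- function(behaviors, allow_missing = FALSE) {
  m <- as_item_matrix(behaviors, 4L)
  if (any(!is.na(m) & !m %in% c(0, 1))) {
    stop("behavior indicators must be 0/1")
  }
  if (allow_missing) rowSums(m, na.rm = TRUE) else rowSums(m)
}

#' Derive all analysis variables for a wide panel
#'
#' Applies every scoring rule wave by wave to a raw panel (as produced by
#' [generate_panel()] with `emit_raw_items = TRUE`, or read from CSV with
#' the same column convention), returning a wide table of derived variables:
#' `demands_w`, `support_w`, `depressive_w`, the four behavior indicators,
#' and `unhealthy_count_w`.
#'
#' When the panel already carries binary behavior indicator columns and no
#' raw items, the indicators are passed through unchanged.
#'
#' @param panel wide data.frame with `<item>_<wave>` columns.
#' @param rules a [derivation_rules()].
#' @param n_waves number of waves (inferred from columns by default).
#' @param smoking_variant,inactivity_variant operationalization variants
#'   passed to [derive_smoking()] and [derive_inactivity()].
#' @return A wide data.frame of derived variables with the panel's `id` and
#'   covariate columns.
#' @export
derive_variables <- function(panel, rules = derivation_rules(),
                             n_waves = NULL,
                             smoking_variant = "daily",
                             inactivity_variant = "main") {
  nm <- names(panel)
  if (is.null(n_waves)) {
    waves <- as.integer(sub(".*_", "", grep("^dep1_[0-9]+$", nm,
                                            value = TRUE)))
    n_waves <- max(waves)
  }
  keep <- intersect(c("id", "age", "female", "single", "edu"), nm)
  out <- panel[, keep, drop = FALSE]
  sex <- if ("female" %in% nm) {
    ifelse(panel$female == 1, "female", "male")
  } else {
    NULL
  }

  for (w in seq_len(n_waves)) {
    gv <- function(stub) panel[, paste0(stub, "_", w)]
    has <- function(stub) all(paste0(stub, "_", w) %in% nm)

    out[[paste0("demands_", w)]] <- score_scale(
      as.matrix(panel[, paste0("dem", 1:4, "_", w)]), "demands", rules
    )
    out[[paste0("support_", w)]] <- score_scale(
      as.matrix(panel[, paste0("sup", 1:5, "_", w)]), "support", rules
    )
    out[[paste0("depressive_", w)]] <- score_scl_cd6(
      as.matrix(panel[, paste0("dep", 1:6, "_", w)]), rules
    )

    smoking <- if (has("smoke_status")) {
      derive_smoking(gv("smoke_status"), smoking_variant)
    } else {
      gv("smoking")
    }
    alcohol <- if (rules$alcohol_instrument[w] == "audit" &&
                     has("alc_units")) {
      derive_alcohol_audit(sex, gv("alc_units"), gv("alc_binge"), rules)
    } else if (rules$alcohol_instrument[w] == "cage" && has("cage1")) {
      derive_alcohol_cage(
        as.matrix(panel[, paste0("cage", 1:4, "_", w)]), rules
      )
    } else {
      gv("alcohol")
    }
    diet <- if (has("diet_cat")) {
      derive_diet(gv("diet_cat"), rules)
    } else {
      gv("diet")
    }
    inact <- if (has("exercise")) {
      derive_inactivity(gv("exercise"), inactivity_variant, rules)
    } else {
      gv("inactivity")
    }

    out[[paste0("smoking_", w)]] <- smoking
    out[[paste0("alcohol_", w)]] <- alcohol
    out[[paste0("diet_", w)]] <- diet
    out[[paste0("inactivity_", w)]] <- inact
    out[[paste0("unhealthy_count_", w)]] <- count_unhealthy(
      cbind(smoking, alcohol, diet, inact)
    )
  }
  out
}

as_item_matrix <- function(items, k) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.matrix(items)) {
    if (ncol(items) != k) stop("expected ", k, " item columns")
    return(items)
  }
  if (length(items) != k) stop("expected ", k, " items")
  matrix(items, nrow = 1)
}

normalize_sex <- function(sex) {
  if (is.numeric(sex)) {
    return(ifelse(is.na(sex), NA_character_,
                  ifelse(sex == 1, "female", "male")))
  }
  s <- tolower(as.character(sex))
  bad <- !is.na(s) & !s %in% c("male", "female", "m", "f")
  if (any(bad)) stop("unknown sex code: ", paste(unique(s[bad]),
                                                 collapse = ", "))
  ifelse(is.na(s), NA_character_, ifelse(s %in% c("female", "f"),
                                         "female", "male"))
}
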