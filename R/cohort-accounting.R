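# Cohort-level accounting: family conclusions, transitions, yields,
# reclassification statistics.

#' Five-level family conclusion scale, best first
#' @export
family_conclusion_levels <- c("pathogenic", "likely_pathogenic", "vus",
                              "candidate_gene", "negative")

#' Round half away from zero
#'
#' Percentages throughout the cohort summaries use commercial (half-up)
#' rounding rather than R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits to keep (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(36.84, 18.42, 40.5))
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Best-supported family conclusion from its findings
#'
#' A finding counts toward a molecular diagnosis only when its variant tier is
#' P or LP *and* the gene-disease association is established; a P/LP variant
#' in a gene that is not established supports at most a candidate-gene
#' conclusion, and a VUS requires an established gene to be reported as VUS.
#' Benign/likely-benign findings contribute nothing. With several findings the
#' family takes the best-supported conclusion (pathogenic > likely_pathogenic
#' > vus > candidate_gene > negative).
#'
#' @param findings Data frame with columns `variant_tier` (`"P"`, `"LP"`,
#'   `"VUS"`, `"LB"`, `"B"`) and `gda_tier` (`"established"`,
#'   `"published_candidate"`, `"candidate"`); may have zero rows.
#' @return One of [family_conclusion_levels].
#' @export
#' @examples
#' best_tier(data.frame(variant_tier = "LP", gda_tier = "published_candidate"))
best_tier <- function(findings) {
  if (is.null(findings) || nrow(findings) == 0L) return("negative")
  one <- function(vt, gt) {
    if (vt %in% c("B", "LB")) return("negative")
    if (!identical(gt, "established")) return("candidate_gene")
    switch(vt, P = "pathogenic", LP = "likely_pathogenic", VUS = "vus",
           "negative")
  }
  tiers <- mapply(one, findings$variant_tier, findings$gda_tier)
  family_conclusion_levels[min(match(tiers, family_conclusion_levels))]
}

validate_family_records <- function(records) {
  r <- tibble::as_tibble(records)
  stopifnot(all(c("family_id", "prior", "current") %in% names(r)))
  dup <- r$family_id[duplicated(r$family_id)]
  if (length(dup) > 0L) {
    stop("duplicate family_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(r$prior %in% family_conclusion_levels),
            all(r$current %in% family_conclusion_levels))
  r
}

#' Family-conclusion transition matrix
#'
#' Cross-tabulates prior against current family conclusions (the edge list of
#' an alluvial plot). Cell counts sum to the number of families.
#'
#' @param records Data frame with one row per family and columns `family_id`,
#'   `prior`, `current`.
#' @return An integer matrix with prior conclusions as rows and current
#'   conclusions as columns, both ordered best-first.
#' @export
transition_matrix <- function(records) {
  r <- validate_family_records(records)
  table(prior = factor(r$prior, family_conclusion_levels),
        current = factor(r$current, family_conclusion_levels))
}

#' Edge list of the family transition alluvial
#'
#' @param records As for [transition_matrix()].
#' @return Tibble with columns `prior`, `current`, `n`, dropping empty cells.
#' @export
transition_edges <- function(records) {
  m <- transition_matrix(records)
  df <- tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  names(df) <- c("prior", "current", "n")
  df[df$n > 0L, , drop = FALSE]
}

change_event_types <- c("variant_downgrade", "gda_downgrade",
                        "gda_established", "novel_diagnosis")

parse_change_events <- function(x, n = length(x)) {
  if (is.null(x)) x <- rep("", n)
  ev <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(ev, function(e) {
    e <- trimws(e[nzchar(trimws(e))])
    bad <- setdiff(e, change_event_types)
    if (length(bad) > 0L) {
      stop("unknown change event(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    e
  })
}

#' Count families with a clinically relevant change
#'
#' A family counts once toward the headline number if it carries at least one
#' change event (a previously reported variant downgraded out of P/LP, a
#' gene-disease association downgraded or newly established, or a novel
#' diagnosis); the breakdown tallies each event type separately, so a family
#' with several events contributes to several event tallies but only once to
#' the headline count.
#'
#' @param records Data frame with columns `family_id` and `change_events`
#'   (semicolon-joined tags from `variant_downgrade`, `gda_downgrade`,
#'   `gda_established`, `novel_diagnosis`; empty for no change).
#' @return List with `n_families`, `n_changed`, `change_rate_pct` (half-up
#'   integer percent) and `breakdown` (named integer vector per event type).
#' @export
clinically_relevant_changes <- function(records) {
  r <- validate_family_records(records)
  events <- parse_change_events(r[["change_events"]], nrow(r))
  changed <- lengths(events) > 0L
  breakdown <- vapply(change_event_types, function(t) {
    sum(vapply(events, function(e) t %in% e, logical(1)))
  }, integer(1))
  list(n_families = nrow(r),
       n_changed = sum(changed),
       change_rate_pct = round_half_up(100 * sum(changed) / nrow(r)),
       breakdown = breakdown)
}

#' Diagnostic yield at a given stage
#'
#' A family is diagnosed when its conclusion at the stage is pathogenic or
#' likely pathogenic (which, via [best_tier()], presupposes an established
#' gene-disease association; VUS and candidate-gene findings never count).
#'
#' @param records Family records as for [transition_matrix()].
#' @param stage `"prior"` or `"current"`.
#' @return List with `n_families`, `n_diagnosed` and `yield_pct` (half-up
#'   integer percent).
#' @export
diagnostic_yield <- function(records, stage = c("prior", "current")) {
  stage <- match.arg(stage)
  r <- validate_family_records(records)
  if (nrow(r) == 0L) stop("yield undefined for an empty cohort", call. = FALSE)
  diagnosed <- r[[stage]] %in% c("pathogenic", "likely_pathogenic")
  list(n_families = nrow(r), n_diagnosed = sum(diagnosed),
       yield_pct = round_half_up(100 * sum(diagnosed) / nrow(r)))
}

#' Three-stage corrected diagnostic yield
#'
#' Decomposes the yield correction into: the yield as originally reported;
#' the retroactively adjusted yield after removing families whose reported
#' finding was downgraded (variant re-classified out of P/LP, or the
#' gene-disease association downgraded); and the current yield after adding
#' novel diagnoses and newly established associations.
#'
#' @param records Family records with `prior`, `current` and `change_events`.
#' @return Tibble with one row per stage (`prior`, `after_downgrades`,
#'   `current`) and columns `n_diagnosed`, `n_families`, `yield_pct`.
#' @export
yield_correction_chain <- function(records) {
  r <- validate_family_records(records)
  events <- parse_change_events(r[["change_events"]], nrow(r))
  prior_dx <- r$prior %in% c("pathogenic", "likely_pathogenic")
  downgraded <- vapply(events, function(e) {
    any(c("variant_downgrade", "gda_downgrade") %in% e)
  }, logical(1))
  current_dx <- r$current %in% c("pathogenic", "likely_pathogenic")
  n <- nrow(r)
  counts <- c(prior = sum(prior_dx),
              after_downgrades = sum(prior_dx & !downgraded),
              current = sum(current_dx))
  tibble::tibble(stage = names(counts),
                 n_diagnosed = as.integer(counts),
                 n_families = n,
                 yield_pct = unname(round_half_up(100 * counts / n)))
}

#' Variant reclassification statistics
#'
#' Compares prior and current five-tier classifications of the same variants
#' and summarises the transitions. A reclassification is *clinically
#' relevant* when it crosses the (likely) pathogenic boundary: the variant was
#' P or LP and is no longer (including loss of classification through a
#' gene-disease-association downgrade, coded as current tier `"NC"`).
#'
#' @param variants Data frame with columns `variant_id`, `prior_tier` (`"P"`,
#'   `"LP"`, `"VUS"`), `current_tier` (`"P"`, `"LP"`, `"VUS"`, `"LB"`, `"B"`,
#'   or `"NC"` for not classified) and optionally `gda_change`.
#' @return List with `n_variants`, `transitions` (prior x current table),
#'   `n_clinically_reclassified`, `reclassified_pct` (half-up integer
#'   percent), and `per_prior` (named list of current-tier counts for each
#'   prior tier).
#' @export
reclassification_stats <- function(variants) {
  v <- tibble::as_tibble(variants)
  stopifnot(all(c("variant_id", "prior_tier", "current_tier") %in% names(v)))
  dup <- v$variant_id[duplicated(v$variant_id)]
  if (length(dup) > 0L) {
    stop("duplicate variant identity: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  prior_lv <- c("P", "LP", "VUS", "LB", "B")
  curr_lv <- c("P", "LP", "VUS", "LB", "B", "NC")
  stopifnot(all(v$prior_tier %in% prior_lv), all(v$current_tier %in% curr_lv))
  trans <- table(prior = factor(v$prior_tier, prior_lv),
                 current = factor(v$current_tier, curr_lv))
  relevant <- v$prior_tier %in% c("P", "LP") &
    !(v$current_tier %in% c("P", "LP"))
  per_prior <- lapply(stats::setNames(nm = intersect(prior_lv, v$prior_tier)),
                      function(t) trans[t, , drop = TRUE])
  list(n_variants = nrow(v),
       transitions = trans,
       n_clinically_reclassified = sum(relevant),
       reclassified_pct = round_half_up(100 * sum(relevant) / nrow(v)),
       per_prior = per_prior)
}
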