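# Shared generators for property-style tests.

# random valid criteria set as a canonical string (no duplicates; random
# effective strengths, incl. off-base modifiers)
random_criteria_string <- function(max_n = 6, include_ba1 = FALSE) {
  codes <- acmg_codes()
  if (!include_ba1) codes <- codes[codes$code != "BA1", ]
  n <- sample.int(max_n, 1)
  pick <- codes[sample.int(nrow(codes), n), ]
  strengths <- c("VeryStrong", "Strong", "Moderate", "Supporting")
  toks <- vapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.3) {
      paste0(pick$code[i], "_", sample(strengths, 1))
    } else {
      pick$code[i]
    }
  }, character(1))
  paste(toks, collapse = ",")
}

# random family records with self-consistent change events
random_family_records <- function(n = 60) {
  lv <- family_conclusion_levels
  prior <- sample(lv, n, replace = TRUE)
  current <- sample(lv, n, replace = TRUE)
  dx <- function(x) x %in% c("pathogenic", "likely_pathogenic")
  events <- character(n)
  events[dx(prior) & !dx(current)] <- "variant_downgrade"
  events[!dx(prior) & dx(current)] <- "novel_diagnosis"
  tibble::tibble(family_id = sprintf("R%03d", seq_len(n)),
                 prior = prior, current = current, change_events = events)
}
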