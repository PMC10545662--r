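# ACMG/AMP evidence criteria: parsing and two classification engines.

strength_levels <- c("Supporting", "Moderate", "Strong", "VeryStrong", "StandAlone")

# Integer evidence weights of the ACGS/Tavtigian points framework.
strength_points <- c(Supporting = 1L, Moderate = 2L, Strong = 4L, VeryStrong = 8L,
                     StandAlone = 8L)

#' Table of the 28 ACMG/AMP evidence codes
#'
#' Each code carries a fixed direction (pathogenic or benign) and a default
#' ("base") evidence strength determined by its prefix: `PVS` is very strong,
#' `PS`/`BS` are strong, `PM` is moderate, `PP`/`BP` are supporting, and `BA1`
#' is the stand-alone benign code.
#'
#' @return A tibble with columns `code`, `direction` and `base_strength`.
#' @export
#' @examples
#' acmg_codes()
acmg_codes <- function() {
  codes <- c("PVS1",
             paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
             "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
  base <- c("VeryStrong",
            rep("Strong", 4), rep("Moderate", 6), rep("Supporting", 5),
            "StandAlone", rep("Strong", 4), rep("Supporting", 7))
  tibble::tibble(
    code = codes,
    direction = ifelse(substr(codes, 1, 1) == "P", "pathogenic", "benign"),
    base_strength = base
  )
}

.engine_cache <- new.env(parent = emptyenv())

acmg_code_lookup <- function() {
  # cached lookup keyed by code id
  if (is.null(.engine_cache$codes)) {
    tab <- acmg_codes()
    .engine_cache$codes <- structure(split(tab, seq_len(nrow(tab))),
                                     names = tab$code)
  }
  .engine_cache$codes
}

new_criteria_set <- function(df) {
  structure(df, class = c("criteria_set", class(tibble::tibble())))
}

#' Parse an applied-criteria string into a criteria set
#'
#' Criteria strings are comma-separated token lists as printed in clinical
#' variant tables, e.g. `"PVS1,PS2_Strong,PM2"`. Each token is a code id,
#' optionally followed by `_Strength` when the criterion was applied at a
#' non-default evidence level (matched case-insensitively, so `PS4_supporting`
#' and `PS4_Supporting` are equivalent), and optionally a parenthesised free
#' text comment, e.g. `PP3(according to unpublished data)`. Comments are kept
#' verbatim in the `annotation` column and never influence classification.
#'
#' @param text A single criteria string; `""` or `NA` yield an empty set.
#' @return A `criteria_set`: a tibble with one row per applied criterion and
#'   columns `code`, `direction`, `base_strength`, `effective_strength`,
#'   `annotation`.
#' @export
#' @examples
#' parse_criteria("PVS1,PS2_Strong,PM2")
#' parse_criteria("PS4_supporting,PM2,PM3,PP1_Strong,PP3(unpublished)")
parse_criteria <- function(text) {
  stopifnot(length(text) == 1L)
  empty <- tibble::tibble(code = character(), direction = character(),
                          base_strength = character(),
                          effective_strength = character(),
                          annotation = character())
  if (is.na(text) || !nzchar(trimws(text))) {
    return(new_criteria_set(empty))
  }
  tokens <- strsplit(text, ",", fixed = TRUE)[[1]]
  lookup <- acmg_code_lookup()
  rows <- lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec(
      "^\\s*([A-Za-z]+[0-9]*)\\s*(?:_\\s*([A-Za-z]+))?\\s*(?:\\((.*)\\))?\\s*$",
      tok))[[1]]
    if (length(m) == 0L) {
      stop("malformed criteria token: '", trimws(tok), "'", call. = FALSE)
    }
    code <- toupper(m[2])
    info <- lookup[[code]]
    if (is.null(info)) {
      stop("unknown ACMG criterion code in token '", trimws(tok), "'",
           call. = FALSE)
    }
    eff <- info$base_strength
    if (nzchar(m[3])) {
      hit <- match(tolower(m[3]),
                   tolower(c("VeryStrong", "Strong", "Moderate", "Supporting")))
      if (is.na(hit)) {
        stop("malformed strength modifier in token '", trimws(tok), "'",
             call. = FALSE)
      }
      eff <- c("VeryStrong", "Strong", "Moderate", "Supporting")[hit]
    }
    tibble::tibble(code = code, direction = info$direction,
                   base_strength = info$base_strength,
                   effective_strength = eff, annotation = m[4])
  })
  out <- do.call(rbind, rows)
  dup <- out$code[duplicated(out$code)]
  if (length(dup) > 0L) {
    stop("duplicate criterion code(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  new_criteria_set(out)
}

#' Serialize a criteria set to its canonical string
#'
#' The canonical dialect emits comma-joined `CODE` tokens, appending
#' `_Strength` only when the effective strength differs from the code's base
#' strength. Annotations are not emitted (they are commentary, not evidence).
#'
#' @param set A `criteria_set` from [parse_criteria()].
#' @return A single string; `""` for an empty set.
#' @export
format_criteria <- function(set) {
  if (nrow(set) == 0L) return("")
  tok <- ifelse(set$effective_strength == set$base_strength, set$code,
                paste0(set$code, "_", set$effective_strength))
  paste(tok, collapse = ",")
}

#' @export
print.criteria_set <- function(x, ...) {
  cat("<criteria_set> ", format_criteria(x), "\n", sep = "")
  NextMethod()
}

#' Signed evidence points of applied criteria
#'
#' Supporting, moderate, strong and very strong evidence score 1, 2, 4 and 8
#' points at the applied (effective) strength; benign-direction criteria score
#' negatively. The stand-alone `BA1` scores -8.
#'
#' @param set A `criteria_set`.
#' @return Integer vector, one signed value per criterion.
#' @export
#' @examples
#' criterion_points(parse_criteria("PVS1,BS3,PM3_Supporting"))
criterion_points <- function(set) {
  if (nrow(set) == 0L) return(integer())
  pts <- strength_points[set$effective_strength]
  as.integer(ifelse(set$direction == "benign", -pts, pts))
}

classification_result <- function(tier, points, engine, conflict, rule_path = "") {
  structure(list(tier = tier, points = as.integer(points), engine = engine,
                 conflict = conflict, rule_path = rule_path),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification> %s (%+d points, %s engine%s%s)\n", x$tier,
              x$points, x$engine,
              if (x$conflict) ", conflicting evidence" else "",
              if (nzchar(x$rule_path)) paste0("; ", x$rule_path) else ""))
  invisible(x)
}

has_conflict <- function(set) {
  any(set$direction == "pathogenic") && any(set$direction == "benign")
}

#' Points-engine five-tier classification
#'
#' Sums the signed evidence points of a criteria set and maps the total onto
#' the five-tier scale: pathogenic at >= +10, likely pathogenic +6..+9,
#' uncertain 0..+5, likely benign -6..-1, benign at <= -7. `BA1` is stand-alone
#' and forces the benign tier regardless of the sum.
#'
#' @param set A `criteria_set`.
#' @return A `classification_result` with fields `tier` (one of `"P"`, `"LP"`,
#'   `"VUS"`, `"LB"`, `"B"`), `points`, `engine = "points"` and `conflict`
#'   (both evidence directions present).
#' @export
#' @examples
#' classify_points(parse_criteria("PVS1,PS2_Strong,PM2"))  # P, 14 points
#' classify_points(parse_criteria("PVS1_Strong,PM2,BS3"))  # VUS, conflicting
classify_points <- function(set) {
  pts <- sum(criterion_points(set))
  tier <- if ("BA1" %in% set$code) "B" else points_tier(pts)
  classification_result(tier, pts, "points", has_conflict(set))
}

points_tier <- function(points) {
  if (points >= 10L) "P"
  else if (points >= 6L) "LP"
  else if (points >= 0L) "VUS"
  else if (points >= -6L) "LB"
  else "B"
}

#' Rule-combination five-tier classification
#'
#' Applies the published evidence-combination rules at the effective strengths
#' of the applied criteria. Pathogenic combinations include one very strong
#' plus one strong/two moderate/one moderate and one supporting/two
#' supporting, two strong, or one strong with three moderate (or 2 moderate +
#' 2 supporting, or 1 moderate + 4 supporting); likely-pathogenic
#' combinations include one very strong or strong plus one moderate, one
#' strong plus two supporting, three moderate, two moderate plus two
#' supporting, or one moderate plus four supporting. On the benign side `BA1`
#' alone, or two strong benign criteria, give benign; one strong benign plus
#' one supporting benign, or two supporting benign, give likely benign.
#' A set mixing pathogenic- and benign-direction evidence is never averaged:
#' it resolves to the uncertain tier (except for stand-alone `BA1`).
#'
#' @param set A `criteria_set`.
#' @return A `classification_result` with `engine = "rules"`; `rule_path`
#'   records the matched combination, and `points` carries the points-engine
#'   total for reference.
#' @export
#' @examples
#' classify_rules(parse_criteria("PS3,PM2,PM3,PP1_Moderate"))  # P
#' classify_rules(parse_criteria("PM2,PP3"))                   # VUS
classify_rules <- function(set) {
  pts <- sum(criterion_points(set))
  conflict <- has_conflict(set)
  if ("BA1" %in% set$code) {
    return(classification_result("B", pts, "rules", conflict,
                                 "BA1 stand-alone"))
  }
  if (conflict) {
    return(classification_result("VUS", pts, "rules", TRUE,
                                 "conflicting evidence directions"))
  }
  path <- set[set$direction == "pathogenic", ]
  ben <- set[set$direction == "benign", ]
  n <- function(df, lev) sum(df$effective_strength == lev)
  vs <- n(path, "VeryStrong"); st <- n(path, "Strong")
  mo <- n(path, "Moderate"); su <- n(path, "Supporting")
  bs <- n(ben, "Strong") + n(ben, "VeryStrong")
  bp <- n(ben, "Supporting") + n(ben, "Moderate")

  if (nrow(path) > 0L) {
    if (vs >= 2L) {
      return(classification_result("P", pts, "rules", FALSE, ">=2 VeryStrong"))
    }
    if (vs >= 1L) {
      if (st >= 1L) return(classification_result("P", pts, "rules", FALSE,
                                                 "1 VeryStrong + >=1 Strong"))
      if (mo >= 2L) return(classification_result("P", pts, "rules", FALSE,
                                                 "1 VeryStrong + >=2 Moderate"))
      if (mo >= 1L && su >= 1L) {
        return(classification_result("P", pts, "rules", FALSE,
                                     "1 VeryStrong + 1 Moderate + >=1 Supporting"))
      }
      if (su >= 2L) return(classification_result("P", pts, "rules", FALSE,
                                                 "1 VeryStrong + >=2 Supporting"))
    }
    if (st >= 2L) {
      return(classification_result("P", pts, "rules", FALSE, ">=2 Strong"))
    }
    if (st >= 1L &&
        (mo >= 3L || (mo >= 2L && su >= 2L) || (mo >= 1L && su >= 4L))) {
      return(classification_result("P", pts, "rules", FALSE,
                                   "1 Strong + Moderate/Supporting combination"))
    }
    if (vs >= 1L && mo >= 1L) {
      return(classification_result("LP", pts, "rules", FALSE,
                                   "1 VeryStrong + 1 Moderate"))
    }
    if (st >= 1L && mo >= 1L) {
      return(classification_result("LP", pts, "rules", FALSE,
                                   "1 Strong + 1-2 Moderate"))
    }
    if (st >= 1L && su >= 2L) {
      return(classification_result("LP", pts, "rules", FALSE,
                                   "1 Strong + >=2 Supporting"))
    }
    if (mo >= 3L) {
      return(classification_result("LP", pts, "rules", FALSE, ">=3 Moderate"))
    }
    if (mo >= 2L && su >= 2L) {
      return(classification_result("LP", pts, "rules", FALSE,
                                   "2 Moderate + >=2 Supporting"))
    }
    if (mo >= 1L && su >= 4L) {
      return(classification_result("LP", pts, "rules", FALSE,
                                   "1 Moderate + >=4 Supporting"))
    }
  }
  if (nrow(ben) > 0L) {
    if (bs >= 2L) {
      return(classification_result("B", pts, "rules", FALSE, ">=2 Strong benign"))
    }
    if (bs >= 1L && bp >= 1L) {
      return(classification_result("LB", pts, "rules", FALSE,
                                   "1 Strong benign + >=1 Supporting benign"))
    }
    if (bp >= 2L) {
      return(classification_result("LB", pts, "rules", FALSE,
                                   ">=2 Supporting benign"))
    }
  }
  classification_result("VUS", pts, "rules", FALSE, "no combination met")
}

#' Classify a table of criteria strings
#'
#' Table-level convenience around [parse_criteria()], [classify_points()] and
#' [classify_rules()]: one row in, one row out, with both engines' calls.
#' Parse failures are reported with the offending row number.
#'
#' @param variants A data frame with at least the column named in
#'   `criteria_col`; typically also a variant identifier.
#' @param criteria_col Name of the column holding criteria strings.
#' @return The input tibble with added columns `tier_points`, `points`,
#'   `tier_rules`, `conflict` and `rule_path`. Rows with empty criteria
#'   strings get `NA` tiers.
#' @export
classify_variants <- function(variants, criteria_col = "criteria") {
  stopifnot(criteria_col %in% names(variants))
  out <- tibble::as_tibble(variants)
  res <- lapply(seq_len(nrow(out)), function(i) {
    txt <- out[[criteria_col]][i]
    if (is.na(txt) || !nzchar(trimws(txt))) {
      return(list(tier_points = NA_character_, points = NA_integer_,
                  tier_rules = NA_character_, conflict = NA,
                  rule_path = NA_character_))
    }
    set <- tryCatch(parse_criteria(txt), error = function(e) {
      stop("row ", i, ": ", conditionMessage(e), call. = FALSE)
    })
    p <- classify_points(set)
    r <- classify_rules(set)
    list(tier_points = p$tier, points = p$points, tier_rules = r$tier,
         conflict = p$conflict, rule_path = r$rule_path)
  })
  out$tier_points <- vapply(res, `[[`, character(1), "tier_points")
  out$points <- vapply(res, `[[`, integer(1), "points")
  out$tier_rules <- vapply(res, `[[`, character(1), "tier_rules")
  out$conflict <- vapply(res, `[[`, logical(1), "conflict")
  out$rule_path <- vapply(res, `[[`, character(1), "rule_path")
  out
}
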