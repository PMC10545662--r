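# 3-step re-analysis triage screen over annotated variant tables.

lof_consequence_default <- c("stop_gained", "frameshift", "splice_acceptor",
                             "splice_donor", "start_lost")

consequence_levels <- c(lof_consequence_default, "missense", "inframe_indel",
                        "synonymous", "intronic", "other")

#' Configuration of the triage screen
#'
#' The screen itself only says "rare"; the thresholds making that operational
#' are configurable here. Defaults are conventional rare-disease cutoffs:
#' population-maximum allele frequency below 0.1% for heterozygous candidates
#' (dominant/de novo model) and below 1% with no reference-population
#' homozygotes for homozygous or hemizygous candidates (recessive/X-linked
#' model). Start-loss counts as likely loss-of-function.
#'
#' @param rare_af_dominant Popmax allele-frequency cutoff for heterozygous
#'   variants (default 0.001).
#' @param rare_af_recessive Popmax cutoff for homozygous/hemizygous variants
#'   (default 0.01); must be >= `rare_af_dominant`.
#' @param max_homozygotes_recessive Maximum reference-database homozygote
#'   count tolerated for homozygous/hemizygous variants (default 0).
#' @param lof_consequences Consequence classes treated as likely
#'   loss-of-function.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(rare_af_dominant = 0.001,
                          rare_af_recessive = 0.01,
                          max_homozygotes_recessive = 0L,
                          lof_consequences = lof_consequence_default) {
  stopifnot(rare_af_dominant <= rare_af_recessive,
            rare_af_dominant >= 0, max_homozygotes_recessive >= 0)
  structure(list(rare_af_dominant = rare_af_dominant,
                 rare_af_recessive = rare_af_recessive,
                 max_homozygotes_recessive = as.integer(max_homozygotes_recessive),
                 lof_consequences = lof_consequences),
            class = "screen_config")
}

#' Pathogenicity knowledge base for the screen
#'
#' Abstracts ClinVar/HGMD-style knowledge into two deduplicated lookups so
#' that no live database is queried: known pathogenic variants (by opaque
#' variant key, matched exactly after whitespace normalisation) and gene/
#' protein positions carrying a known pathogenic missense variant.
#'
#' @param pathogenic_keys Character vector of variant keys.
#' @param pathogenic_positions Data frame with columns `gene` and `position`.
#' @return A list of class `knowledge_base`.
#' @export
knowledge_base <- function(pathogenic_keys = character(),
                           pathogenic_positions = NULL) {
  if (is.null(pathogenic_positions)) {
    pathogenic_positions <- tibble::tibble(gene = character(),
                                           position = integer())
  }
  pos <- tibble::as_tibble(pathogenic_positions)
  stopifnot(all(c("gene", "position") %in% names(pos)))
  pos <- unique(pos[, c("gene", "position")])
  pos$position <- as.integer(pos$position)
  structure(list(pathogenic_variant_keys = unique(normalize_key(pathogenic_keys)),
                 pathogenic_positions = pos),
            class = "knowledge_base")
}

normalize_key <- function(x) gsub("\\s+", "", x)

#' Rarity test behind the triage screen
#'
#' A heterozygous variant is rare when its popmax allele frequency is below
#' the dominant cutoff; a homozygous or hemizygous variant when its popmax
#' frequency is below the recessive cutoff and the reference database carries
#' no more than the tolerated number of homozygotes. A missing popmax
#' frequency counts as 0 (absent from references).
#'
#' @param variants Data frame of annotated variants (columns `zygosity`,
#'   `popmax_af`, `n_homozygotes_ref_db`; the latter defaults to 0 if absent).
#' @param cfg A [screen_config()].
#' @return Logical vector, one value per row.
#' @export
is_rare <- function(variants, cfg = screen_config()) {
  af <- variants$popmax_af
  af[is.na(af)] <- 0
  stopifnot(all(af >= 0 & af <= 1))
  nhom <- variants[["n_homozygotes_ref_db"]]
  if (is.null(nhom)) nhom <- rep(0L, nrow(variants))
  nhom[is.na(nhom)] <- 0L
  recessive <- variants$zygosity %in% c("homozygous", "hemizygous")
  ifelse(recessive,
         af < cfg$rare_af_recessive & nhom <= cfg$max_homozygotes_recessive,
         af < cfg$rare_af_dominant)
}

#' Run the 3-step triage screen
#'
#' Flags a variant when at least one rule fires:
#' * **A_rare_lof** — likely loss-of-function consequence and rare;
#' * **B_known_pathogenic** — variant key present in the knowledge base of
#'   known pathogenic variants;
#' * **C_missense_at_pathogenic_position** — rare missense variant at a
#'   protein position with a known pathogenic missense variant in the same
#'   gene (position only; the alternate residue is not compared).
#'
#' Variants with `quality_pass = FALSE` are skipped (excluded from screening
#' but tallied in the `skipped` attribute of the result). Input order is
#' preserved.
#'
#' @param variants Data frame of annotated variants with columns `variant_key`,
#'   `gene`, `consequence`, `zygosity`, `popmax_af`, and optionally
#'   `protein_position`, `n_homozygotes_ref_db`, `quality_pass`.
#' @param kb A [knowledge_base()].
#' @param cfg A [screen_config()].
#' @return Tibble of hits (subset of input rows) with an added `rules_fired`
#'   column (semicolon-joined rule tags); attribute `skipped` counts
#'   quality-failed rows.
#' @export
screen_variants <- function(variants, kb, cfg = screen_config()) {
  v <- tibble::as_tibble(variants)
  stopifnot(inherits(kb, "knowledge_base"))
  if (is.null(v[["quality_pass"]])) v$quality_pass <- TRUE
  skipped <- sum(!v$quality_pass)
  v_pass <- v[v$quality_pass, , drop = FALSE]

  rare <- is_rare(v_pass, cfg)
  rule_a <- v_pass$consequence %in% cfg$lof_consequences & rare

  rule_b <- normalize_key(v_pass$variant_key) %in% kb$pathogenic_variant_keys

  is_mis <- v_pass$consequence == "missense"
  rule_c <- rep(FALSE, nrow(v_pass))
  need_c <- which(is_mis & rare)
  if (length(need_c) > 0L) {
    pp <- v_pass[["protein_position"]]
    if (is.null(pp)) pp <- rep(NA_integer_, nrow(v_pass))
    bad <- need_c[is.na(pp[need_c])]
    if (length(bad) > 0L) {
      stop("missing protein_position for rare missense variant(s): ",
           paste(v_pass$variant_key[bad], collapse = ", "), call. = FALSE)
    }
    kb_pp <- paste(kb$pathogenic_positions$gene, kb$pathogenic_positions$position)
    rule_c[need_c] <- paste(v_pass$gene[need_c], pp[need_c]) %in% kb_pp
  }

  hit <- rule_a | rule_b | rule_c
  out <- v_pass[hit, , drop = FALSE]
  tags <- cbind(A_rare_lof = rule_a[hit], B_known_pathogenic = rule_b[hit],
                C_missense_at_pathogenic_position = rule_c[hit])
  out$rules_fired <- apply(tags, 1, function(r) {
    paste(colnames(tags)[r], collapse = ";")
  })
  attr(out, "skipped") <- skipped
  out
}

#' Inheritance-consistency annotation of variant candidates
#'
#' Retains variants compatible with at least one inheritance model for the
#' family at hand and annotates how they should be prioritised for manual
#' review. Homozygous variants inside a run of homozygosity are the core
#' expectation in consanguineous families and are flagged `prioritized`;
#' hemizygous variants cover the X-linked model; heterozygous variants are
#' retained in simplex families as possible de novo events, and in multiplex
#' families retained but flagged `caution` (an inherited heterozygous variant
#' shared by affected siblings from an unaffected parent needs extra
#' scrutiny, e.g. for parental mosaicism).
#'
#' @param variants Data frame with columns `zygosity` and optionally `in_roh`.
#' @param family_structure `"simplex"` or `"multiplex"`.
#' @param consanguineous Logical; consanguineous families never drop
#'   homozygous-in-RoH variants.
#' @return Tibble of retained variants with added logical columns
#'   `prioritized` and `caution`.
#' @export
inheritance_filter <- function(variants, family_structure = c("simplex", "multiplex"),
                               consanguineous = TRUE) {
  family_structure <- match.arg(family_structure)
  v <- tibble::as_tibble(variants)
  in_roh <- if (is.null(v[["in_roh"]])) rep(FALSE, nrow(v)) else v[["in_roh"]] %in% TRUE
  hom <- v$zygosity == "homozygous"
  hemi <- v$zygosity == "hemizygous"
  het <- v$zygosity == "heterozygous"
  keep <- hom | hemi | het
  # homozygous in-RoH variants are never dropped for consanguineous families
  if (consanguineous) keep <- keep | (hom & in_roh)
  out <- v[keep, , drop = FALSE]
  hom_k <- hom[keep]; het_k <- het[keep]; roh_k <- in_roh[keep]
  out$prioritized <- hom_k & roh_k & consanguineous
  out$caution <- het_k & family_structure == "multiplex"
  out
}
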