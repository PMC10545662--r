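# Gene-disease association (GDA) validity from literature evidence.

gda_tiers <- c("candidate", "published_candidate", "established")

#' Parse a literature evidence count
#'
#' Evidence cells in curation tables often give lower bounds such as `">14"`.
#' For threshold rules a lower bound suffices, so `">N"` is read as `N`.
#'
#' @param x Character or numeric vector of counts, possibly `">"`-prefixed.
#' @return Integer vector.
#' @export
#' @examples
#' parse_evidence_count(c("11", ">14", 3))
parse_evidence_count <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  out <- as.integer(sub("^\\s*>\\s*", "", trimws(as.character(x))))
  if (anyNA(out) && !anyNA(x)) stop("unparseable evidence count", call. = FALSE)
  out
}

#' Construct a gene-evidence record
#'
#' @param gene Gene symbol.
#' @param n_affected Reported affected individuals (accepts `">N"`).
#' @param n_families Reported families (accepts `">N"`).
#' @param n_groups Independent research groups with separate publications
#'   (accepts `">N"`); co-authored joint papers count once.
#' @param has_functional Wet-lab functional data interrogating the gene
#'   product's function (animal models included; bare expression assays such
#'   as RT-PCR or western blot do not count).
#' @param screening_only Gene only ever reported in large screening cohorts.
#' @return A list of class `gene_evidence`.
#' @export
gene_evidence <- function(gene, n_affected, n_families, n_groups,
                          has_functional = FALSE, screening_only = FALSE) {
  ev <- list(gene = gene,
             n_affected = parse_evidence_count(n_affected),
             n_families = parse_evidence_count(n_families),
             n_groups = parse_evidence_count(n_groups),
             has_functional = isTRUE(has_functional),
             screening_only = isTRUE(screening_only))
  if (ev$n_affected < 0 || ev$n_families < 0 || ev$n_groups < 0) {
    stop("evidence counts must be non-negative", call. = FALSE)
  }
  if (ev$n_affected > 0 && ev$n_families > 0 && ev$n_families > ev$n_affected) {
    stop("n_families cannot exceed n_affected", call. = FALSE)
  }
  structure(ev, class = "gene_evidence")
}

#' Classify gene-disease association validity
#'
#' A GDA is `established` when at least three families have been reported by
#' at least two independent research groups in separate publications, or when
#' functional data compensates for thinner count evidence (at least one
#' reported family plus wet-lab functional or animal-model data). Genes with a
#' published phenotype association below this confidence are
#' `published_candidate`; genes only seen in large screening cohorts (or with
#' no phenotype publication at all beyond the screen) are `candidate`.
#'
#' @param evidence A [gene_evidence()] record.
#' @return A list with `tier` (one of `"established"`, `"published_candidate"`,
#'   `"candidate"`) and a `rationale` string naming the clause that fired.
#' @export
#' @examples
#' classify_gda(gene_evidence("DARS2", 11, 8, 2))
#' classify_gda(gene_evidence("TSEN15", 5, 3, 1))
classify_gda <- function(evidence) {
  stopifnot(inherits(evidence, "gene_evidence"))
  e <- evidence
  if (e$screening_only) {
    return(list(tier = "candidate",
                rationale = "only reported in large screening cohorts"))
  }
  published <- e$n_families >= 1 || e$n_groups >= 1
  if (!published) {
    stop("invalid evidence for ", e$gene,
         ": no published phenotype association and not screening-only",
         call. = FALSE)
  }
  if (e$n_families >= 3 && e$n_groups >= 2) {
    return(list(tier = "established",
                rationale = sprintf(
                  ">=3 families (%d) reported by >=2 independent groups (%d)",
                  e$n_families, e$n_groups)))
  }
  if (e$has_functional && e$n_families >= 1) {
    return(list(tier = "established",
                rationale = sprintf(
                  "functional data compensating for limited reports (%d families, %d groups)",
                  e$n_families, e$n_groups)))
  }
  list(tier = "published_candidate",
       rationale = sprintf(
         "phenotype association published but below confidence threshold (%d families, %d groups, %s functional data)",
         e$n_families, e$n_groups, if (e$has_functional) "with" else "no"))
}

#' Classify a table of gene-evidence tuples
#'
#' @param genes Data frame with columns `gene`, `n_affected`, `n_families`,
#'   `n_groups`, `has_functional`, `screening_only` (the last two optional,
#'   default `FALSE`); count columns accept `">N"` strings.
#' @return The input as a tibble with added `tier` and `rationale` columns.
#' @export
classify_gda_table <- function(genes) {
  out <- tibble::as_tibble(genes)
  if (is.null(out[["has_functional"]])) out$has_functional <- FALSE
  if (is.null(out[["screening_only"]])) out$screening_only <- FALSE
  res <- lapply(seq_len(nrow(out)), function(i) {
    classify_gda(gene_evidence(out$gene[i], out$n_affected[i],
                               out$n_families[i], out$n_groups[i],
                               out$has_functional[i], out$screening_only[i]))
  })
  out$tier <- vapply(res, `[[`, character(1), "tier")
  out$rationale <- vapply(res, `[[`, character(1), "rationale")
  out
}
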