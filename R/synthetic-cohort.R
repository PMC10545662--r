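# Synthetic cohort and variant-table generator.
#
# Emulates a consanguineous NDD exome screening cohort: family strata
# (simplex / multiplex by number of affected), sex ratio, a platform-quality
# mix driving the background count of rare homozygous calls per family, and
# planted causal variants with configurable detection profiles so that the
# triage screen and the accounting stages can be exercised against known
# ground truth.

#' Cohort specification
#'
#' Defaults reproduce the structure of a 152-family consanguineous cohort:
#' 44 simplex families with one affected child, 79 multiplex families with
#' two, 24 with three and 5 with four or more; 63% of affected individuals
#' male; and a 35% share of families sequenced on an older, lower-quality
#' platform (short-read SOLiD-era data vs modern Illumina).
#'
#' @param n_simplex,n_multiplex_2,n_multiplex_3,n_multiplex_4plus Stratum
#'   sizes (default 44/79/24/5).
#' @param male_fraction Probability an affected individual is male.
#' @param platform_mix Fraction of families on the low-quality platform.
#' @param seed Integer seed making the cohort reproducible.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_simplex = 44L, n_multiplex_2 = 79L,
                        n_multiplex_3 = 24L, n_multiplex_4plus = 5L,
                        male_fraction = 0.63, platform_mix = 0.35,
                        seed = 1L) {
  counts <- c(n_simplex, n_multiplex_2, n_multiplex_3, n_multiplex_4plus)
  if (any(counts < 0)) stop("stratum counts must be non-negative", call. = FALSE)
  stopifnot(male_fraction >= 0, male_fraction <= 1,
            platform_mix >= 0, platform_mix <= 1)
  structure(list(n_simplex = as.integer(n_simplex),
                 n_multiplex_2 = as.integer(n_multiplex_2),
                 n_multiplex_3 = as.integer(n_multiplex_3),
                 n_multiplex_4plus = as.integer(n_multiplex_4plus),
                 male_fraction = male_fraction,
                 platform_mix = platform_mix,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Background-noise model for filtered variant counts
#'
#' Per-family counts of rare homozygous calls surviving filtering follow a
#' negative-binomial-shaped discrete distribution calibrated so that its
#' median matches the configured platform median: 28.5 on the low-quality
#' platform versus 10 on the high-quality one (lower coverage and quality
#' leave more calls after filtering). `dispersion` is the negative-binomial
#' size parameter; `het_artifact_rate` adds that fraction of extra
#' heterozygous artifact calls on the low-quality platform.
#'
#' @param background_hom_median_lowq,background_hom_median_highq Target
#'   medians of filtered homozygous calls per family (defaults 28.5 and 10).
#' @param het_artifact_rate Fraction of additional heterozygous artifact
#'   calls relative to the homozygous background (default 0.2).
#' @param dispersion Negative-binomial size parameter (default 8).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(background_hom_median_lowq = 28.5,
                        background_hom_median_highq = 10,
                        het_artifact_rate = 0.2,
                        dispersion = 8) {
  stopifnot(background_hom_median_lowq > background_hom_median_highq,
            dispersion > 0, het_artifact_rate >= 0)
  structure(list(background_hom_median_lowq = background_hom_median_lowq,
                 background_hom_median_highq = background_hom_median_highq,
                 het_artifact_rate = het_artifact_rate,
                 dispersion = dispersion),
            class = "noise_model")
}

# Negative-binomial mean giving a distribution median at the target count:
# solves P(X <= floor(target)) = 0.5 in mu, which is continuous and
# monotone even though the quantile itself is a step function.
nb_mu_for_median <- function(target, size) {
  k <- floor(target)
  f <- function(mu) stats::pnbinom(k, size = size, mu = mu) - 0.5
  stats::uniroot(f, lower = max(target / 4, 0.1), upper = target * 4,
                 extendInt = "yes")$root
}

#' Planted-causal-variant specification
#'
#' Controls the ground truth of a synthetic variant table. Each causal family
#' receives one planted variant drawn from a profile mix describing how the
#' 3-step triage screen can detect it: a rare loss-of-function variant
#' (rule A), a known pathogenic missense variant whose key is written into
#' the knowledge base (rule B), a rare missense variant at a protein position
#' carrying a known pathogenic variant (rule C), or an `undetectable` variant
#' that the screen cannot flag (e.g. a de novo missense absent from the
#' databases) — still disease-causing, with a criteria profile classifying
#' P/LP. Default mix 5:4:1:2 over A/B/C/undetectable; default causal-family
#' fraction 0.41 (a realistic consanguineous-NDD diagnostic yield).
#'
#' @param fraction_families_with_causal Probability a family carries a
#'   planted causal variant (default 0.41).
#' @param causal_profile_mix Named weights over `rare_lof`,
#'   `known_pathogenic_missense`, `missense_at_pathogenic_position`,
#'   `undetectable`; normalised to sum to 1.
#' @param criteria_template Named character vector mapping each profile to the
#'   applied-criteria string its variant is assigned.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(fraction_families_with_causal = 0.41,
                       causal_profile_mix = c(rare_lof = 5,
                                              known_pathogenic_missense = 4,
                                              missense_at_pathogenic_position = 1,
                                              undetectable = 2),
                       criteria_template = c(
                         rare_lof = "PVS1,PM2,PM3",
                         known_pathogenic_missense = "PS1,PS3,PM2",
                         missense_at_pathogenic_position = "PM5,PM1,PM2,PP3",
                         undetectable = "PS2,PM2,PP1")) {
  profiles <- c("rare_lof", "known_pathogenic_missense",
                "missense_at_pathogenic_position", "undetectable")
  stopifnot(fraction_families_with_causal >= 0,
            fraction_families_with_causal <= 1,
            setequal(names(causal_profile_mix), profiles),
            all(causal_profile_mix >= 0), sum(causal_profile_mix) > 0,
            all(profiles %in% names(criteria_template)))
  structure(list(fraction_families_with_causal = fraction_families_with_causal,
                 causal_profile_mix =
                   causal_profile_mix[profiles] / sum(causal_profile_mix),
                 criteria_template = criteria_template[profiles]),
            class = "plant_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a synthetic family cohort
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with one row per family: `family_id`, `stratum`,
#'   `n_affected`, `n_affected_male`, `consanguineous` (always `TRUE`),
#'   `platform` (`"lowq"` or `"highq"`). Reproducible for a fixed
#'   `spec$seed`.
#' @export
#' @examples
#' generate_cohort(cohort_spec())
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  strata <- rep(c("simplex", "multiplex_2", "multiplex_3", "multiplex_4plus"),
                c(spec$n_simplex, spec$n_multiplex_2, spec$n_multiplex_3,
                  spec$n_multiplex_4plus))
  n <- length(strata)
  if (n == 0L) {
    return(tibble::tibble(family_id = character(), stratum = character(),
                          n_affected = integer(), n_affected_male = integer(),
                          consanguineous = logical(), platform = character()))
  }
  with_seed(spec$seed, {
    n_aff <- c(simplex = 1L, multiplex_2 = 2L, multiplex_3 = 3L,
               multiplex_4plus = 4L)[strata]
    tibble::tibble(
      family_id = sprintf("SIM%04d", seq_len(n)),
      stratum = strata,
      n_affected = unname(n_aff),
      n_affected_male = stats::rbinom(n, n_aff, spec$male_fraction),
      consanguineous = TRUE,
      platform = ifelse(stats::runif(n) < spec$platform_mix, "lowq", "highq")
    )
  })
}

#' Generate a synthetic annotated variant table with planted causal variants
#'
#' Background variants per family are rare homozygous calls (count drawn from
#' the platform-calibrated negative binomial) plus heterozygous artifact
#' calls on the low-quality platform; background consequences are missense,
#' synonymous or intronic, at positions absent from the knowledge base, so
#' the triage screen by construction never flags them. Causal variants are
#' planted per [plant_spec()]; for the `known_pathogenic_missense` profile
#' the variant's key is inserted into the knowledge base, for
#' `missense_at_pathogenic_position` its gene and protein position are.
#' Decoy knowledge-base entries are added on top.
#'
#' @param families Cohort tibble from [generate_cohort()].
#' @param noise A [noise_model()].
#' @param plant A [plant_spec()].
#' @param n_decoy_keys,n_decoy_positions Decoy knowledge-base entries.
#' @param seed Integer seed.
#' @return List with `variants` (annotated variant tibble), `kb`
#'   ([knowledge_base()]) and `truth` (one row per planted variant:
#'   `family_id`, `variant_key`, `profile`, `criteria`, `detectable`).
#' @export
generate_variant_table <- function(families, noise = noise_model(),
                                   plant = plant_spec(),
                                   n_decoy_keys = 50L, n_decoy_positions = 50L,
                                   seed = 1L) {
  stopifnot(inherits(noise, "noise_model"), inherits(plant, "plant_spec"))
  fam <- tibble::as_tibble(families)
  n_fam <- nrow(fam)
  mu_low <- nb_mu_for_median(noise$background_hom_median_lowq, noise$dispersion)
  mu_high <- nb_mu_for_median(noise$background_hom_median_highq, noise$dispersion)
  profiles <- names(plant$causal_profile_mix)

  with_seed(seed, {
    # -- background --
    mu <- ifelse(fam$platform == "lowq", mu_low, mu_high)
    n_hom <- stats::rnbinom(n_fam, size = noise$dispersion, mu = mu)
    n_het <- stats::rpois(n_fam,
                          ifelse(fam$platform == "lowq",
                                 noise$het_artifact_rate * n_hom, 0))
    bg_one <- function(fid, n, zyg) {
      if (n == 0L) return(NULL)
      tibble::tibble(
        family_id = fid,
        gene = sprintf("BGGENE%04d", sample.int(5000L, n, replace = TRUE)),
        variant_key = sprintf("%s:%s:c.%d%s>%s", fid,
                              sprintf("bg%03d", seq_len(n)),
                              sample.int(5000L, n, replace = TRUE),
                              sample(c("A", "C", "G", "T"), n, TRUE),
                              sample(c("A", "C", "G", "T"), n, TRUE)),
        consequence = sample(c("missense", "synonymous", "intronic"), n, TRUE,
                             prob = c(0.5, 0.3, 0.2)),
        zygosity = zyg,
        popmax_af = stats::rbeta(n, 0.5, 200),
        n_homozygotes_ref_db = 0L,
        protein_position = sample.int(2000L, n, replace = TRUE),
        in_roh = zyg == "homozygous" & stats::runif(n) < 0.8,
        quality_pass = TRUE,
        causal = FALSE,
        criteria = ""
      )
    }
    bg <- do.call(rbind, c(
      lapply(seq_len(n_fam), function(i) bg_one(fam$family_id[i], n_hom[i],
                                                "homozygous")),
      lapply(seq_len(n_fam), function(i) bg_one(fam$family_id[i], n_het[i],
                                                "heterozygous"))))

    # -- plants --
    causal_fam <- which(stats::runif(n_fam) < plant$fraction_families_with_causal)
    prof <- if (length(causal_fam) > 0L) {
      sample(profiles, length(causal_fam), replace = TRUE,
             prob = plant$causal_profile_mix)
    } else character()
    plant_rows <- lapply(seq_along(causal_fam), function(j) {
      i <- causal_fam[j]; p <- prof[j]
      gene <- sprintf("CAUSAL%04d", j)
      pos <- sample.int(1500L, 1L)
      key <- sprintf("%s:c.%d%s>%s", gene, pos * 3L,
                     sample(c("A", "C", "G", "T"), 1L),
                     sample(c("A", "C", "G", "T"), 1L))
      cons <- if (p == "rare_lof") {
        sample(lof_consequence_default, 1L)
      } else "missense"
      tibble::tibble(family_id = fam$family_id[i], gene = gene,
                     variant_key = key, consequence = cons,
                     zygosity = sample(c("homozygous", "heterozygous"), 1L,
                                       prob = c(0.7, 0.3)),
                     popmax_af = 0, n_homozygotes_ref_db = 0L,
                     protein_position = pos,
                     in_roh = TRUE, quality_pass = TRUE, causal = TRUE,
                     criteria = unname(plant$criteria_template[p]))
    })
    plants <- do.call(rbind, plant_rows)

    kb_keys <- character()
    kb_pos <- tibble::tibble(gene = character(), position = integer())
    if (!is.null(plants)) {
      kb_keys <- plants$variant_key[prof == "known_pathogenic_missense"]
      cpos <- plants[prof == "missense_at_pathogenic_position", ]
      kb_pos <- tibble::tibble(gene = cpos$gene,
                               position = as.integer(cpos$protein_position))
    }
    # decoys use a gene namespace disjoint from background and plants
    if (n_decoy_keys > 0L) {
      kb_keys <- c(kb_keys, sprintf("DECOY%04d:c.%dA>G", seq_len(n_decoy_keys),
                                    sample.int(5000L, n_decoy_keys, TRUE)))
    }
    if (n_decoy_positions > 0L) {
      kb_pos <- rbind(kb_pos,
                      tibble::tibble(gene = sprintf("DECOY%04d",
                                                    seq_len(n_decoy_positions)),
                                     position = sample.int(2000L,
                                                           n_decoy_positions,
                                                           TRUE)))
    }

    variants <- rbind(bg, plants)
    if (is.null(variants)) {
      variants <- tibble::tibble(
        family_id = character(), gene = character(), variant_key = character(),
        consequence = character(), zygosity = character(), popmax_af = numeric(),
        n_homozygotes_ref_db = integer(), protein_position = integer(),
        in_roh = logical(), quality_pass = logical(), causal = logical(),
        criteria = character())
    }
    truth <- if (is.null(plants)) {
      tibble::tibble(family_id = character(), variant_key = character(),
                     profile = character(), criteria = character(),
                     detectable = logical())
    } else {
      tibble::tibble(family_id = plants$family_id,
                     variant_key = plants$variant_key,
                     profile = prof,
                     criteria = plants$criteria,
                     detectable = prof != "undetectable")
    }
    list(variants = variants,
         kb = knowledge_base(kb_keys, kb_pos),
         truth = truth)
  })
}
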