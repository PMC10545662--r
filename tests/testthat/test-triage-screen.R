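mkvar <- function(variant_key = "G:c.1A>T", gene = "G",
                  consequence = "missense", zygosity = "heterozygous",
                  popmax_af = 0, n_homozygotes_ref_db = 0L,
                  protein_position = NA_integer_, in_roh = FALSE,
                  quality_pass = TRUE) {
  tibble::tibble(variant_key = variant_key, gene = gene,
                 consequence = consequence, zygosity = zygosity,
                 popmax_af = popmax_af,
                 n_homozygotes_ref_db = n_homozygotes_ref_db,
                 protein_position = protein_position, in_roh = in_roh,
                 quality_pass = quality_pass)
}

test_that("rarity uses the dominant cutoff for heterozygous and the recessive cutoff plus homozygote count otherwise", {
  cfg <- screen_config()
  expect_true(is_rare(mkvar(popmax_af = 0), cfg))
  expect_false(is_rare(mkvar(popmax_af = 0.05), cfg))
  expect_true(is_rare(mkvar(zygosity = "homozygous", popmax_af = 0.005), cfg))
  expect_false(is_rare(mkvar(zygosity = "homozygous", popmax_af = 0.005,
                             n_homozygotes_ref_db = 3L), cfg))
  expect_false(is_rare(mkvar(popmax_af = 0.005), cfg))  # het: dominant cutoff
  expect_true(is_rare(mkvar(popmax_af = NA_real_), cfg))  # absent counts as 0
  expect_error(screen_config(rare_af_dominant = 0.05, rare_af_recessive = 0.01))
})

test_that("the three screen rules fire independently and are tagged", {
  kb <- knowledge_base("GCDH:c.1204C>T",
                       tibble::tibble(gene = "GRIN2A", position = 693L))
  vs <- rbind(
    mkvar("ZEB2:c.2177_2178del", "ZEB2", "frameshift"),
    mkvar("GCDH:c.1204C>T", "GCDH", "missense", "homozygous",
          popmax_af = 0.02, protein_position = 402L),  # not rare: B only
    mkvar("GRIN2A:c.2077A>G", "GRIN2A", "missense", protein_position = 693L),
    mkvar("X:c.1G>A", "X", "synonymous"),
    mkvar("Y:c.2G>A", "Y", "missense", protein_position = 12L))
  hits <- screen_variants(vs, kb)
  expect_equal(hits$variant_key,
               c("ZEB2:c.2177_2178del", "GCDH:c.1204C>T", "GRIN2A:c.2077A>G"))
  expect_equal(hits$rules_fired,
               c("A_rare_lof", "B_known_pathogenic",
                 "C_missense_at_pathogenic_position"))
  # variant-key match survives whitespace differences
  hits2 <- screen_variants(mkvar("GCDH : c.1204 C>T", "GCDH", "missense",
                                 "homozygous", popmax_af = 0.02,
                                 protein_position = 402L), kb)
  expect_equal(nrow(hits2), 1L)
})

test_that("a rare missense without protein position is an annotation error; quality failures are skipped and tallied", {
  kb <- knowledge_base()
  expect_error(screen_variants(mkvar("A:c.1A>T", "A", "missense"), kb),
               "protein_position")
  v <- mkvar("A:c.1A>T", "A", "frameshift", quality_pass = FALSE)
  hits <- screen_variants(v, kb)
  expect_equal(nrow(hits), 0L)
  expect_equal(attr(hits, "skipped"), 1L)
})

test_that("screen output is a subset, idempotent, and the union of the single-rule screens", {
  fams <- generate_cohort(cohort_spec(n_simplex = 10, n_multiplex_2 = 10,
                                      n_multiplex_3 = 0, n_multiplex_4plus = 0,
                                      seed = 5))
  gen <- generate_variant_table(fams, seed = 5)
  cfg <- screen_config()
  hits <- screen_variants(gen$variants, gen$kb, cfg)
  expect_true(all(hits$variant_key %in% gen$variants$variant_key))
  again <- screen_variants(hits[names(gen$variants)], gen$kb, cfg)
  expect_equal(again$variant_key, hits$variant_key)
  expect_equal(again$rules_fired, hits$rules_fired)

  # union decomposition: each rule's membership matches the tags
  no_lof <- screen_config(lof_consequences = character(0))
  only_a <- setdiff(hits$variant_key,
                    screen_variants(gen$variants, gen$kb, no_lof)$variant_key)
  expect_setequal(only_a,
                  hits$variant_key[hits$rules_fired == "A_rare_lof"])
  empty_kb <- knowledge_base()
  ab <- screen_variants(gen$variants, empty_kb, cfg)
  expect_true(all(ab$rules_fired == "A_rare_lof"))
  expect_true(all(ab$variant_key %in%
                    hits$variant_key[grepl("A_rare_lof", hits$rules_fired)]))
})

test_that("tightening rarity thresholds never enlarges the hit set", {
  fams <- generate_cohort(cohort_spec(n_simplex = 15, n_multiplex_2 = 5,
                                      n_multiplex_3 = 0, n_multiplex_4plus = 0,
                                      seed = 9))
  gen <- generate_variant_table(fams, seed = 9)
  loose <- screen_variants(gen$variants, gen$kb,
                           screen_config(rare_af_dominant = 0.005,
                                         rare_af_recessive = 0.05,
                                         max_homozygotes_recessive = 5))
  tight <- screen_variants(gen$variants, gen$kb,
                           screen_config(rare_af_dominant = 0.0001,
                                         rare_af_recessive = 0.001))
  expect_true(all(tight$variant_key %in% loose$variant_key))
})

test_that("inheritance annotation keeps de novo candidates in simplex families and flags multiplex heterozygous sharing", {
  v <- rbind(mkvar("H:c.1A>T", "H", "missense", "homozygous",
                   protein_position = 1L, in_roh = TRUE),
             mkvar("D:c.2A>T", "D", "missense", "heterozygous",
                   protein_position = 2L))
  sim <- inheritance_filter(v, "simplex", consanguineous = TRUE)
  expect_equal(nrow(sim), 2L)            # de novo possible despite consanguinity
  expect_true(sim$prioritized[sim$gene == "H"])   # homozygous in RoH
  expect_false(any(sim$caution))
  mult <- inheritance_filter(v, "multiplex", consanguineous = TRUE)
  expect_true(mult$caution[mult$gene == "D"])     # shared het from unaffected parent
  expect_true("H" %in% mult$gene)        # homozygous-in-RoH never dropped
})
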