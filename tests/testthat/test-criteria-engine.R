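test_that("criteria strings parse into applied criteria with modifiers and annotations", {
  s <- parse_criteria("PVS1,PS2_Strong,PM2")
  expect_equal(s$code, c("PVS1", "PS2", "PM2"))
  expect_equal(s$effective_strength, c("VeryStrong", "Strong", "Moderate"))
  expect_equal(s$annotation, c("", "", ""))

  # modifier casing is irrelevant; parenthetical comments are preserved verbatim
  s <- parse_criteria("PS4_supporting,PM2,PM3,PP1_Strong,PP3(accordingtounpublisheddata)")
  expect_equal(s$effective_strength,
               c("Supporting", "Moderate", "Moderate", "Strong", "Supporting"))
  expect_equal(s$annotation[5], "accordingtounpublisheddata")
  expect_equal(s$code[5], "PP3")

  expect_equal(nrow(parse_criteria("")), 0L)
  expect_equal(nrow(parse_criteria(NA_character_)), 0L)

  # whitespace tolerance
  expect_equal(parse_criteria(" PM2 , PP3 ")$code, c("PM2", "PP3"))
})

test_that("malformed criteria strings are rejected with informative errors", {
  expect_error(parse_criteria("PM2,PX9"), "unknown ACMG criterion")
  expect_error(parse_criteria("PM2,PM2_Supporting"), "duplicate criterion")
  expect_error(parse_criteria("PM2_Weak"), "malformed strength modifier")
  expect_error(parse_criteria("PM2_Very Strong"), "malformed")
})

test_that("criterion points follow the strength table with benign negation", {
  pts <- criterion_points(parse_criteria("PVS1,BS3,PM3_Supporting,BA1,PP1"))
  expect_identical(pts, c(8L, -4L, 1L, -8L, 1L))
})

test_that("points engine sums evidence and maps onto the five-tier bounds", {
  r <- classify_points(parse_criteria("PVS1,PS2_Strong,PM2"))
  expect_equal(r$tier, "P")
  expect_equal(r$points, 14L)
  expect_false(r$conflict)

  r <- classify_points(parse_criteria("BS1,BS2"))
  expect_equal(r$tier, "B")
  expect_equal(r$points, -8L)

  # conflicting directions sum through but flag the conflict
  r <- classify_points(parse_criteria("PVS1_Strong,PM2,BS3"))
  expect_equal(r$tier, "VUS")
  expect_equal(r$points, 2L)
  expect_true(r$conflict)

  r <- classify_points(parse_criteria(""))
  expect_equal(r$tier, "VUS")
  expect_equal(r$points, 0L)
})

test_that("tier bounds partition the integers at the documented cut points", {
  tiers <- vapply(-30:30, exomereval:::points_tier, character(1))
  expect_true(all(tiers %in% c("P", "LP", "VUS", "LB", "B")))
  # boundaries: B <= -7 < LB <= -1 < VUS <= 5 < LP <= 9 < P
  expect_equal(unname(tiers[match(c(-7, -6, -1, 0, 5, 6, 9, 10), -30:30)]),
               c("B", "LB", "LB", "VUS", "VUS", "LP", "LP", "P"))
  expect_equal(rle(tiers)$values, c("B", "LB", "VUS", "LP", "P"))
})

test_that("rules engine applies the published evidence combinations", {
  expect_equal(classify_rules(parse_criteria("PS3,PM2,PM3,PP1_Moderate"))$tier, "P")
  expect_equal(classify_rules(parse_criteria("PM2,PP3"))$tier, "VUS")
  expect_equal(classify_rules(parse_criteria("PM2,PP1_Moderate,PP2,PP3"))$tier, "LP")
  expect_equal(classify_rules(parse_criteria("PVS1,PM2"))$tier, "LP")
  expect_equal(classify_rules(parse_criteria("PVS1,PM2,PM3_Supporting"))$tier, "P")
  expect_equal(classify_rules(parse_criteria("BS1,BP4"))$tier, "LB")
  expect_equal(classify_rules(parse_criteria("BP4,BP7"))$tier, "LB")
  expect_equal(classify_rules(parse_criteria("BS1,BS2"))$tier, "B")
  # mixed evidence directions never average
  r <- classify_rules(parse_criteria("PVS1_Strong,PM2,BS3"))
  expect_equal(r$tier, "VUS")
  expect_true(r$conflict)
})

test_that("BA1 is stand-alone benign in both engines", {
  for (f in list(classify_points, classify_rules)) {
    expect_equal(f(parse_criteria("BA1"))$tier, "B")
    expect_equal(f(parse_criteria("PVS1,PS1,BA1"))$tier, "B")
  }
})

test_that("canonical serialization round-trips and emits modifiers only off base", {
  # PS2's base strength already is Strong, so the modifier is redundant and
  # dropped from the canonical form
  expect_equal(format_criteria(parse_criteria("PVS1, PS2_Strong ,PM2")),
               "PVS1,PS2,PM2")
  expect_equal(format_criteria(parse_criteria("PS4_supporting,PM2")),
               "PS4_Supporting,PM2")
  expect_equal(format_criteria(parse_criteria("PM3_moderate")), "PM3")
  set.seed(42)
  for (i in 1:50) {
    s <- parse_criteria(random_criteria_string())
    s2 <- parse_criteria(format_criteria(s))
    expect_equal(s2$code, s$code)
    expect_equal(s2$effective_strength, s$effective_strength)
  }
})

test_that("classification is invariant under permutation of the criteria", {
  set.seed(7)
  for (i in 1:25) {
    txt <- random_criteria_string(include_ba1 = TRUE)
    s <- parse_criteria(txt)
    perm <- s[sample.int(nrow(s)), ]
    expect_equal(classify_points(perm)$tier, classify_points(s)$tier)
    expect_equal(classify_points(perm)$points, classify_points(s)$points)
    expect_equal(classify_rules(perm)$tier, classify_rules(s)$tier)
  }
})

test_that("points total is monotone in added evidence", {
  set.seed(11)
  codes <- acmg_codes()
  for (i in 1:40) {
    s <- parse_criteria(random_criteria_string())
    base_pts <- classify_points(s)$points
    extra <- codes[!(codes$code %in% s$code), ]
    add <- extra[sample.int(nrow(extra), 1), ]
    s2 <- parse_criteria(paste(c(format_criteria(s), add$code), collapse = ","))
    delta <- classify_points(s2)$points - base_pts
    if (add$direction == "pathogenic") expect_gte(delta, 0) else expect_lte(delta, 0)
  }
})

test_that("classify_variants reports parse failures with the row number", {
  df <- tibble::tibble(variant_id = c("a", "b"), criteria = c("PM2", "NOPE1"))
  expect_error(classify_variants(df), "row 2")
  # a genuine engine divergence: very strong + moderate reaches 10 points
  # but only the likely-pathogenic rule combination
  out <- classify_variants(tibble::tibble(criteria = c("PVS1,PM2", "")))
  expect_equal(out$tier_points, c("P", NA))
  expect_equal(out$tier_rules, c("LP", NA))
})
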