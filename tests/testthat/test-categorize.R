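test_that("name rules classify canonical labels", {
  rb <- default_rulebook()
  gov <- classify_by_name("government hospital", rulebook = rb)
  expect_equal(
    unlist(gov[c("facility_status", "level", "sector")], use.names = FALSE),
    c("facility", "hospital", "public")
  )
  home <- classify_by_name("home", rulebook = rb)
  expect_equal(home$facility_status, "non_facility")
  expect_equal(home$level, "not_applicable")
  expect_equal(home$sector, "not_applicable")

  clin <- classify_by_name("clinic", rulebook = rb)
  expect_equal(
    unlist(clin[c("facility_status", "level", "sector")], use.names = FALSE),
    c("facility", "unknown_level", "unknown_sector")
  )

  fallback <- classify_by_name("", rulebook = rb)
  expect_equal(fallback$facility_status, "unknown")

  # case/whitespace folding
  expect_equal(
    classify_by_name("  Government   HOSPITAL ", rulebook = rb),
    gov
  )
})

test_that("classification is deterministic and mutually exclusive", {
  rb <- default_rulebook()
  labels <- c(
    "government hospital", "private clinic", "maternity home", "hospital",
    "health post", "clinic", "home", "", "polyclinic", "mission hospital"
  )
  for (lab in labels) {
    a1 <- classify_by_name(lab, rulebook = rb)
    a2 <- classify_by_name(lab, rulebook = rb)
    expect_identical(a1, a2)
    # exactly one value per axis
    expect_length(a1$level, 1)
    expect_length(a1$sector, 1)
    # level/sector applicable iff facility
    expect_identical(
      a1$facility_status == "facility",
      a1$level != "not_applicable"
    )
    expect_identical(
      a1$facility_status == "facility",
      a1$sector != "not_applicable"
    )
  }
})

test_that("country overrides take precedence over generic rules", {
  rb <- default_rulebook()
  rb$overrides <- tibble::tibble(
    location_id = "C1", label = "clinic",
    facility_status = "facility", level = "hospital", sector = "public"
  )
  hit <- classify_by_name("clinic", "C1", rb)
  expect_equal(hit$level, "hospital")
  expect_equal(hit$provenance, "country_literature")
  # other countries still use the generic rule
  miss <- classify_by_name("clinic", "C2", rb)
  expect_equal(miss$level, "unknown_level")
})

test_that("caesarean sorting assigns the nearest comparator level", {
  # rate 0.20 is nearer the hospital comparator 0.18 than lower 0.02
  expect_equal(classify_by_csection(100, 20, 0.18, 0.02), "hospital")
  # exact match to the lower comparator
  expect_equal(classify_by_csection(100, 2, 0.18, 0.02), "lower")
  # equidistant tie stays unknown
  expect_equal(classify_by_csection(100, 10, 0.18, 0.02), "unknown_level")
  # below the minimum weighted count stays unknown
  expect_equal(classify_by_csection(10, 2, 0.18, 0.02), "unknown_level")
  expect_error(classify_by_csection(0, 0, 0.18, 0.02), "zero")
})

test_that("non-profit merge is correct and idempotent", {
  x <- c(
    "public", "private_non_profit", "private_for_profit",
    "unknown_sector", "not_applicable"
  )
  merged <- merge_nonprofit(x)
  expect_equal(merged, c(
    "public_nfp", "public_nfp", "private_fp", "unknown_sector",
    "not_applicable"
  ))
  expect_equal(merge_nonprofit(merged), merged)
})

test_that("completeness fractions are weighted over facility births only", {
  opts <- tibble::tibble(
    weighted_count = c(90, 6, 4, 50),
    facility_status = c("facility", "facility", "facility", "non_facility"),
    level = c("hospital", "lower", "unknown_level", "not_applicable"),
    sector = c("public", "unknown_sector", "unknown_sector", "not_applicable")
  )
  f <- known_information_fractions(opts)
  expect_equal(f$f_both, 0.90)
  expect_equal(f$f_level, 0.96)

  # fully categorised
  full <- known_information_fractions(opts[1, ])
  expect_equal(full$f_both, 1)
  expect_equal(full$f_level, 1)

  # all unknown level
  none <- known_information_fractions(tibble::tibble(
    weighted_count = 10, facility_status = "facility",
    level = "unknown_level", sector = "unknown_sector"
  ))
  expect_equal(none$f_both, 0)
  expect_equal(none$f_level, 0)

  expect_error(
    known_information_fractions(opts[4, ]),
    "no facility births"
  )
})

test_that("f_both never exceeds f_level on random option tables", {
  withr::with_seed(11, {
    for (i in 1:50) {
      n <- sample(2:8, 1)
      opts <- tibble::tibble(
        weighted_count = stats::runif(n, 0, 100),
        facility_status = "facility",
        level = sample(c("hospital", "lower", "unknown_level"), n, TRUE),
        sector = sample(
          c("public", "private_for_profit", "unknown_sector"), n, TRUE
        )
      )
      f <- known_information_fractions(opts)
      expect_lte(f$f_both, f$f_level + 1e-12)
    }
  })
})

test_that("inclusion flags apply inclusive thresholds", {
  th <- inclusion_thresholds()
  f1 <- inclusion_flags(0.86, 0.97, th)
  expect_true(f1$in_level_sector_models)
  expect_true(f1$in_level_models)

  f2 <- inclusion_flags(0.849, 0.96, th)
  expect_false(f2$in_level_sector_models)
  expect_true(f2$in_level_models)

  f3 <- inclusion_flags(1, 1, th)
  expect_true(f3$in_level_sector_models)
  expect_true(f3$in_level_models)

  # boundary values are included (inclusive >=)
  f4 <- inclusion_flags(0.85, 0.95, th)
  expect_true(f4$in_level_sector_models)
  expect_true(f4$in_level_models)

  # monotone: raising f_both cannot revoke inclusion
  for (f in seq(0.85, 1, by = 0.01)) {
    expect_true(inclusion_flags(f, 1, th)$in_level_sector_models)
  }
})

test_that("classify_options resolves unknown levels by caesarean sorting", {
  catalogue <- tibble::tibble(
    source_id = "S1", location_id = "C1",
    label = c("government hospital", "health post", "polyclinic"),
    weighted_count = c(500, 400, 100),
    csec_count = c(75, 12, 14) # rates 0.15, 0.03, 0.14 -> hospital
  )
  asg <- classify_options(catalogue)
  poly <- asg[asg$label == "polyclinic", ]
  expect_equal(poly$level, "hospital")
  expect_equal(poly$provenance, "csec_sort")
  # without sorting it stays unknown
  raw <- classify_options(catalogue, use_csec_sorting = FALSE)
  expect_equal(raw$level[raw$label == "polyclinic"], "unknown_level")
  # modelling sector merged
  expect_true(all(
    asg$modelling_sector %in%
      c("public_nfp", "private_fp", "unknown_sector", "not_applicable")
  ))
})
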