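test_that("generated scans hit their target TIA and class at zero noise", {
  s20 <- generate_scan(scan_recipe("flat", target_tia = 20))
  expect_equal(compute_tia750(s20), 20, tolerance = 0.1)
  expect_identical(classify_quadrant(s20)$angle_class, "open")
  s8 <- generate_scan(scan_recipe("flat", target_tia = 8))
  expect_identical(classify_quadrant(s8)$angle_class, "narrow")
  sbt <- generate_scan(scan_recipe("bombe_thick", target_tia = 8))
  expect_identical(classify_iris_configuration(sbt), "mixed")
  expect_true(classify_quadrant(sbt)$angle_class %in% c("narrow", "closed"))
})

test_that("generated scans satisfy the angle_scan invariants", {
  set.seed(10)
  for (i in 1:20) {
    r <- scan_recipe(sample(c("flat", "bowing", "bombe", "thick_peripheral",
                              "bombe_thick"), 1),
                     target_tia = runif(1, 3, 30), noise_sd = runif(1, 0, 15),
                     seed = i)
    expect_length(validate_angle_scan(generate_scan(r)), 0)
  }
  expect_error(scan_recipe("flat", target_tia = 40), class = "bad-recipe")
  expect_error(scan_recipe("flat", n_vertices = 10), class = "bad-recipe")
  expect_error(scan_recipe("flat", sagitta = 2000), class = "bad-recipe")
})

test_that("generator and grader agree on intended classes at zero noise", {
  set.seed(77)
  tias <- c(runif(40, 1, 11), runif(40, 13, 30))
  # the anterior surface follows the chord for flat and thick presets, so the
  # chord TIA determines the class on both sides of the threshold
  for (tia in tias) {
    for (cfgname in c("flat", "thick_peripheral")) {
      cls <- classify_quadrant(generate_scan(scan_recipe(cfgname, target_tia = tia)),
                               metrics = FALSE)$angle_class
      expect_identical(cls %in% c("narrow", "closed"), tia < 12,
                       label = sprintf("%s at %.2f", cfgname, tia))
    }
  }
  # bowing recedes from the preset arm (open at any wide chord angle); bombe
  # presses into it (qualifying at any narrow chord angle)
  for (tia in runif(20, 13, 30)) {
    cls <- classify_quadrant(generate_scan(scan_recipe("bowing", target_tia = tia)),
                             metrics = FALSE)$angle_class
    expect_identical(cls, "open")
  }
  for (tia in runif(20, 1, 11)) {
    cls <- classify_quadrant(generate_scan(scan_recipe("bombe", target_tia = tia)),
                             metrics = FALSE)$angle_class
    expect_true(cls %in% c("narrow", "closed"))
  }
})

test_that("scan generation is deterministic under a fixed seed", {
  r <- scan_recipe("bombe", target_tia = 9, noise_sd = 12, seed = 99)
  expect_identical(generate_scan(r), generate_scan(r))
  r2 <- scan_recipe("bombe", target_tia = 9, noise_sd = 12, seed = 100)
  expect_false(identical(generate_scan(r), generate_scan(r2)))
})

test_that("annotations round-trip through the JSON schema", {
  scans <- lapply(c("temporal", "nasal", "superior", "inferior"), function(q) {
    generate_scan(scan_recipe("bombe", target_tia = 15, quadrant = q,
                              noise_sd = 5, seed = match(q, c("temporal", "nasal",
                                                              "superior", "inferior"))))
  })
  eyes <- list(list(participant_id = "rt1", eye = "OD", scans = scans))
  path <- tempfile(fileext = ".json")
  write_annotations(eyes, path)
  back <- read_annotations(path)
  expect_length(attr(back, "problems"), 0)
  for (i in 1:4) {
    expect_equal(back[[1]]$scans[[i]]$iris_anterior, scans[[i]]$iris_anterior,
                 tolerance = 1e-8)
    expect_equal(back[[1]]$scans[[i]]$scleral_spur, scans[[i]]$scleral_spur,
                 tolerance = 1e-8)
    expect_identical(back[[1]]$scans[[i]]$quadrant, scans[[i]]$quadrant)
  }
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "other"), tmp, auto_unbox = TRUE)
  expect_error(read_annotations(tmp), class = "bad-schema")
})

test_that("the annotation reader downgrades invalid scans and reports fields", {
  s <- generate_scan(scan_recipe("flat", target_tia = 20))
  s$scleral_spur <- s$scleral_spur + c(0, 500)  # landmark off the trace
  path <- tempfile(fileext = ".json")
  write_annotations(list(list(participant_id = "bad1", eye = "OD", scans = list(s))),
                    path)
  back <- read_annotations(path)
  expect_gt(length(attr(back, "problems")), 0)
  expect_match(attr(back, "problems")[1], "scleral_spur")
  expect_false(back[[1]]$scans[[1]]$gradable)
})

test_that("the reader normalises frames so the cornea is above the iris", {
  s <- generate_scan(scan_recipe("flat", target_tia = 20))
  flip <- function(m) { m[, 2] <- -m[, 2]; m }
  s$cornea_inner <- flip(s$cornea_inner)
  s$iris_anterior <- flip(s$iris_anterior)
  s$iris_posterior <- flip(s$iris_posterior)
  s$scleral_spur[2] <- -s$scleral_spur[2]
  path <- tempfile(fileext = ".json")
  write_annotations(list(list(participant_id = "fl1", eye = "OD", scans = list(s))),
                    path)
  back <- read_annotations(path)
  scan <- back[[1]]$scans[[1]]
  expect_gt(mean(scan$cornea_inner[, 2]), mean(scan$iris_anterior[, 2]))
  expect_equal(compute_tia750(scan), 20, tolerance = 0.1)
})

test_that("the reference roster reproduces the published accounting exactly", {
  roster <- reference_cohort()
  expect_identical(nrow(roster), 1282L)
  expect_identical(reference_cohort(), roster)  # deterministic, no RNG
  validate_roster(roster)
  res <- apply_exclusions(roster)
  expect_identical(res$accounting$n_included, 991L)
  expect_identical(
    unname(res$accounting$counts),
    c(80L, 93L, 17L, 30L, 38L, 33L)
  )
  inc <- res$included
  expect_identical(sum(inc$hrac_label), 78L)
  expect_identical(sum(inc$gender == "male"), 579L)
  expect_identical(sum(inc$gender == "female"), 412L)
  expect_true(all(inc$age >= 40 & inc$age <= 84))
  # per-stratum HRAC labels match the published cells
  ref <- reference_counts()
  for (i in seq_len(nrow(ref$cells))) {
    sel <- inc$gender == ref$cells$gender[i] &
      as.character(age_band(inc$age)) == ref$cells$age_band[i]
    expect_identical(sum(inc$hrac_label[sel]), as.integer(ref$cells$numerator[i]))
  }
  cfg <- table(inc$configuration[inc$hrac_label])
  expect_identical(as.integer(cfg[c("bombe", "thick_peripheral", "mixed")]),
                   c(19L, 22L, 37L))
})

test_that("cohort simulation is seed-deterministic and respects prevalence zero", {
  spec0 <- cohort_spec(seed = 4)
  expect_identical(simulate_cohort(spec0), simulate_cohort(spec0))
  z <- cohort_spec(seed = 4)
  z$strata$prevalence <- 0
  sim <- simulate_cohort(z)
  expect_identical(sum(sim$roster$hrac_label, na.rm = TRUE), 0L)
  # qualifying quadrants never reach 3 in a zero-prevalence cohort
  narrow <- tapply(sim$recipes$target_tia < 12, sim$recipes$id, sum)
  expect_true(all(narrow <= 2))
})

test_that("mean simulated prevalence matches the binomial mixture oracle", {
  spec <- cohort_spec()
  oracle <- sum(spec$strata$n * spec$strata$prevalence) / sum(spec$strata$n)
  n_seeds <- 100
  prev <- vapply(seq_len(n_seeds), function(s) {
    spec$seed <- 5000 + s
    roster <- simulate_cohort(spec)$roster
    mean(roster$hrac_label, na.rm = TRUE)
  }, numeric(1))
  se <- sqrt(oracle * (1 - oracle) / (sum(spec$strata$n) * n_seeds))
  expect_lt(abs(mean(prev) - oracle), 4 * se)
})
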