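test_that("sample CSV parsing round-trips and tolerates column order", {
  s <- demo_samples()
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(s, path)
  expect_identical(read_samples(path), s)

  # header-named columns in a different order parse to the canonical layout
  shuffled <- s[, c("cd_conc", "sample_id", "cacao_pct", "chocolate_type")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(shuffled, path2)
  expect_identical(read_samples(path2), s)
})

test_that("invalid sample rows are rejected with row-indexed diagnostics", {
  s <- demo_samples()

  expect_error(
    validate_samples(s[, -4]),
    "missing required column.*cd_conc",
    class = "chocrisk_schema_error"
  )

  bad <- s
  bad$cd_conc[2] <- -0.1
  expect_error(
    validate_samples(bad),
    "row 2.*non-negative",
    class = "chocrisk_validation_error"
  )

  bad <- s
  bad$cacao_pct[3] <- 105
  expect_error(validate_samples(bad), "row 3.*\\[0, 100\\]")

  bad <- s
  bad$chocolate_type[1] <- "white"
  expect_error(validate_samples(bad), "row 1.*'milk' or 'dark'")
})

test_that("type/cacao disagreement warns but keeps the row", {
  s <- demo_samples()
  s$chocolate_type[1] <- "milk" # 72 % cacao labelled milk
  expect_warning(out <- validate_samples(s), "disagree in row\\(s\\) 1")
  expect_equal(nrow(out), 4)
})

test_that("MRL schedule is a non-decreasing step function over [0, 100]", {
  expect_equal(mrl_for(72), 0.8)
  expect_equal(mrl_for(30), 0.3) # boundary belongs to the upper category
  expect_equal(mrl_for(50), 0.8)
  expect_equal(mrl_for(0), 0.1)
  expect_equal(mrl_for(100), 0.8)

  grid <- seq(0, 100, by = 0.25)
  vals <- mrl_for(grid)
  expect_true(all(vals %in% c(0.1, 0.3, 0.8)))
  expect_true(all(diff(vals) >= 0))

  expect_error(mrl_for(-1), "\\[0, 100\\]")
  expect_error(mrl_for(101), "\\[0, 100\\]")
})

test_that("compliance margin satisfies margin + cd_conc = mrl exactly", {
  s <- tibble::tibble(
    sample_id = c("A", "B", "C"),
    chocolate_type = c("dark", "milk", "milk"),
    cacao_pct = c(72, 40, 40),
    cd_conc = c(0.29, 0.3, 0.31)
  )
  out <- check_compliance(s)
  expect_equal(out$compliant, c(TRUE, TRUE, FALSE)) # boundary is compliant
  expect_equal(out$margin[1], 0.51)
  expect_identical(out$margin + out$cd_conc, out$mrl)
})

test_that("LOD and LOQ follow the 3x/10x blank-deviation definition", {
  res <- lod_loq(blank_sd = 0.0003, slope = 1)
  expect_equal(res$lod, 0.0009)
  expect_equal(res$loq, 0.003)

  expect_equal(lod_loq(0, 2), list(lod = 0, loq = 0))

  # the 10/3 ratio is forced by the definition for any valid input
  withr::with_seed(11, {
    for (i in 1:20) {
      r <- lod_loq(runif(1, 0, 1), runif(1, 0.1, 10))
      expect_equal(r$loq, r$lod * 10 / 3)
    }
  })
  expect_error(lod_loq(0.1, 0), "positive")
})

test_that("sub-LOQ substitution replaces values by LOQ/2 only when invoked", {
  s <- demo_samples()
  s$cd_conc[2] <- 0.0004
  expect_message(out <- censor_below_loq(s, loq = 0.001), "1 concentration")
  expect_equal(out$cd_conc[2], 0.0005)
  expect_equal(out$cd_conc[-2], s$cd_conc[-2])
})

test_that("constants config validates and round-trips through YAML", {
  consts <- default_constants()
  expect_equal(consts$ptwi, 2.5)
  expect_equal(consts$at_c, 25550)

  path <- withr::local_tempfile(fileext = ".yml")
  write_constants(consts, path)
  back <- read_constants(path)
  expect_equal(unclass(back), unclass(consts))

  broken <- unclass(consts)
  broken$rfd <- NULL
  expect_error(validate_constants(broken), "rfd", class = "chocrisk_schema_error")
  broken <- unclass(consts)
  broken$ef <- -1
  expect_error(validate_constants(broken), "positive")
})

test_that("population table validates and round-trips through CSV", {
  pop <- default_population()
  expect_equal(nrow(pop), 7)
  expect_equal(pop$ingr_w_milk[pop$group == "toddlers"], 0.00703)
  expect_equal(pop$ingr_w_dark[pop$group == "toddlers"], 0.00525)
  expect_equal(pop$ed_years[pop$group == "elderly"], 15)

  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  expect_identical(read_population(path), pop)

  bad <- pop
  bad$ed_years[1] <- 0
  expect_error(validate_population(bad), "row\\(s\\) 1")
})
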