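consts <- default_constants()

test_that("EWI is the product of concentration and weekly rate", {
  expect_equal(ewi(290, 0.00525), 290 * 0.00525) # = 1.5225
  expect_equal(ewi(0, 0.01), 0)
  expect_equal(ewi(10, 0.00179), 0.0179)
  expect_error(ewi(-1, 0.01), "non-negative")
})

test_that("%PTWI reproduces the published group extremes at printed precision", {
  expect_equal(round(pct_ptwi(ewi(290, 0.00525), 2.5), 1), 60.9) # toddlers max
  expect_equal(round(pct_ptwi(ewi(290, 0.00547), 2.5), 1), 63.5) # other children max
  expect_equal(round(pct_ptwi(ewi(10, 0.00179), 2.5), 2), 0.72) # elderly min
  expect_equal(round(pct_ptwi(ewi(10, 0.00703), 2.5), 2), 2.81) # toddlers min
  expect_equal(pct_ptwi(2.5, 2.5), 100)
  expect_error(pct_ptwi(1, 0), "positive")
})

test_that("weekly-to-daily rate conversion divides by 7 and rescales kg to g", {
  expect_equal(daily_from_weekly(0.00703), 0.00703 / 7 * 1000)
  expect_equal(daily_from_weekly(0.007), 1)
  expect_equal(daily_from_weekly(0), 0)
})

test_that("HQ matches hand evaluation and is invariant to exposure duration", {
  # (EF/365) * C * IngR * CF / RfD, evaluated independently
  expect_equal(hq(0.29, 0.75, consts, ed_years = 2), (350 / 365) * 0.29 * 0.75 * 1e-3 / 1e-3)
  expect_equal(hq(0, 0.75, consts, ed_years = 5), 0)

  # ED cancels through AT_nc = 365 * ED
  expect_identical(
    hq(0.13, 0.4, consts, ed_years = 2),
    hq(0.13, 0.4, consts, ed_years = 30)
  )

  # with EF = 365 the time factor collapses to 1
  c365 <- validate_constants(modifyList(unclass(consts), list(ef = 365)))
  expect_equal(hq(0.1, 0.5, c365, ed_years = 7), 0.1 * 0.5 * 1e-3 / 1e-3)
})

test_that("CR matches hand evaluation and is linear in exposure duration", {
  expect_equal(
    cr(0.29, 0.75, consts, ed_years = 30),
    (350 * 30 / 25550) * 0.29 * 0.75 * 1e-3 * 6.1
  )
  expect_equal(cr(0, 1, consts, ed_years = 30), 0)
  expect_equal(
    cr(0.05, 0.3, consts, ed_years = 20),
    2 * cr(0.05, 0.3, consts, ed_years = 10)
  )
})

test_that("absolute and per-bw intake modes agree at the nominal body weight", {
  ingr_perbw <- 0.37 # g/kg bw/day
  bw <- 70
  expect_equal(
    hq(0.06, ingr_perbw * bw, consts, ed_years = 30, bw = bw),
    hq(0.06, ingr_perbw, consts, ed_years = 30)
  )
  expect_equal(
    cr(0.06, ingr_perbw * bw, consts, ed_years = 30, bw = bw),
    cr(0.06, ingr_perbw, consts, ed_years = 30)
  )
})

test_that("risk classes apply the printed thresholds with inclusive boundaries", {
  expect_equal(classify_hq(0.165), "safe")
  expect_equal(classify_cr(2e-5), "moderate")
  expect_equal(classify_hq(1), "safe")
  expect_equal(classify_cr(1e-6), "negligible")
  expect_equal(classify_hq(2), "adverse")
  expect_equal(classify_cr(2e-4), "unacceptable")
  expect_equal(classify_cr(1e-4), "moderate")
})

test_that("all four indices are homogeneous of degree 1 in concentration", {
  withr::with_seed(5, {
    for (i in 1:25) {
      c0 <- runif(1, 0.01, 0.3)
      r_w <- runif(1, 0.001, 0.01)
      k <- runif(1, 0.1, 10)
      ed <- sample(c(2, 5, 7, 15, 30), 1)
      r_d <- daily_from_weekly(r_w)
      expect_equal(ewi(k * c0 * 1000, r_w), k * ewi(c0 * 1000, r_w))
      expect_equal(
        pct_ptwi(ewi(k * c0 * 1000, r_w)),
        k * pct_ptwi(ewi(c0 * 1000, r_w))
      )
      expect_equal(hq(k * c0, r_d, consts, ed), k * hq(c0, r_d, consts, ed))
      expect_equal(cr(k * c0, r_d, consts, ed), k * cr(c0, r_d, consts, ed))
    }
  })
})

test_that("%PTWI of EWI has the closed form 40 * c * rate at PTWI 2.5", {
  withr::with_seed(6, {
    c_ugkg <- runif(10, 1, 300)
    rate <- runif(10, 0.001, 0.01)
    expect_equal(pct_ptwi(ewi(c_ugkg, rate), 2.5), 40 * c_ugkg * rate)
  })
})

test_that("indices agree with an independent brute-force oracle to 1e-12", {
  # the oracle spells the four dose equations out in plain arithmetic,
  # sharing no code with the package implementation
  oracle <- function(c_mgkg, ingr_w, ed) {
    ingr_d <- (ingr_w / 7) * 1000
    at_nc <- 365 * ed
    list(
      ewi = (c_mgkg * 1000) * ingr_w,
      pct = (c_mgkg * 1000) * ingr_w * 100 / 2.5,
      hq = (350 * ed * c_mgkg * ingr_d * 1e-3) / (at_nc * 1e-3),
      cr = (350 * ed * c_mgkg * ingr_d * 1e-3 * 6.1) / 25550
    )
  }
  withr::with_seed(7, {
    c_mgkg <- runif(1000, 0, 0.3)
    ingr_w <- runif(1000, 0, 0.01)
    ed <- sample(c(2, 5, 7, 15, 30), 1000, replace = TRUE)
  })
  exp_vals <- oracle(c_mgkg, ingr_w, ed)
  ingr_d <- daily_from_weekly(ingr_w)
  expect_equal(ewi(c_mgkg * 1000, ingr_w), exp_vals$ewi, tolerance = 1e-12)
  expect_equal(pct_ptwi(ewi(c_mgkg * 1000, ingr_w)), exp_vals$pct, tolerance = 1e-12)
  expect_equal(hq(c_mgkg, ingr_d, consts, ed), exp_vals$hq, tolerance = 1e-12)
  expect_equal(cr(c_mgkg, ingr_d, consts, ed), exp_vals$cr, tolerance = 1e-12)
})

test_that("risk table evaluates each sample under its own type's rate", {
  s <- demo_samples()
  risk <- risk_table(s, default_population(), consts)
  expect_equal(nrow(risk), nrow(s) * 7)

  # dark sample S1 for toddlers: dark rate applies
  row <- risk[risk$sample_id == "S1" & risk$group == "toddlers", ]
  expect_equal(row$ewi, ewi(0.29 * 1000, 0.00525))
  # milk sample S2 for toddlers: milk rate applies
  row <- risk[risk$sample_id == "S2" & risk$group == "toddlers", ]
  expect_equal(row$ewi, ewi(0.021 * 1000, 0.00703))
})

test_that("group summaries order min <= mean <= max and fractions sum to 1", {
  fx <- builtin_study_fixture(seed = 3)
  risk <- risk_table(fx$samples, fx$population, fx$constants)
  summ <- summarize_risk(risk)
  expect_equal(nrow(summ), 7 * 4)
  expect_true(all(summ$min <= summ$mean & summ$mean <= summ$max))
  fr <- summ[summ$endpoint == "cr", ]
  expect_equal(
    fr$frac_negligible + fr$frac_moderate + fr$frac_unacceptable,
    rep(1, nrow(fr))
  )

  # identical samples collapse the spread
  one <- demo_samples()[rep(1, 5), ]
  one$sample_id <- paste0("R", 1:5)
  s1 <- summarize_risk(risk_table(one, default_population(), consts))
  expect_equal(s1$min, s1$max)
  expect_equal(s1$min, s1$mean)

  expect_error(summarize_risk(risk[0, ]), "empty")

  by_type <- summarize_risk(risk, by_type = TRUE)
  expect_true(all(c("milk", "dark") %in% by_type$chocolate_type))
})
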