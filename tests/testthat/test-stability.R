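test_that("COV follows the sample-SD/|mean| definition", {
  expect_equal(cov_percent(c(7, 7, 7)), 0)
  expect_equal(cov_percent(c(1, 2, 3)), 50)  # mean 2, sample SD 1
  expect_equal(cov_percent(c(10, 20)), 100 * sd(c(10, 20)) / 15)
  expect_error(cov_percent(5), "at least 2")
})

test_that("zero-mean series are flagged as undefined COV", {
  expect_true(is.na(cov_percent(c(-1, 1))))
  expect_true(is.na(cov_percent(c(-1e-15, 1e-15) + 0)))
  expect_equal(cov_percent(c(0, 0, 0)), 0)  # constant zero: no variation
})

test_that("COV is invariant to positive scaling", {
  x <- c(3.2, 4.8, 4.1, 3.9)
  for (c_ in c(0.01, 1, 250))
    expect_equal(cov_percent(c_ * x), cov_percent(x))
})

test_that("category boundaries are inclusive on the more stable side", {
  expect_equal(categorize_stability(0), "stable")
  expect_equal(categorize_stability(5.0), "stable")
  expect_equal(categorize_stability(5.0001), "moderately_stable")
  expect_equal(categorize_stability(10.0), "moderately_stable")
  expect_equal(categorize_stability(20.0), "poorly_stable")
  expect_equal(categorize_stability(20.01), "unstable")
  expect_error(categorize_stability(-1), "negative")
  # monotone: higher COV never maps to a more stable category
  cats <- c("stable", "moderately_stable", "poorly_stable", "unstable")
  v <- categorize_stability(sort(runif(50, 0, 40)))
  expect_true(all(diff(match(v, cats)) >= 0))
})

# Analytic feature table: one feature constant, one a pure function of the
# filter FWHM, over the full 21-setting grid.
analytic_table <- function() {
  st <- settings_table(enumerate_settings())
  rbind(
    data.frame(feature = "flat", shape_id = 1, setting_id = st$setting_id,
               family = st$family, value = 3.3),
    data.frame(feature = "filter_driven", shape_id = 1,
               setting_id = st$setting_id, family = st$family,
               value = 10 + st$filter_fwhm))
}

test_that("family COVs isolate the varying parameter family", {
  stab <- stability_table(analytic_table(), shape_id = 1)
  flat <- stab[stab$feature == "flat", ]
  expect_equal(flat$cov_overall, 0)
  expect_equal(flat$category, "stable")

  fd <- stab[stab$feature == "filter_driven", ]
  expect_equal(fd$cov_subsets, 0)
  expect_equal(fd$cov_iterations, 0)
  expect_equal(fd$cov_tof, 0)
  # filter family: values 10 + (0..7) at the 8 filter settings
  expect_equal(fd$cov_filter, cov_percent(10 + 0:7))
  expect_equal(fd$cov_overall, cov_percent(10 + 0:7) / 4)
})

test_that("pooled overall COV mode pools all 21 settings", {
  stab <- stability_table(analytic_table(), 1, overall = "pooled")
  fd <- stab[stab$feature == "filter_driven", ]
  st <- settings_table(enumerate_settings())
  expect_equal(fd$cov_overall, cov_percent(10 + st$filter_fwhm))
})

test_that("incomplete tables are rejected", {
  tab <- analytic_table()
  expect_error(stability_table(tab[-1, ], 1), "missing settings")
  expect_error(stability_table(tab, 2), "no rows")
})

test_that("category counts partition the catalogue", {
  tab <- analytic_table()
  stab <- stability_table(tab, 1)
  cc <- radstab:::category_counts(stab)
  expect_equal(sum(unlist(cc$overall)) + cc$undefined, nrow(stab))
})
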