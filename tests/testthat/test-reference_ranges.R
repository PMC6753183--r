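test_that("age strata partition all non-negative ages, boundary to the older group", {
  expect_identical(get_age_group(0.25), "infant_0_6m")
  expect_identical(get_age_group(0.5), "child_6m_12y")
  expect_identical(get_age_group(30), "over_12y")
  expect_identical(get_age_group(0), "infant_0_6m")
  expect_identical(get_age_group(12), "over_12y")

  set.seed(42)
  ages <- c(runif(500, 0, 120), 0, 0.5, 12, 11.999, 0.499)
  groups <- get_age_group(ages)
  expect_true(all(groups %in% cda_age_groups()))
  # independent re-derivation of the stratum
  expect_identical(groups,
                   ifelse(ages < 0.5, "infant_0_6m",
                          ifelse(ages < 12, "child_6m_12y", "over_12y")))
})

test_that("invalid ages are rejected", {
  expect_error(get_age_group(-1), "finite and >= 0")
  expect_error(get_age_group(Inf), "finite and >= 0")
  expect_error(get_age_group("x"), "numeric")
})

test_that("packaged table reproduces all 24 published intervals digit-for-digit", {
  tab <- reference_ranges()
  expect_identical(nrow(tab), 24L)
  exp <- expected_ranges_table()
  key <- function(d) paste(d$parameter, d$sex, d$age_group, sep = "|")
  tab <- tab[match(key(exp), key(tab)), ]
  expect_identical(tab$low, exp$low)
  expect_identical(tab$high, exp$high)
  expect_identical(tab$unit, exp$unit)
})

test_that("lookup_range returns the published bounds for spot checks", {
  rv <- lookup_range("hemoglobin", "M", "over_12y")
  expect_identical(c(rv$low, rv$high), c(13, 17.5))
  expect_identical(rv$unit, "g/dL")
  rv <- lookup_range("reticulocytes", "F", "child_6m_12y")
  expect_identical(c(rv$low, rv$high), c(40, 162))
  rv <- lookup_range("platelets", "M", "infant_0_6m")
  expect_identical(c(rv$low, rv$high), c(145, 450))
  # spelled-out sex codes are accepted
  expect_identical(lookup_range("hemoglobin", "female", "over_12y")$low, 12)
})

test_that("a replacement table must be complete and well-formed", {
  tab <- reference_ranges()
  tmp <- tempfile(fileext = ".csv")
  write.csv(tab[-1, ], tmp, row.names = FALSE)
  expect_error(reference_ranges(tmp), "24")
  bad <- tab
  bad$low[1] <- bad$high[1] + 1
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(reference_ranges(tmp), "low < high")
})

test_that("flag_value is an inclusive-WITHIN trichotomy, monotone in value", {
  rv <- lookup_range("hemoglobin", "M", "over_12y")
  expect_identical(flag_value(12.9, rv), "below")
  expect_identical(flag_value(13.0, rv), "within")
  expect_identical(flag_value(17.5, rv), "within")
  expect_identical(flag_value(18.0, rv), "above")

  set.seed(7)
  for (i in 1:50) {
    lo <- runif(1, 1, 100)
    range <- list(low = lo, high = lo + runif(1, 1, 100))
    vals <- sort(runif(40, 0.1, 250))
    flags <- flag_value(vals, range)
    expect_true(all(flags %in% c("below", "within", "above")))
    # monotone: once past below, never back
    order_idx <- match(flags, c("below", "within", "above"))
    expect_true(all(diff(order_idx) >= 0))
    expect_identical(flags, ifelse(vals < range$low, "below",
                                   ifelse(vals > range$high, "above",
                                          "within")))
  }
})

test_that("flag_value rejects non-positive or non-finite values", {
  rv <- list(low = 1, high = 2)
  expect_error(flag_value(0, rv), "finite and > 0")
  expect_error(flag_value(-3, rv), "finite and > 0")
  expect_error(flag_value(NaN, rv), "finite and > 0")
})
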