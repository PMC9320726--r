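minus_profile <- function() make_profile(integer(0), integer(0), kind = "minus_lib")

test_that("rates average over the union of non-zero positions", {
  plus <- make_profile(c(10L, 20L, 30L), c(10L, 20L, 30L))
  minus <- make_profile(integer(0), integer(0), kind = "minus_lib")
  r <- estimate_rates(plus, minus, "chr", "+")
  expect_equal(r$lambda_plus, 20)
  expect_equal(r$lambda_minus, 0)
  empty <- estimate_rates(minus_profile(), minus_profile(), "chr", "+")
  expect_equal(empty$lambda_plus, 0)
  expect_equal(empty$lambda_minus, 0)
  expect_true(empty$flagged_empty)
})

test_that("rate recovery on seeded Poisson profiles", {
  set.seed(41)
  n <- 1e4
  kp <- rpois(n, 5); km <- rpois(n, 5)
  keep <- kp > 0 | km > 0
  plus <- make_profile(which(kp > 0), kp[kp > 0])
  minus <- make_profile(which(km > 0), km[km > 0], kind = "minus_lib")
  r <- estimate_rates(plus, minus, "chr", "+")
  # mean over union positions; both-zero positions are so rare at lambda=5
  # that the exclusion bias is negligible against 3 SE
  expect_lt(abs(r$lambda_plus - 5), 3 * sqrt(5 / sum(keep)))
  expect_lt(abs(r$lambda_minus - 5), 3 * sqrt(5 / sum(keep)))
})

test_that("a strongly enriched site is called exactly once", {
  plus <- make_profile(500L, 50L)
  minus <- make_profile(500L, 2L, kind = "minus_lib")
  calls <- call_tss(plus, minus,
                    rates = list(lambda_plus = 0.5, lambda_minus = 0.4))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$position, 500L)
  expect_equal(calls$k_plus, 50L)
  expect_equal(calls$k_minus, 2L)
  expect_lt(calls$p_value, conv_skellam_sf(48, 0.5, 0.4) + 1e-12)
  expect_equal(calls$p_value, conv_skellam_sf(48, 0.5, 0.4), tolerance = 1e-9)
})

test_that("empty profiles yield an empty call set", {
  calls <- call_tss(make_profile(integer(0), integer(0)),
                    make_profile(integer(0), integer(0), kind = "minus_lib"))
  expect_s3_class(calls, "tss_calls")
  expect_equal(nrow(calls), 0)
})

test_that("adjacent significant candidates fuse keeping the largest difference", {
  plus <- make_profile(c(100L, 101L), c(40L, 30L))
  minus <- make_profile(integer(0), integer(0), kind = "minus_lib")
  rates <- list(lambda_plus = 0.5, lambda_minus = 0.4)
  calls <- call_tss(plus, minus, detection_params(merge = 1), rates)
  expect_equal(calls$position, 100L)
  # equal differences tie-break 5'-most per strand
  plus_tie <- make_profile(c(100L, 101L), c(40L, 40L))
  expect_equal(call_tss(plus_tie, minus, rates = rates)$position, 100L)
  plus_m <- make_profile(c(100L, 101L), c(40L, 40L), strand = "-")
  minus_m <- make_profile(integer(0), integer(0), strand = "-", kind = "minus_lib")
  expect_equal(call_tss(plus_m, minus_m, rates = rates)$position, 101L)
  # merge = 0 keeps both
  expect_equal(nrow(call_tss(plus, minus, detection_params(merge = 0), rates)), 2)
})

test_that("the noise threshold and enrichment direction gate candidates", {
  plus <- make_profile(c(10L, 20L, 30L), c(9L, 50L, 60L))
  minus <- make_profile(c(20L, 30L), c(50L, 70L), kind = "minus_lib")
  rates <- list(lambda_plus = 0.5, lambda_minus = 0.4)
  calls <- call_tss(plus, minus, rates = rates)
  expect_equal(nrow(calls), 0)  # below noise / balanced / depleted
})

test_that("null equal-rate profiles keep the false-positive rate at bay", {
  set.seed(97)
  n <- 1e4
  kp <- rpois(n, 20); km <- rpois(n, 20)
  plus <- make_profile(which(kp > 0), kp[kp > 0])
  minus <- make_profile(which(km > 0), km[km > 0], kind = "minus_lib")
  r <- estimate_rates(plus, minus, "chr", "+")
  d <- kp - km
  pv <- vapply(sort(unique(d)), skellam_sf, 0,
               lambda1 = r$lambda_plus, lambda2 = r$lambda_minus)
  fpr <- mean(pv[match(d, sort(unique(d)))] <= 0.01)
  expect_lte(fpr, 0.01 + 3 * sqrt(0.01 * 0.99 / n))
})
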