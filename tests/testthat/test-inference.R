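# Estimators: SDS frequency, transmission scan, goodness of fit.

test_that("estimate_sds recovers the SDS fraction with exact intervals and
           the tetrad map distance", {
  est <- estimate_sds(9000, 1000)
  expect_equal(est$s_hat, 0.10)
  expect_equal(est$map_distance_cM, 5)
  expect_true(est$ci_low <= est$s_hat && est$s_hat <= est$ci_high)
  expect_true(est$ci_low >= 0 && est$ci_high <= 1)
  # matches the exact binomial interval
  ci <- binom.test(1000, 10000)$conf.int
  expect_equal(c(est$ci_low, est$ci_high), as.numeric(ci))

  est0 <- estimate_sds(100, 0)
  expect_equal(est0$s_hat, 0)
  expect_equal(est0$ci_low, 0)
  expect_error(estimate_sds(0, 0), "no asci")
})

test_that("estimate_sds refuses loci whose killing is masked or silent", {
  # homozygous Spok2 in SKT20 x S
  expect_error(assert_sds_estimable(registry_cross("SKT20xS"), "spok2"),
               "homozygous")
  # Spok2 masked by the opposite haplotype's Spok1 in S x T
  expect_error(assert_sds_estimable(registry_cross("SxT"), "spok2"),
               "masked")
  # the unmasked killer is estimable
  expect_true(assert_sds_estimable(registry_cross("SxT"), "spok1"))
  expect_true(assert_sds_estimable(registry_cross("Spok1DxS"), "spok2"))
  expect_error(estimate_sds(90, 10, cross = registry_cross("SxT"),
                            locus_id = "spok2"), "masked")
})

test_that("the scan flags a fully transmitted driver with the closed-form
           binomial tail and leaves unlinked markers unflagged", {
  set.seed(19)
  g <- data.frame(drv = rep("T", 50),
                  unl = sample(c("S", "T"), 50, replace = TRUE, prob = c(.5, .5)))
  sc <- transmission_scan(g, focal = "T")
  expect_equal(sc$fraction[sc$marker == "drv"], 1)
  expect_equal(sc$p[sc$marker == "drv"], 2 * 0.5^50, tolerance = 1e-12)
  expect_true(all(sc$p_adj >= sc$p - 1e-15))
  expect_true(all(sc$fraction >= 0 & sc$fraction <= 1))
  expect_true("drv" %in% attr(sc, "region"))
  expect_false("unl" %in% attr(sc, "region"))
  expect_error(transmission_scan(data.frame()), "empty")
})

test_that("goodness of fit is zero at exact proportions and calibrated under
           the null", {
  p <- c(`2-spored` = 0.9, `4-spored` = 0.1)
  fit0 <- goodness_of_fit(c(`2-spored` = 900, `4-spored` = 100), p)
  expect_equal(fit0$statistic, 0)
  expect_equal(fit0$p.value, 1)

  set.seed(23)
  pvals <- replicate(400, {
    counts <- as.vector(rmultinom(1, 500, p))
    names(counts) <- names(p)
    goodness_of_fit(counts, p)$p.value
  })
  expect_gt(mean(pvals < 0.05), 0.02)
  expect_lt(mean(pvals < 0.05), 0.09)
})

test_that("goodness of fit rejects a wrong SDS frequency at large n", {
  sim <- simulate_cross(registry_cross("SxT"), n_asci = 10000, seed = 1,
                        survivors = FALSE)
  wrong <- c(`2-spored` = 0.5, `4-spored` = 0.5)
  fit <- goodness_of_fit(sim$counts, wrong)
  expect_lt(fit$p.value, 1e-10)
  right <- enumerate_cross(registry_cross("SxT"))
  expect_gt(goodness_of_fit(sim$counts, right)$p.value, 1e-4)
})

test_that("small samples use the exact multinomial test", {
  p <- c(a = 0.9, b = 0.1)
  fit <- goodness_of_fit(c(a = 9, b = 1), p)
  expect_equal(fit$method, "exact multinomial")
  expect_true(fit$p.value > 0 && fit$p.value <= 1)
  # the most probable table cannot be rejected
  expect_gt(fit$p.value, 0.5)
  expect_error(goodness_of_fit(c(zz = 5), p), "zero expected")
})
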