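# Monte-Carlo cross simulator and ascus classification.

test_that("identical seeds give identical tables", {
  cx <- registry_cross("SxT")
  s1 <- simulate_cross(cx, n_asci = 500, seed = 123)
  s2 <- simulate_cross(cx, n_asci = 500, seed = 123)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$survivors, s2$survivors)
})

test_that("simulated class frequencies match the exact enumeration", {
  n <- 3000
  for (id in c("SxT", "Spok1DxS", "PaPKS1_Spok1xS", "SpokNxS")) {
    d <- enumerate_cross(registry_cross(id))
    sim <- simulate_cross(registry_cross(id), n_asci = n, seed = 21,
                          survivors = FALSE)
    for (cl in unique(d$class)) {
      p <- percent_class(d, cl) / 100
      phat <- percent_class(sim, cl) / 100
      expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
    }
  }
})

test_that("octad-mode killer crosses give exactly four viable and four dead
           spores in every ascus regardless of s", {
  for (s in c(0.05, 0.9)) {
    cx <- killer_cross(s = s, packaging = "uninucleate_octad")
    sim <- simulate_cross(cx, n_asci = 300, seed = 4)
    expect_identical(unique(sim$counts$class), "4-spored")
    expect_equal(sum(sim$counts$count), 300L)
    expect_true(all(!sim$survivors$heterokaryotic))
  }
})

test_that("classify_ascus maps viability and pigment to class labels", {
  cx <- registry_cross("PaPKS1_Spok1xS")
  ctx <- zygote_context(cx)
  set.seed(31)
  fds <- apply_spore_killing(ascus_with_pattern(cx, c(pks1 = FALSE)), ctx)
  cls <- classify_ascus(fds)
  expect_equal(cls$class, "2-spored")
  expect_equal(cls$n_unpigmented, 2L) # survivors carry the colorless insertion
  sds <- apply_spore_killing(ascus_with_pattern(cx, c(pks1 = TRUE)), ctx)
  cls2 <- classify_ascus(sds)
  expect_equal(cls2$class, "4-spored")
  expect_equal(cls2$n_pigmented, 4L) # heterokaryotic spores are pigmented
})

test_that("empty asci stay in the percentage denominator", {
  d <- enumerate_cross(registry_cross("Spok2AAxSpok2D"))
  expect_equal(percent_class(d, "empty"), 100, tolerance = 1e-12)
  expect_equal(percent_class(d, "4-spored"), 0, tolerance = 1e-12)
})

test_that("classify_ascus and simulate_cross reject invalid input", {
  a <- simulate_meiosis(killer_cross(), seed = 1)
  expect_error(classify_ascus(a), "viability")
  expect_error(simulate_cross(killer_cross(), n_asci = 0), "positive")
})
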