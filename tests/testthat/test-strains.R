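# Reference strain library, cross registry, and synthetic marker datasets.

test_that("strain library encodes the documented allele activities", {
  lib <- spok_strain_library()
  al <- spok_alleles()
  expect_equal(unname(lib$SKT20$alleles[c("spok1", "spok2")]),
               c("Spok1", "Spok2"))
  # strain A: responder-only Spok2 variant
  a_var <- al[[lib$strainA$alleles[["spok2"]]]]
  expect_false(a_var$distorter_active)
  expect_true("Spok2" %in% a_var$responder_covers)
  # heterologous killer: distorter whose responder needs trans-activation
  spokN <- al$pks1_SpokN
  expect_true(spokN$distorter_active)
  expect_gt(length(spokN$trans_activators), 0)
  # asymmetric resistance: Spok1 covers Spok2, not the reverse
  expect_true("Spok2" %in% al$Spok1$responder_covers)
  expect_false("Spok1" %in% al$Spok2$responder_covers)
  # resistant non-killers
  for (s in c("PaPKS1_Spok1_GFP", "A406")) {
    a <- al[[lib[[s]]$alleles[[if (s == "A406") "spok2" else "pks1"]]]]
    expect_false(a$distorter_active)
    expect_true(all(c("Spok1", "Spok2") %in% a$responder_covers))
  }
})

test_that("every registry cross with a documented outcome matches its exact
           enumeration", {
  reg <- spok_cross_registry()
  for (i in seq_len(nrow(reg))) {
    if (is.na(reg$expected_2spored[i])) next
    d <- enumerate_cross(registry_cross(reg$id[i]))
    expect_equal(percent_class(d, "2-spored"), reg$expected_2spored[i],
                 tolerance = 1e-9, label = paste(reg$id[i], "2-spored"))
    expect_equal(percent_class(d, "4-spored"), reg$expected_4spored[i],
                 tolerance = 1e-9, label = paste(reg$id[i], "4-spored"))
    expect_equal(percent_class(d, "empty"), reg$expected_empty[i],
                 tolerance = 1e-9, label = paste(reg$id[i], "empty"))
    if (!is.na(reg$expected_2sp_unpigmented[i]))
      expect_equal(percent_class(d, "2-spored", n_pigmented = 0),
                   reg$expected_2sp_unpigmented[i], tolerance = 1e-9,
                   label = paste(reg$id[i], "2-spored unpigmented"))
  }
})

test_that("survivor segregation columns of the registry hold: killed crosses
           fix the killer, unlinked loci split 50:50", {
  d <- enumerate_cross(registry_cross("SxT"))
  sv <- survivor_distribution(d)
  expect_true(all(grepl("Spok1($|/)", sv$spok1)))
  d2 <- enumerate_cross(registry_cross("Spok1DxS"))
  sv2 <- survivor_distribution(d2)
  expect_true(all(grepl("(^|/)Spok2($|/)", sv2$spok2)))
})

test_that("marker datasets fix the driver column and split unlinked markers", {
  cx <- registry_cross("SxT")
  g <- generate_marker_dataset(60, cx, "spok1", seed = 13)
  expect_equal(dim(g), c(60L, 3L))
  expect_true(all(g[, "spok1"] == "T")) # all progeny carry the killer
  # spok2 at r = 0.5: parental origins near 50:50
  frac <- mean(g[, "spok2"] == "T")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 60))
  expect_error(generate_marker_dataset(10, cx, "nope"), "not in cross")
})

test_that("the synthetic scan cross places the driver on a decaying linkage
           map", {
  st <- scan_test_cross()
  expect_length(st$cross$loci, 10L)
  drv <- st$cross$loci[[st$driver_locus]]
  expect_equal(drv$sds_prob, 0.10, tolerance = 1e-9)
  expect_true(all(vapply(st$cross$linkage$r, function(r) r <= 0.5, TRUE)))
})
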