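# Exact enumeration oracle.

test_that("a single heterozygous killer gives P(2-spored) = 1 - s and
           P(4-spored) = s", {
  for (s in c(0, 0.3, 1)) {
    d <- enumerate_cross(killer_cross(s = s))
    expect_equal(percent_class(d, "2-spored"), 100 * (1 - s), tolerance = 1e-12)
    expect_equal(percent_class(d, "4-spored"), 100 * s, tolerance = 1e-12)
  }
})

test_that("a distorter with no coverage anywhere empties every ascus", {
  d <- enumerate_cross(killer_cross(s = 0.3, covers = character()))
  expect_equal(percent_class(d, "empty"), 100, tolerance = 1e-12)
})

test_that("enumeration probabilities sum to one for every reference cross", {
  reg <- spok_cross_registry()
  for (id in reg$id) {
    d <- enumerate_cross(registry_cross(id))
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
  }
})

test_that("enumeration refuses more than three heterozygous loci", {
  ids <- paste0("L", 1:4)
  al <- unlist(lapply(ids, function(l)
    list(allele(paste0(l, "_A"), l), allele(paste0(l, "_a"), l))),
    recursive = FALSE)
  h1 <- haplotype("p1", stats::setNames(paste0(ids, "_A"), ids))
  h2 <- haplotype("p2", stats::setNames(paste0(ids, "_a"), ids))
  cx <- cross_spec(h1, h2, loci = lapply(ids, locus, chromosome = "1",
                                         sds_prob = 0.5), alleles = al)
  expect_error(enumerate_cross(cx), "at most 3")
})

test_that("expected survivor genotypes of S x T carry the killer, with the
           unlinked killer segregating 50:50 among homokaryons", {
  d <- enumerate_cross(registry_cross("SxT"))
  sv <- survivor_distribution(d)
  expect_true(all(grepl("Spok1($|/)", sv$spok1)))
  homo <- sv[!grepl("/", sv$spok2, fixed = TRUE), ]
  share_spok2 <- sum(homo$share[homo$spok2 == "Spok2"])
  share_spok2_0 <- sum(homo$share[homo$spok2 == "Spok2_0"])
  expect_equal(share_spok2, share_spok2_0, tolerance = 1e-9)
})

test_that("enumeration agrees between phenomenological and mechanistic
           parameterisations of the same locus", {
  x <- 0.4
  d_mech <- enumerate_cross(killer_cross(s = 0, mode = "mechanistic", x = x))
  d_phen <- enumerate_cross(killer_cross(s = sds_from_map_length(x)))
  expect_equal(percent_class(d_mech, "4-spored"),
               percent_class(d_phen, "4-spored"), tolerance = 1e-6)
})
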