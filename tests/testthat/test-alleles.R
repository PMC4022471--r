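# Domain types: construction and validation.

test_that("allele and locus constructors validate their fields", {
  a <- allele("Spok1", "spok1", distorter_active = TRUE,
              responder_covers = c("Spok1", "Spok2"))
  expect_s3_class(a, "spok_allele")
  expect_true(a$distorter_active)
  expect_setequal(a$responder_covers, c("Spok1", "Spok2"))
  expect_error(allele("x", "l", killing_efficiency = 1.2), "probability")
  expect_error(locus("l", "1", sds_prob = 1.5), "probability")
  expect_error(locus("l", "1", sds_prob = 0.5, position_morgans = -1),
               "non-negative")
})

test_that("cross_spec enforces haplotype completeness and declared alleles", {
  al <- list(allele("A", "L1"), allele("a", "L1"), allele("B", "L2"))
  lo <- list(locus("L1", "1", 0.1), locus("L2", "1", 0.5))
  h_ok <- haplotype("p1", c(L1 = "A", L2 = "B"))
  # missing locus
  expect_error(cross_spec(h_ok, haplotype("p2", c(L1 = "a")), lo, al),
               "lacks an allele")
  # undeclared allele id
  expect_error(
    cross_spec(h_ok, haplotype("p2", c(L1 = "a", L2 = "ZZ")), lo, al),
    "undeclared allele")
  # allele assigned to the wrong locus
  expect_error(
    cross_spec(h_ok, haplotype("p2", c(L1 = "B", L2 = "B")), lo, al),
    "belongs to locus")
  # responder reference outside the declared set
  al_bad <- c(al[1:2], list(allele("B", "L2", responder_covers = "ghost")))
  expect_error(cross_spec(h_ok, haplotype("p2", c(L1 = "a", L2 = "B")),
                          lo, al_bad), "undeclared allele")
})

test_that("linkage fractions are bounded and reference known loci", {
  al <- list(allele("A", "L1"), allele("a", "L1"), allele("B", "L2"))
  lo <- list(locus("L1", "1", 0.1), locus("L2", "1", 0.5))
  h1 <- haplotype("p1", c(L1 = "A", L2 = "B"))
  h2 <- haplotype("p2", c(L1 = "a", L2 = "B"))
  expect_error(cross_spec(h1, h2, lo, al,
                          linkage = data.frame(locus1 = "L1", locus2 = "L2",
                                               r = 0.7)),
               "\\[0, 0.5\\]")
  expect_error(cross_spec(h1, h2, lo, al,
                          linkage = data.frame(locus1 = "L1", locus2 = "LX",
                                               r = 0.1)),
               "unknown locus")
  expect_error(cross_spec(h1, h2, lo, al, n_asci = 0), "positive")
})

test_that("mechanistic mode requires map positions", {
  expect_error(
    cross_spec(haplotype("p1", c(L1 = "A")), haplotype("p2", c(L1 = "a")),
               loci = list(locus("L1", "1", 0.1)),
               alleles = list(allele("A", "L1"), allele("a", "L1")),
               mode = "mechanistic"),
    "position_morgans")
})
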