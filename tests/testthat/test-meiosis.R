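# Meiosis engine: segregation geometry, nucleus conservation, packaging,
# pigmentation, and the mechanistic crossover mode.

test_that("a fully centromere-linked heterozygous locus (s = 0) gives two
           homokaryotic spores per genotype", {
  cx <- neutral_cross(s = 0)
  a <- simulate_meiosis(cx, seed = 1)
  genos <- vapply(a$spores, function(sp) {
    g <- unique(vapply(sp$nuclei, `[[`, "", "L1"))
    expect_length(g, 1) # homokaryotic
    g
  }, "")
  expect_equal(as.integer(sort(table(genos))), c(2L, 2L))
  expect_false(a$sds_pattern[["L1"]])
})

test_that("an obligate second-division locus (s = 1) gives four heterokaryotic
           spores", {
  cx <- neutral_cross(s = 1)
  for (seed in 1:5) {
    a <- simulate_meiosis(cx, seed = seed)
    expect_true(a$sds_pattern[["L1"]])
    for (sp in a$spores)
      expect_setequal(vapply(sp$nuclei, `[[`, "", "L1"), c("A", "a"))
  }
})

test_that("homozygous crosses yield identical nuclei regardless of s", {
  al <- list(allele("A", "L1"))
  cx <- cross_spec(haplotype("p1", c(L1 = "A")), haplotype("p2", c(L1 = "A")),
                   loci = list(locus("L1", "1", 0.7)), alleles = al)
  a <- simulate_meiosis(cx, seed = 3)
  nuclei <- unlist(lapply(a$spores, function(sp)
    vapply(sp$nuclei, `[[`, "", "L1")))
  expect_true(all(nuclei == "A"))
})

test_that("every ascus conserves eight nuclei with 4:4 allele dosage at
           heterozygous loci, and FDS/SDS patterns match spore karyotype", {
  cx <- registry_cross("SxT")
  set.seed(42)
  for (i in 1:40) {
    a <- simulate_meiosis(cx)
    nuclei <- unlist(lapply(a$spores, `[[`, "nuclei"), recursive = FALSE)
    expect_length(nuclei, 8L)
    for (l in c("spok1", "spok2")) {
      alleles <- vapply(nuclei, `[[`, "", l)
      expect_equal(as.integer(sort(table(alleles))), c(4L, 4L))
      het <- vapply(a$spores, function(sp)
        length(unique(vapply(sp$nuclei, `[[`, "", l))) > 1, TRUE)
      if (a$sds_pattern[[l]]) expect_true(all(het)) else expect_false(any(het))
    }
  }
})

test_that("the SDS frequency of a locus converges to its sds_prob", {
  s <- 0.35
  n <- 4000
  sim <- simulate_cross(neutral_cross(s = s), n_asci = n, seed = 7,
                        survivors = TRUE)
  # with no killer every ascus is 4-spored; SDS asci are all-heterokaryotic
  sds_frac <- mean(tapply(sim$survivors$heterokaryotic, sim$survivors$ascus, all))
  expect_lt(abs(sds_frac - s), 3 * sqrt(s * (1 - s) / n))
})

test_that("uninucleate octads hold eight single-nucleus spores that cannot be
           heterokaryotic", {
  cx <- neutral_cross(s = 1)
  cx$packaging <- "uninucleate_octad"
  a <- simulate_meiosis(cx, seed = 2)
  expect_length(a$spores, 8L)
  for (sp in a$spores) expect_length(sp$nuclei, 1L)
  alleles <- vapply(a$spores, function(sp) sp$nuclei[[1]][["L1"]], "")
  expect_equal(as.integer(sort(table(alleles))), c(4L, 4L))
})

test_that("mechanistic crossover mode reproduces the no-interference SDS
           closed form", {
  x <- 0.3
  n <- 3000
  s_theory <- sds_from_map_length(x)
  sim <- simulate_cross(neutral_cross(s = 0, mode = "mechanistic", x = x),
                        n_asci = n, seed = 11)
  sds_frac <- mean(tapply(sim$survivors$heterokaryotic, sim$survivors$ascus, all))
  expect_lt(abs(sds_frac - s_theory), 3 * sqrt(s_theory * (1 - s_theory) / n))
})

test_that("pigmentation is dominant over the insertion null allele", {
  cx <- registry_cross("PaPKS1_Spok1xS")
  hap_ins <- c(spok1 = "Spok1_0", spok2 = "Spok2", pks1 = "pks1_Spok1")
  hap_wt <- c(spok1 = "Spok1_0", spok2 = "Spok2", pks1 = "PKS1")
  expect_false(spore_pigment(list(nuclei = list(hap_ins, hap_ins)), cx))
  expect_true(spore_pigment(list(nuclei = list(hap_ins, hap_wt)), cx))
  expect_true(spore_pigment(list(nuclei = list(hap_wt, hap_wt)), cx))
  # crosses without a pigmentation locus default to pigmented
  expect_true(spore_pigment(list(nuclei = list(c(L1 = "A"))), neutral_cross(0.5)))
})
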