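# Killing engine: responder coverage, trans-activation, and the survival rule.

test_that("responder coverage follows the resistance epistasis of the Spok
           system", {
  ctx_sxt <- zygote_context(registry_cross("SxT"))
  lib <- spok_strain_library()
  spore_of <- function(strain)
    list(nuclei = list(lib[[strain]]$alleles, lib[[strain]]$alleles))
  # Spok1 protects against both killers (and the heterologous one)
  cov_t <- effective_responders(spore_of("T"), ctx_sxt)
  expect_true(all(c("Spok1", "Spok2", "pks1_SpokN") %in% cov_t))
  # Spok2 does not protect against Spok1
  cov_s <- effective_responders(spore_of("S"), ctx_sxt)
  expect_true("Spok2" %in% cov_s)
  expect_false("Spok1" %in% cov_s)
})

test_that("a trans-activated responder works only when its activator is in
           the zygote", {
  lib <- spok_strain_library()
  mch <- lib$PaPKS1_mCherry_Spok2$alleles
  spore <- list(nuclei = list(mch, mch))
  # no wild-type Spok2 anywhere: coverage lost entirely
  ctx_off <- zygote_context(registry_cross("mCherry_Spok2xSpok2D"))
  expect_length(effective_responders(spore, ctx_off), 0L)
  # a wild-type Spok2 copy restores coverage of the Spok2 family
  ctx_on <- zygote_context(registry_cross("mCherry_Spok2xPaPKS1_Spok2"))
  cov <- effective_responders(spore, ctx_on)
  expect_true(all(c("Spok2", "pks1_mCherry_Spok2") %in% cov))
})

test_that("undeclared allele ids in a spore raise a configuration error", {
  ctx <- zygote_context(killer_cross())
  expect_error(
    effective_responders(list(nuclei = list(c(sk = "mystery"))), ctx),
    "undeclared")
})

test_that("killing an S x T first-division ascus leaves the two killer-carrying
           spores", {
  cx <- registry_cross("SxT")
  ctx <- zygote_context(cx)
  set.seed(5)
  a <- ascus_with_pattern(cx, c(spok1 = FALSE)) # FDS at the killer
  a <- apply_spore_killing(a, ctx)
  viable <- vapply(a$spores, `[[`, TRUE, "viable")
  expect_equal(sum(viable), 2L)
  for (sp in a$spores[viable])
    expect_true(all(vapply(sp$nuclei, `[[`, "", "spok1") == "Spok1"))
  expect_equal(classify_ascus(a)$class, "2-spored")
})

test_that("a second-division killer ascus survives intact through
           heterokaryotic rescue", {
  cx <- registry_cross("SKT20xS")
  ctx <- zygote_context(cx)
  set.seed(6)
  a <- ascus_with_pattern(cx, c(spok1 = TRUE)) # SDS: all spores Spok1/Spok1_0
  a <- apply_spore_killing(a, ctx)
  expect_true(all(vapply(a$spores, `[[`, TRUE, "viable")))
})

test_that("a killer without effective responder kills every spore; without
           any distorter every spore lives", {
  set.seed(8)
  # mCherry-Spok2 style: killer, no activator present
  cxe <- registry_cross("mCherry_Spok2xSpok2D")
  a <- apply_spore_killing(simulate_meiosis(cxe), zygote_context(cxe))
  expect_false(any(vapply(a$spores, `[[`, TRUE, "viable")))
  expect_equal(classify_ascus(a)$class, "empty")
  # no distorter at all
  cx0 <- registry_cross("Spok1DxSpok2D")
  a0 <- apply_spore_killing(simulate_meiosis(cx0), zygote_context(cx0))
  expect_true(all(vapply(a0$spores, `[[`, TRUE, "viable")))
})

test_that("homozygous distorters are silent: every homozygous reference cross
           is 100% four-spored", {
  for (id in c("SxS", "TxT", "SKT20xSKT20", "Spok2DxSpok2D")) {
    d <- enumerate_cross(registry_cross(id))
    expect_equal(percent_class(d, "4-spored"), 100, tolerance = 1e-12)
  }
})

test_that("every simulated survivor's effective responders cover the active
           distorters", {
  for (id in c("SxT", "SpokNxS")) {
    cx <- registry_cross(id)
    ctx <- zygote_context(cx)
    sim <- simulate_cross(cx, n_asci = 300, seed = 9)
    loci <- names(cx$loci)
    for (i in seq_len(nrow(sim$survivors))) {
      sp <- survivor_spore(sim$survivors[i, ], loci)
      expect_true(all(ctx$active_distorters %in% effective_responders(sp, ctx)))
    }
  }
})

test_that("a heterozygous distorter masked by the complementary killer does
           not change ascus-class frequencies", {
  # Spok2 heterozygous and masked by Spok1 (S x T) vs Spok2 homozygous
  # (SKT20 x S): identical exact class distributions
  d_masked <- enumerate_cross(registry_cross("SxT"))
  d_homo <- enumerate_cross(registry_cross("SKT20xS"))
  for (cl in c("4-spored", "2-spored", "empty"))
    expect_equal(percent_class(d_masked, cl), percent_class(d_homo, cl),
                 tolerance = 1e-12)
})

test_that("partial killing efficiency produces odd spore classes", {
  d <- enumerate_cross(killer_cross(s = 0, efficiency = 0.5))
  expect_equal(percent_class(d, "4-spored"), 25, tolerance = 1e-9)
  expect_equal(percent_class(d, "3-spored"), 50, tolerance = 1e-9)
  expect_equal(percent_class(d, "2-spored"), 25, tolerance = 1e-9)
})
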