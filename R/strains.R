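# Reference strain library and cross registry: every characterised strain,
# allele and cross of the Spok spore-killer system, encoded so that the
# killing engine reproduces the published ascus phenotypes.
#
# Loci:
#   spok1 - chromosome 5, tightly centromere-linked (SDS 0.10)
#   spok2 - chromosome 5, ~600 kb away on the same arm (SDS 0.60);
#           recombination fraction to spok1 defaults to 0.5 (the observed
#           ~50:50 Spok2 segregation among S x T survivors)
#   pks1  - the PaPKS1 melanin polyketide-synthase locus at the chromosome-2
#           centromere (SDS 0.01); insertion alleles are pigment-null and
#           dominant-functional wild type is pigmented
#
# Resistance epistasis is encoded as two coverage families:
#   Spok1-family killers are resisted only by Spok1-type responders;
#   Spok2-family killers (incl. the tagged/mutant/heterologous alleles) are
#   resisted by both Spok1- and Spok2-type responders.
# Trans-activated responders (mCherry-Spok2, Spok2-AA, Spok-N) protect only
# when a wild-type Spok2 copy is present in the zygote.

SPOK1_FAMILY <- c("Spok1", "pks1_Spok1", "pks1_GFP_Spok1")
SPOK2_FAMILY <- c("Spok2", "pks1_Spok2", "pks1_Spok2AA",
                  "pks1_mCherry_Spok2", "pks1_SpokN")
SPOK2_WT <- c("Spok2", "pks1_Spok2") # trans-activators of crippled responders

#' Reference allele set of the Spok system
#'
#' @return Named list of [allele()] objects.
#' @export
spok_alleles <- function() {
  covers_all <- c(SPOK1_FAMILY, SPOK2_FAMILY)
  al <- list(
    # chromosome-5 spok1 locus
    allele("Spok1", "spok1", distorter_active = TRUE,
           responder_covers = covers_all),
    allele("Spok1_0", "spok1"), # locus devoid of Spok1 (strain S)
    allele("Spok1_D", "spok1", selectable_markers = "hygR"), # CDS replaced
    # chromosome-5 spok2 locus
    allele("Spok2", "spok2", distorter_active = TRUE,
           responder_covers = SPOK2_FAMILY),
    allele("Spok2_0", "spok2"), # locus devoid of Spok2 (strain T)
    allele("Spok2_D", "spok2", selectable_markers = "hygR"),
    allele("Spok2_A", "spok2", # strain A variant: responder-only
           responder_covers = SPOK2_FAMILY),
    allele("Res_A406", "spok2", # uncharacterised resistant non-killer factor
           responder_covers = covers_all),
    # PaPKS1 pigment locus and its insertion alleles (all pigment-null)
    allele("PKS1", "pks1", pigment_functional = TRUE),
    allele("pks1_Spok1", "pks1", distorter_active = TRUE,
           responder_covers = covers_all, pigment_functional = FALSE),
    allele("pks1_Spok2", "pks1", distorter_active = TRUE,
           responder_covers = SPOK2_FAMILY, pigment_functional = FALSE),
    allele("pks1_Spok2AA", "pks1", distorter_active = TRUE,
           responder_covers = SPOK2_FAMILY, trans_activators = SPOK2_WT,
           pigment_functional = FALSE), # kinase-site mutant: killer, crippled responder
    allele("pks1_mCherry_Spok2", "pks1", distorter_active = TRUE,
           responder_covers = SPOK2_FAMILY, trans_activators = SPOK2_WT,
           pigment_functional = FALSE), # N-tag: killer, crippled responder
    allele("pks1_GFP_Spok1", "pks1", distorter_active = TRUE,
           responder_covers = covers_all, pigment_functional = FALSE),
    allele("pks1_Spok1_GFP", "pks1", # C-tag: responder-only
           responder_covers = covers_all, pigment_functional = FALSE),
    allele("pks1_Spok2_mCherry", "pks1", # C-tag: responder-only
           responder_covers = SPOK2_FAMILY, pigment_functional = FALSE),
    allele("pks1_SpokN", "pks1", distorter_active = TRUE,
           responder_covers = SPOK2_FAMILY, trans_activators = SPOK2_WT,
           pigment_functional = FALSE), # heterologous killer, crippled responder
    # Sordaria macrospora transgene locus (uninucleate octads)
    allele("Sm_Spok1", "sm_ins", distorter_active = TRUE,
           responder_covers = "Sm_Spok1"),
    allele("Sm_null", "sm_ins")
  )
  names(al) <- vapply(al, `[[`, "", "id")
  al
}

#' Reference loci of the Spok system
#' @return Named list of [locus()] objects.
#' @export
spok_loci <- function() {
  lo <- list(
    locus("spok1", "5", sds_prob = 0.10),
    locus("spok2", "5", sds_prob = 0.60),
    locus("pks1", "2", sds_prob = 0.01),
    # transgene insertion site in S. macrospora; SDS unconstrained by the
    # octad phenotype (uninucleate spores cannot be heterokaryotic), 0.5 used
    locus("sm_ins", "Sm1", sds_prob = 0.5)
  )
  names(lo) <- vapply(lo, `[[`, "", "id")
  lo
}

#' Reference strain library
#'
#' Named haplotypes over the spok1/spok2/pks1 loci (plus the two Sordaria
#' transformation strains over their insertion locus): the S and T wild
#' isolates, the 20x backcrossed killer introgression strain SKT20 and its
#' deletion derivatives, the PaPKS1 insertion strains of the wild-type,
#' tagged, kinase-mutant and heterologous alleles, the natural responder-only
#' variant (strain A), the resistant non-killer A406, and the Spok-free
#' strains X and CBS411.78.
#'
#' @return Named list of [haplotype()] objects.
#' @export
spok_strain_library <- function() {
  h <- function(id, s1, s2, pk) haplotype(id, c(spok1 = s1, spok2 = s2, pks1 = pk))
  lib <- list(
    S = h("S", "Spok1_0", "Spok2", "PKS1"),
    T = h("T", "Spok1", "Spok2_0", "PKS1"),
    SKT20 = h("SKT20", "Spok1", "Spok2", "PKS1"),
    SKT20D = h("SKT20D", "Spok1_D", "Spok2", "PKS1"),
    Spok1D = h("Spok1D", "Spok1_D", "Spok2_0", "PKS1"), # T background
    Spok2D = h("Spok2D", "Spok1_0", "Spok2_D", "PKS1"), # S background
    SKT20_Spok2D = h("SKT20_Spok2D", "Spok1", "Spok2_D", "PKS1"),
    PaPKS1_Spok1 = h("PaPKS1_Spok1", "Spok1_0", "Spok2", "pks1_Spok1"),
    PaPKS1_Spok2 = h("PaPKS1_Spok2", "Spok1_0", "Spok2_D", "pks1_Spok2"),
    PaPKS1_Spok2AA = h("PaPKS1_Spok2AA", "Spok1_0", "Spok2_D", "pks1_Spok2AA"),
    PaPKS1_mCherry_Spok2 = h("PaPKS1_mCherry_Spok2", "Spok1_0", "Spok2_D",
                             "pks1_mCherry_Spok2"),
    PaPKS1_GFP_Spok1 = h("PaPKS1_GFP_Spok1", "Spok1_0", "Spok2_D",
                         "pks1_GFP_Spok1"),
    PaPKS1_Spok1_GFP = h("PaPKS1_Spok1_GFP", "Spok1_0", "Spok2",
                         "pks1_Spok1_GFP"),
    PaPKS1_Spok2_mCherry = h("PaPKS1_Spok2_mCherry", "Spok1_0", "Spok2_D",
                             "pks1_Spok2_mCherry"),
    PaPKS1_SpokN = h("PaPKS1_SpokN", "Spok1_0", "Spok2_D", "pks1_SpokN"),
    strainA = h("strainA", "Spok1_0", "Spok2_A", "PKS1"),
    A406 = h("A406", "Spok1_0", "Res_A406", "PKS1"),
    X = h("X", "Spok1_0", "Spok2_0", "PKS1"),
    CBS411_78 = h("CBS411_78", "Spok1_0", "Spok2_0", "PKS1"),
    Sm_Spok1 = haplotype("Sm_Spok1", c(sm_ins = "Sm_Spok1")),
    Sm_wt = haplotype("Sm_wt", c(sm_ins = "Sm_null"))
    # Strain Y and P. comata CBS237.71 carry a third, uncharacterised
    # Spok-related killer ("Spok3", 90% SDS vs strain S) whose interaction
    # with the Spok1 killer is unresolved; they are deliberately not encoded:
    # Y = h("Y", "?", "Spok3?", "PKS1"),
    # CBS237_71 = h("CBS237_71", "?", "Spok3?", "PKS1"),
  )
  lib
}

#' Build a cross from the reference registry
#'
#' @param id Registry cross id (see [spok_cross_registry()]), or two strain
#'   names joined by `"x"`, e.g. `"SxT"`.
#' @param n_asci,seed Simulation defaults stored in the spec.
#' @return A [cross_spec()].
#' @export
registry_cross <- function(id, n_asci = 10000L, seed = 1L) {
  reg <- spok_cross_registry()
  hit <- reg[reg$id == id, ]
  if (!nrow(hit)) stop("unknown registry cross '", id, "'", call. = FALSE)
  spok_cross(hit$parent1, hit$parent2, packaging = hit$packaging,
             n_asci = n_asci, seed = seed, id = id)
}

#' Cross two library strains
#'
#' @param strain1,strain2 Strain names from [spok_strain_library()].
#' @param packaging Ascus packaging mode.
#' @param n_asci,seed Simulation defaults.
#' @param id Optional cross label.
#' @return A [cross_spec()] restricted to the loci the strains carry, with
#'   the default spok1-spok2 linkage (r = 0.5).
#' @export
spok_cross <- function(strain1, strain2,
                       packaging = c("binucleate_tetrad", "uninucleate_octad"),
                       n_asci = 10000L, seed = 1L, id = NULL) {
  lib <- spok_strain_library()
  for (s in c(strain1, strain2))
    if (!s %in% names(lib)) stop("unknown strain '", s, "'", call. = FALSE)
  p1 <- lib[[strain1]]; p2 <- lib[[strain2]]
  loci <- spok_loci()[names(p1$alleles)]
  link <- data.frame(locus1 = "spok1", locus2 = "spok2", r = 0.5)
  link <- link[link$locus1 %in% names(loci) & link$locus2 %in% names(loci), ]
  cross_spec(p1, p2, loci = loci, alleles = spok_alleles(),
             linkage = if (nrow(link)) link,
             packaging = packaging, n_asci = n_asci, seed = seed,
             id = id %||% paste0(strain1, "x", strain2))
}

#' Registry of reference crosses with their published outcomes
#'
#' One row per documented cross, with the expected ascus-class percentages
#' (exact model expectations; `NA` where the source is qualitative) used by
#' the test harness: `expected_2spored`, `expected_4spored`,
#' `expected_empty` as percentages of all asci, and
#' `expected_2sp_unpigmented` where pigmentation was scored. `deterministic`
#' marks outcomes that are certain (100%/0%) rather than stochastic.
#'
#' @return Data frame, one row per registry cross.
#' @export
spok_cross_registry <- function() {
  r <- function(id, p1, p2, e2, e4, eempty = 0, e2u = NA, det = FALSE,
                pack = "binucleate_tetrad", note = "") {
    data.frame(id = id, parent1 = p1, parent2 = p2, expected_2spored = e2,
               expected_4spored = e4, expected_empty = eempty,
               expected_2sp_unpigmented = e2u, deterministic = det,
               packaging = pack, note = note, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    r("SxS", "S", "S", 0, 100, det = TRUE),
    r("TxT", "T", "T", 0, 100, det = TRUE),
    r("SxT", "S", "T", 90, 10, note = "all survivors carry Spok1; Spok2 50:50"),
    r("SKT20xS", "SKT20", "S", 90, 10),
    r("SKT20xT", "SKT20", "T", 0, 100, det = TRUE,
      note = "Spok2 heterozygous but masked by homozygous Spok1"),
    r("SKT20xSKT20", "SKT20", "SKT20", 0, 100, det = TRUE),
    r("SKT20DxSKT20", "SKT20D", "SKT20", 90, 10),
    r("SKT20DxSKT20D", "SKT20D", "SKT20D", 0, 100, det = TRUE),
    r("SKT20DxS", "SKT20D", "S", 0, 100, det = TRUE),
    r("Spok1DxT", "Spok1D", "T", 90, 10),
    r("Spok1DxSpok1D", "Spok1D", "Spok1D", 0, 100, det = TRUE),
    r("Spok1DxS", "Spok1D", "S", 40, 60, note = "all survivors carry Spok2"),
    r("Spok2DxS", "Spok2D", "S", 40, 60),
    r("Spok2DxSpok2D", "Spok2D", "Spok2D", 0, 100, det = TRUE),
    r("Spok2DxT", "Spok2D", "T", 90, 10),
    r("Spok1DxSpok2D", "Spok1D", "Spok2D", 0, 100, det = TRUE),
    r("SKT20xSpok2D", "SKT20", "Spok2D", 90, 10),
    r("SKT20_Spok2DxSKT20", "SKT20_Spok2D", "SKT20", 0, 100, det = TRUE,
      note = "Spok2 masked by homozygous Spok1; Spok2:Spok2_D 50:50 expected"),
    r("SKT20_Spok2DxSKT20_Spok2D", "SKT20_Spok2D", "SKT20_Spok2D", 0, 100,
      det = TRUE),
    r("PaPKS1_Spok1xS", "PaPKS1_Spok1", "S", 99, 1, e2u = 99,
      note = "survivors colorless; 4-spored asci are PaPKS1 SDS, pigmented"),
    r("PaPKS1_Spok2xSpok2D", "PaPKS1_Spok2", "Spok2D", 99, 1, e2u = 99),
    r("mCherry_Spok2xSpok2D", "PaPKS1_mCherry_Spok2", "Spok2D", 0, 0,
      eempty = 100, det = TRUE, note = "killer without effective responder"),
    r("mCherry_Spok2xPaPKS1_Spok2", "PaPKS1_mCherry_Spok2", "PaPKS1_Spok2",
      0, 100, det = TRUE, note = "responder restored by wild-type Spok2 copy"),
    r("Spok2AAxSpok2D", "PaPKS1_Spok2AA", "Spok2D", 0, 0, eempty = 100,
      det = TRUE),
    r("Spok2AAxPaPKS1_Spok2", "PaPKS1_Spok2AA", "PaPKS1_Spok2", 0, 100,
      det = TRUE),
    r("Spok2AAxPaPKS1_Spok1", "PaPKS1_Spok2AA", "PaPKS1_Spok1", 99, 1,
      e2u = 99, note = "Spok1 acts alone; every spore colorless"),
    r("SpokNxSpok2D", "PaPKS1_SpokN", "Spok2D", 0, 0, eempty = 100,
      det = TRUE, note = "barren: non-autonomous killing, no resistance"),
    r("SpokNxPaPKS1_Spok2", "PaPKS1_SpokN", "PaPKS1_Spok2", 0, 100,
      det = TRUE),
    r("SpokNxPaPKS1_Spok1", "PaPKS1_SpokN", "PaPKS1_Spok1", 99, 1, e2u = 99),
    r("SpokNxS", "PaPKS1_SpokN", "S", NA, NA,
      note = "Spok2 confers resistance to SpokN; mixed classes"),
    r("Spok1GFPxS", "PaPKS1_Spok1_GFP", "S", 0, 100, det = TRUE,
      note = "responder-only transgene, no killer segregates"),
    r("Spok2mCherryxSpok2D", "PaPKS1_Spok2_mCherry", "Spok2D", 0, 100,
      det = TRUE),
    r("AxS", "strainA", "S", 0, 100, det = TRUE,
      note = "strain A allele resists Spok2 but cannot kill"),
    r("AxSKT20", "strainA", "SKT20", 90, 10),
    r("AxSpok1D", "strainA", "Spok1D", 0, 100, det = TRUE),
    r("AxSpok2D", "strainA", "Spok2D", 0, 100, det = TRUE,
      note = "50% hygR homokaryotic progeny expected"),
    r("A406xS", "A406", "S", 0, 100, det = TRUE),
    r("A406xSpok1D", "A406", "Spok1D", 0, 100, det = TRUE),
    r("A406xSpok2D", "A406", "Spok2D", 0, 100, det = TRUE),
    r("XxS", "X", "S", 40, 60,
      note = "model expectation from Spok2 SDS 0.60 (printed round figure 50)"),
    r("XxT", "X", "T", 90, 10),
    r("XxSKT20", "X", "SKT20", 90, 10),
    r("XxSpok1D", "X", "Spok1D", 0, 100, det = TRUE),
    r("XxSpok2D", "X", "Spok2D", 0, 100, det = TRUE),
    r("CBS411xS", "CBS411_78", "S", 40, 60,
      note = "Spok-free like X (printed round figure 50)"),
    r("CBS411xT", "CBS411_78", "T", 90, 10),
    r("Sm_Spok1xSm_wt", "Sm_Spok1", "Sm_wt", NA, NA,
      pack = "uninucleate_octad",
      note = "octads: 4 viable pigmented + 4 dead spores in every ascus")
    # Strain Y / CBS237.71 ("Spok3") crosses with T and SKT20 are untestable:
    # low fertility and an unresolved killer-killer interaction.
  ))
}

#' Generate a synthetic progeny marker-genotype matrix
#'
#' Simulates the cross, samples per ascus one surviving spore that is
#' homokaryotic at the driver locus (i.e. from a killed, first-division
#' ascus; asci without one are skipped), and codes each marker by parental
#' origin. A locus at which the sampled spore is heterokaryotic resolves to
#' one of its nuclei uniformly (genotyping of a binucleate spore follows one
#' nuclear haplotype).
#'
#' @param n_progeny Number of progeny rows.
#' @param cross A [cross_spec()] whose loci are the driver plus markers.
#' @param driver_locus Locus id of the driver.
#' @param codes Two labels for parent-1 and parent-2 origin (default
#'   `c("S", "T")`).
#' @param seed Optional integer seed.
#' @return Character matrix `n_progeny` x markers (columns named by locus),
#'   coded by parental origin.
#' @export
generate_marker_dataset <- function(n_progeny, cross, driver_locus,
                                    codes = c("S", "T"), seed = NULL) {
  stopifnot(inherits(cross, "cross_spec"), n_progeny >= 1)
  if (!driver_locus %in% names(cross$loci))
    stop("driver locus '", driver_locus, "' not in cross", call. = FALSE)
  if (length(cross$loci) < 1L) stop("no marker loci", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cc <- compile_cross(cross)
  loci <- cc$locus_ids
  out <- matrix(NA_character_, 0, length(loci), dimnames = list(NULL, loci))
  while (nrow(out) < n_progeny) {
    batch <- ceiling((n_progeny - nrow(out)) * 2.5) + 20L
    sim <- simulate_cross(cross, n_asci = batch, seed = NA)
    surv <- sim$survivors
    # homokaryotic at the driver: genotype string without "/"
    surv <- surv[!grepl("/", surv[[driver_locus]], fixed = TRUE), , drop = FALSE]
    if (!nrow(surv)) next
    pick <- surv[!duplicated(surv$ascus), , drop = FALSE] # one spore per ascus
    g <- sapply(loci, function(l) {
      alleles <- strsplit(pick[[l]], "/", fixed = TRUE)
      vapply(alleles, function(a)
        if (length(a) == 1L) a else sample(a, 1L), "")
    })
    g <- matrix(g, nrow = nrow(pick), dimnames = list(NULL, loci))
    orig <- g
    for (j in seq_along(loci)) # code by parental origin
      orig[, j] <- ifelse(g[, j] == cc$a1[j], codes[1], codes[2])
    out <- rbind(out, orig)
  }
  out[seq_len(n_progeny), , drop = FALSE]
}

#' Synthetic marker map for transmission scans
#'
#' Ten marker loci spaced along one chromosome, the driver collocated with
#' the second (centromere-proximal) marker; SDS probabilities follow the
#' mapping-function closed form for the marker positions and adjacent-pair
#' recombination fractions follow Haldane's function, so the phenomenological
#' chain approximates a physical map.
#'
#' @param driver_sds SDS frequency of the driver (default 0.10).
#' @param n_markers Number of markers (default 10).
#' @return List with `cross` (a [cross_spec()] of an S x T-like cross over the
#'   driver and markers) and `driver_locus`.
#' @export
scan_test_cross <- function(driver_sds = 0.10, n_markers = 10) {
  # driver position back-solved from its SDS frequency
  xd <- -log(1 - 1.5 * driver_sds) / 3
  pos <- sort(unique(c(xd, seq(0.05, 2, length.out = n_markers - 1))))
  ids <- sprintf("m%02d", seq_along(pos))
  driver_id <- ids[which(pos == xd)[1]]
  loci <- lapply(seq_along(pos), function(i)
    locus(ids[i], "5", sds_prob = sds_from_map_length(pos[i]),
          position_morgans = pos[i]))
  link <- data.frame(locus1 = ids[-length(ids)], locus2 = ids[-1],
                     r = haldane_r(diff(pos)))
  alleles <- list(); a1 <- character(); a2 <- character()
  for (i in seq_along(ids)) {
    sA <- paste0(ids[i], "_S"); tA <- paste0(ids[i], "_T")
    if (ids[i] == driver_id) {
      alleles <- c(alleles, list(
        allele(tA, ids[i], distorter_active = TRUE, responder_covers = tA),
        allele(sA, ids[i])))
    } else {
      alleles <- c(alleles, list(allele(sA, ids[i]), allele(tA, ids[i])))
    }
    a1 <- c(a1, sA); a2 <- c(a2, tA)
  }
  names(a1) <- ids; names(a2) <- ids
  cx <- cross_spec(haplotype("Slike", a1), haplotype("Tlike", a2),
                   loci = loci, alleles = alleles, linkage = link,
                   id = "scan_synthetic")
  list(cross = cx, driver_locus = driver_id)
}
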