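# Small cross builders used across the suite.

# single heterozygous killer locus: killer allele K (self-covering unless
# covers = character()) against an inert allele k0
killer_cross <- function(s = 0.1, covers = "K", efficiency = 1,
                         packaging = "binucleate_tetrad",
                         mode = "phenomenological", x = NA_real_,
                         n_asci = 1000L, seed = NULL) {
  al <- list(allele("K", "sk", distorter_active = TRUE,
                    responder_covers = covers,
                    killing_efficiency = efficiency),
             allele("k0", "sk"))
  cross_spec(haplotype("killer", c(sk = "K")),
             haplotype("sensitive", c(sk = "k0")),
             loci = list(locus("sk", "1", sds_prob = s, position_morgans = x)),
             alleles = al, packaging = packaging, mode = mode,
             n_asci = n_asci, seed = seed, id = "killer_test")
}

# neutral two-allele cross at one locus (no killing)
neutral_cross <- function(s, mode = "phenomenological", x = NA_real_) {
  al <- list(allele("A", "L1"), allele("a", "L1"))
  cross_spec(haplotype("p1", c(L1 = "A")), haplotype("p2", c(L1 = "a")),
             loci = list(locus("L1", "1", sds_prob = s, position_morgans = x)),
             alleles = al, mode = mode, id = "neutral_test")
}

# carried alleles of a survivor-table row, as a spore-like object
survivor_spore <- function(row, locus_ids) {
  genos <- lapply(locus_ids, function(l) strsplit(row[[l]], "/", fixed = TRUE)[[1]])
  nuc1 <- vapply(genos, `[`, "", 1)
  nuc2 <- vapply(genos, function(g) g[length(g)], "")
  names(nuc1) <- names(nuc2) <- locus_ids
  list(nuclei = list(nuc1, nuc2))
}

# draw asci until one matches a per-locus FDS/SDS requirement
ascus_with_pattern <- function(cross, want_sds, max_tries = 2000) {
  for (i in seq_len(max_tries)) {
    a <- simulate_meiosis(cross)
    ok <- all(vapply(names(want_sds), function(l)
      a$sds_pattern[[l]] == want_sds[[l]], TRUE))
    if (ok) return(a)
  }
  stop("no ascus with requested segregation pattern in ", max_tries, " draws")
}
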