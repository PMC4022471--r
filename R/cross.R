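#' Specify a cross
#'
#' Bundles the two parental haplotypes, the loci they segregate at, the
#' declared allele set, pairwise linkage, and the ascospore packaging mode.
#'
#' Two linkage modes are available. The phenomenological mode (default, used
#' for all reference crosses) draws each locus's first-/second-division
#' segregation pattern with its own `sds_prob`, and couples parental origins
#' of same-chromosome loci through per-chromatid recombination events with
#' probability `r` between adjacent loci (default r = 0.5: independence). The
#' mechanistic mode places Poisson crossovers on an interval map (no
#' interference, two of four chromatids per crossover); SDS frequencies and
#' recombination fractions then emerge from `position_morgans`.
#'
#' @param parent1,parent2 [haplotype()] objects.
#' @param loci List of [locus()] objects covering every locus named in the
#'   haplotypes.
#' @param alleles List of [allele()] objects declaring every allele id used.
#' @param linkage Optional data frame with columns `locus1`, `locus2`, `r`
#'   giving recombination fractions in [0, 0.5] for same-chromosome locus
#'   pairs (default 0.5; different chromosomes always assort independently).
#' @param packaging `"binucleate_tetrad"` (four two-nucleus ascospores, as in
#'   *Podospora anserina*) or `"uninucleate_octad"` (eight one-nucleus
#'   ascospores, as in *Sordaria macrospora*).
#' @param n_asci Default number of asci for [simulate_cross()].
#' @param seed Default simulation seed (recorded in outputs).
#' @param mode `"phenomenological"` or `"mechanistic"`.
#' @param id Optional cross label.
#' @return An object of class `"cross_spec"`.
#' @examples
#' al <- list(allele("K", "sk", distorter_active = TRUE, responder_covers = "K"),
#'            allele("k0", "sk"))
#' cx <- cross_spec(haplotype("killer", c(sk = "K")),
#'                  haplotype("sensitive", c(sk = "k0")),
#'                  loci = list(locus("sk", "1", sds_prob = 0.1)),
#'                  alleles = al)
#' @export
cross_spec <- function(parent1, parent2, loci, alleles, linkage = NULL,
                       packaging = c("binucleate_tetrad", "uninucleate_octad"),
                       n_asci = 1000L, seed = NULL,
                       mode = c("phenomenological", "mechanistic"),
                       id = NULL) {
  packaging <- match.arg(packaging)
  mode <- match.arg(mode)
  stopifnot(inherits(parent1, "spok_haplotype"), inherits(parent2, "spok_haplotype"))
  if (inherits(loci, "spok_locus")) loci <- list(loci)
  if (inherits(alleles, "spok_allele")) alleles <- list(alleles)
  locus_ids <- vapply(loci, `[[`, "", "id")
  if (anyDuplicated(locus_ids)) stop("duplicated locus ids", call. = FALSE)
  allele_ids <- vapply(alleles, `[[`, "", "id")
  if (anyDuplicated(allele_ids)) stop("duplicated allele ids", call. = FALSE)
  names(loci) <- locus_ids
  names(alleles) <- allele_ids

  for (h in list(parent1, parent2)) {
    missing <- setdiff(locus_ids, names(h$alleles))
    if (length(missing))
      stop(sprintf("haplotype '%s' lacks an allele at locus: %s",
                   h$strain_id, paste(missing, collapse = ", ")), call. = FALSE)
    undeclared <- setdiff(h$alleles[locus_ids], allele_ids)
    if (length(undeclared))
      stop(sprintf("haplotype '%s' uses undeclared allele id: %s",
                   h$strain_id, paste(undeclared, collapse = ", ")), call. = FALSE)
    for (lid in locus_ids) {
      aid <- h$alleles[[lid]]
      if (alleles[[aid]]$locus_id != lid)
        stop(sprintf("allele '%s' belongs to locus '%s', not '%s'",
                     aid, alleles[[aid]]$locus_id, lid), call. = FALSE)
    }
  }
  for (a in alleles) {
    bad <- setdiff(c(a$responder_covers, a$trans_activators), allele_ids)
    if (length(bad))
      stop(sprintf("allele '%s' references undeclared allele id: %s",
                   a$id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(linkage)) {
    linkage <- as.data.frame(linkage)
    if (!all(c("locus1", "locus2", "r") %in% names(linkage)))
      stop("'linkage' needs columns locus1, locus2, r", call. = FALSE)
    if (any(linkage$r < 0 | linkage$r > 0.5))
      stop("recombination fractions must lie in [0, 0.5]", call. = FALSE)
    bad <- setdiff(c(linkage$locus1, linkage$locus2), locus_ids)
    if (length(bad))
      stop("linkage references unknown locus: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (!is.numeric(n_asci) || length(n_asci) != 1L || n_asci < 1)
    stop("'n_asci' must be a positive integer", call. = FALSE)
  if (mode == "mechanistic") {
    pos <- vapply(loci, `[[`, 0, "position_morgans")
    if (anyNA(pos))
      stop("mechanistic mode requires 'position_morgans' for every locus",
           call. = FALSE)
  }
  structure(list(parent1 = parent1, parent2 = parent2, loci = loci,
                 alleles = alleles, linkage = linkage, packaging = packaging,
                 n_asci = as.integer(n_asci), seed = seed, mode = mode,
                 id = id %||% paste0(parent1$strain_id, "x", parent2$strain_id)),
            class = "cross_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cross_spec <- function(x, ...) {
  cc <- compile_cross(x)
  cat(sprintf("<cross %s: %s x %s; %d loci (%d heterozygous); %s, %s mode>\n",
              x$id, x$parent1$strain_id, x$parent2$strain_id,
              length(x$loci), sum(cc$het), x$packaging, x$mode))
  for (j in seq_along(cc$locus_ids))
    cat(sprintf("  %s (chr%s, s=%.3g): %s / %s%s\n", cc$locus_ids[j],
                cc$chrom[j], cc$sds[j], cc$a1[j], cc$a2[j],
                if (cc$het[j]) "" else " [homozygous]"))
  if (length(cc$distorters))
    cat("  active distorters in zygote:", paste(cc$distorters, collapse = ", "), "\n")
  invisible(x)
}

# The six possible parental-origin vectors of the four meiotic products
# (chromatids ordered pole1-product1, pole1-product2, pole2-product1,
# pole2-product2). Rows 1:2 are first-division segregation (each pole
# uniform), rows 3:6 second-division segregation (each pole mixed).
.ORIGIN_V <- rbind(c(1L, 1L, 2L, 2L), c(2L, 2L, 1L, 1L),
                   c(1L, 2L, 1L, 2L), c(1L, 2L, 2L, 1L),
                   c(2L, 1L, 1L, 2L), c(2L, 1L, 2L, 1L))
.FDS_CODES <- 1:2
.SDS_CODES <- 3:6

# Hamming distances between origin vectors, 6 x 6
.ORIGIN_MISMATCH <- local({
  m <- matrix(0L, 6, 6)
  for (u in 1:6) for (v in 1:6) m[u, v] <- sum(.ORIGIN_V[u, ] != .ORIGIN_V[v, ])
  m
})

# Initial distribution over origin codes for SDS probability s
origin_init_probs <- function(s) c(rep((1 - s) / 2, 2), rep(s / 4, 4))

# Transition matrix between adjacent same-chromosome loci: the new locus's
# FDS/SDS pattern is drawn with its own s; within the pattern class the
# origin vector is chosen with weight r^m (1-r)^(4-m) against the previous
# locus's vector (m = per-chromatid origin mismatches), modelling a
# recombination event per meiotic product with probability r. r = 0.5 gives
# independence; r = 0 maximal coupling (minimal-mismatch vectors).
origin_transition <- function(s, r) {
  T <- matrix(0, 6, 6)
  for (u in 1:6) {
    m <- .ORIGIN_MISMATCH[u, ]
    w <- r^m * (1 - r)^(4 - m)
    for (cls in list(list(codes = .FDS_CODES, p = 1 - s),
                     list(codes = .SDS_CODES, p = s))) {
      wc <- w[cls$codes]
      if (sum(wc) == 0) wc <- as.numeric(m[cls$codes] == min(m[cls$codes]))
      T[u, cls$codes] <- cls$p * wc / sum(wc)
    }
  }
  T
}

# Crossover action on origin codes for the mechanistic mode: one crossover
# exchanges the distal segments of one chromatid of each pole, i.e. swaps two
# entries of the origin vector (one from positions 1:2, one from 3:4), each
# of the 4 pairs equally likely.
.CROSSOVER_STEP <- local({
  M <- matrix(0, 6, 6)
  for (u in 1:6) for (a in 1:2) for (b in 3:4) {
    v <- .ORIGIN_V[u, ]
    v[c(a, b)] <- v[c(b, a)]
    code <- which(apply(.ORIGIN_V, 1, identical, v))
    M[u, code] <- M[u, code] + 0.25
  }
  M
})

# Compiled, validated view of a cross used by the simulation/enumeration
# engines: loci ordered within chromosome, parental alleles, heterozygosity,
# Markov-chain pieces, distorter coverage matrices, pigmentation.
compile_cross <- function(cross) {
  loci <- cross$loci
  locus_ids <- names(loci)
  chrom <- vapply(loci, `[[`, "", "chromosome")
  pos <- vapply(loci, `[[`, 0, "position_morgans")
  sds <- vapply(loci, `[[`, 0, "sds_prob")
  # order loci by chromosome, then position (input order when positions absent)
  ord <- order(match(chrom, unique(chrom)),
               ifelse(is.na(pos), seq_along(loci), pos))
  loci <- loci[ord]; locus_ids <- locus_ids[ord]
  chrom <- chrom[ord]; pos <- pos[ord]; sds <- sds[ord]

  a1 <- unname(cross$parent1$alleles[locus_ids])
  a2 <- unname(cross$parent2$alleles[locus_ids])
  het <- a1 != a2

  r_lookup <- function(l1, l2) {
    if (is.null(cross$linkage)) return(0.5)
    hit <- which((cross$linkage$locus1 == l1 & cross$linkage$locus2 == l2) |
                 (cross$linkage$locus1 == l2 & cross$linkage$locus2 == l1))
    if (length(hit)) cross$linkage$r[hit[1]] else 0.5
  }

  chains <- lapply(split(seq_along(locus_ids), factor(chrom, unique(chrom))),
                   function(idx) {
    r_prev <- c(NA_real_,
                if (length(idx) > 1)
                  vapply(seq_len(length(idx) - 1), function(k)
                    r_lookup(locus_ids[idx[k]], locus_ids[idx[k + 1]]), 0))
    list(idx = idx, r_prev = r_prev)
  })

  alleles <- cross$alleles
  zygote <- unique(c(a1, a2))
  distorters <- zygote[vapply(zygote, function(a)
    alleles[[a]]$distorter_active, TRUE)]
  eff <- vapply(zygote, function(a)
    alleles[[a]]$killing_efficiency, 0)[match(distorters, zygote)]

  # effective coverage of each zygote allele against each active distorter,
  # resolving trans-activation against the zygote allele content
  covers_eff <- function(aid) {
    a <- alleles[[aid]]
    if (length(a$trans_activators) &&
        !any(a$trans_activators %in% zygote)) return(character())
    a$responder_covers
  }
  cov1 <- matrix(FALSE, length(locus_ids), length(distorters),
                 dimnames = list(locus_ids, distorters))
  cov2 <- cov1
  for (j in seq_along(locus_ids)) {
    cov1[j, ] <- distorters %in% covers_eff(a1[j])
    cov2[j, ] <- distorters %in% covers_eff(a2[j])
  }

  pig1 <- vapply(a1, function(a) alleles[[a]]$pigment_functional, NA)
  pig2 <- vapply(a2, function(a) alleles[[a]]$pigment_functional, NA)
  pig_loci <- which(!is.na(pig1) | !is.na(pig2))

  list(locus_ids = locus_ids, chrom = chrom, pos = pos, sds = sds,
       a1 = a1, a2 = a2, het = het, chains = chains,
       distorters = distorters, efficiency = eff,
       cov1 = cov1, cov2 = cov2,
       pig1 = isTRUE_vec(pig1), pig2 = isTRUE_vec(pig2), pig_loci = pig_loci,
       zygote = zygote, packaging = cross$packaging, mode = cross$mode)
}

isTRUE_vec <- function(x) !is.na(x) & x
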