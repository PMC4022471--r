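# Meiosis engine: sampling of parental-origin codes for every locus of every
# ascus, and packaging of the eight post-meiotic nuclei into spores.
#
# One meiosis produces four products arranged as two first-division (MI)
# poles of two products each; the post-meiotic mitosis duplicates each
# product, giving eight nuclei. Per locus the parental origins of the four
# products are summarised by one of six origin vectors (.ORIGIN_V): a
# first-division-segregation (FDS) locus has uniform poles, a
# second-division-segregation (SDS) locus mixed poles, with the
# chromatid-within-pole assignment uniform at random.

# vectorised one-step Markov sampling: new code for each row given prev code
sample_markov_step <- function(prev, T) {
  out <- integer(length(prev))
  for (u in unique(prev)) {
    idx <- which(prev == u)
    out[idx] <- sample.int(6L, length(idx), replace = TRUE, prob = T[u, ])
  }
  out
}

# mechanistic step: apply Pois(2*delta) random crossover actions to codes
sample_crossover_step <- function(prev, delta, from_start = FALSE) {
  n <- length(prev)
  nco <- stats::rpois(n, 2 * delta)
  out <- prev
  pows <- list(`0` = diag(6))
  for (k in sort(unique(nco))) {
    if (k == 0L) next
    key <- as.character(k)
    prev_key <- as.character(k - 1L)
    if (is.null(pows[[prev_key]]))
      pows[[prev_key]] <- Reduce(`%*%`, rep(list(.CROSSOVER_STEP), k - 1L),
                                 diag(6))
    pows[[key]] <- pows[[prev_key]] %*% .CROSSOVER_STEP
    idx <- which(nco == k)
    out[idx] <- sample_markov_step(prev[idx], pows[[key]])
  }
  out
}

# n x n_loci matrix of origin codes, honouring per-chromosome coupling
sample_origin_codes <- function(cc, n) {
  codes <- matrix(1L, n, length(cc$locus_ids))
  for (chain in cc$chains) {
    idx <- chain$idx
    if (cc$mode == "phenomenological") {
      codes[, idx[1]] <- sample.int(6L, n, replace = TRUE,
                                    prob = origin_init_probs(cc$sds[idx[1]]))
      for (k in seq_along(idx)[-1]) {
        T <- origin_transition(cc$sds[idx[k]], chain$r_prev[k])
        codes[, idx[k]] <- sample_markov_step(codes[, idx[k - 1]], T)
      }
    } else {
      pos <- cc$pos[idx] # ordered, centromere at 0
      codes[, idx[1]] <- sample_crossover_step(rep(1L, n), pos[1])
      for (k in seq_along(idx)[-1])
        codes[, idx[k]] <- sample_crossover_step(codes[, idx[k - 1]],
                                                 pos[k] - pos[k - 1])
    }
  }
  codes
}

# Exact enumeration closed form for the mechanistic mode (standard tetrad
# theory, Poisson crossovers, no chromatid interference).

#' Second-division segregation frequency at map length x
#'
#' Closed form `s = (2/3) (1 - exp(-3 x))` for the SDS frequency of a locus
#' `x` Morgans from its centromere under Poisson crossovers without
#' interference; asymptote 2/3.
#' @param x Map length in Morgans (non-negative).
#' @return SDS probability.
#' @export
sds_from_map_length <- function(x) {
  stopifnot(all(x >= 0))
  (2 / 3) * (1 - exp(-3 * x))
}

#' Haldane recombination fraction for map distance d Morgans
#' @param d Map distance in Morgans.
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d) 0.5 * (1 - exp(-2 * d))

#' Simulate a single meiosis (one ascus, pre-killing)
#'
#' Generates the four meiotic products of one ascus, duplicates them by the
#' post-meiotic mitosis, and packages the eight nuclei into spores:
#' binucleate-tetrad packaging gives four spores each holding copies of the
#' two distinct products of one MI pole (so an FDS locus yields homokaryotic
#' and an SDS locus heterokaryotic spores); uninucleate-octad packaging gives
#' eight single-nucleus spores.
#'
#' @param cross A [cross_spec()].
#' @param seed Optional integer seed.
#' @return An object of class `"ascus"`: list with `spores` (each a list with
#'   `nuclei`, a list of named locus->allele vectors, plus `viable` and
#'   `pigmented` flags, unset until [apply_spore_killing()] /
#'   [spore_pigment()] run) and `sds_pattern`, a named logical vector (TRUE =
#'   SDS) per locus.
#' @seealso [apply_spore_killing()], [classify_ascus()], [simulate_cross()]
#' @export
simulate_meiosis <- function(cross, seed = NULL) {
  stopifnot(inherits(cross, "cross_spec"))
  if (!is.null(seed)) set.seed(seed)
  cc <- compile_cross(cross)
  codes <- sample_origin_codes(cc, 1L)
  build_ascus(cc, codes[1L, ])
}

# construct an ascus object from one row of origin codes
build_ascus <- function(cc, code_row) {
  nl <- length(cc$locus_ids)
  origin_at <- function(chromatid) {
    o <- .ORIGIN_V[cbind(code_row, rep(chromatid, nl))]
    ifelse(o == 1L, cc$a1, cc$a2)
  }
  products <- lapply(1:4, function(k) {
    g <- origin_at(k)
    names(g) <- cc$locus_ids
    g
  })
  spores <- if (cc$packaging == "binucleate_tetrad") {
    # spores 1,2 from pole 1 (products 1,2), spores 3,4 from pole 2
    lapply(1:4, function(k) {
      p <- if (k <= 2) 1:2 else 3:4
      list(nuclei = products[p], viable = NA, pigmented = NA)
    })
  } else {
    lapply(1:8, function(k)
      list(nuclei = products[ceiling(k / 2)], viable = NA, pigmented = NA))
  }
  sds <- code_row %in% .SDS_CODES
  names(sds) <- cc$locus_ids
  structure(list(spores = spores, sds_pattern = sds,
                 packaging = cc$packaging), class = "ascus")
}

#' @export
print.ascus <- function(x, ...) {
  cat(sprintf("<ascus: %d spores (%s)>\n", length(x$spores), x$packaging))
  for (i in seq_along(x$spores)) {
    sp <- x$spores[[i]]
    g <- vapply(seq_along(sp$nuclei[[1]]), function(j) {
      a <- unique(vapply(sp$nuclei, `[[`, "", j))
      paste(a, collapse = "/")
    }, "")
    cat(sprintf("  spore %d [%s%s]: %s\n", i,
                if (is.na(sp$viable)) "?" else if (sp$viable) "viable" else "dead",
                if (isTRUE(sp$pigmented)) ", pigmented"
                else if (isFALSE(sp$pigmented)) ", unpigmented" else "",
                paste(names(sp$nuclei[[1]]), g, sep = "=", collapse = "; ")))
  }
  invisible(x)
}

#' Pigmentation phenotype of a spore
#'
#' A spore is pigmented unless the cross segregates a pigmentation locus
#' (e.g. PaPKS1, whose null insertion alleles are colorless) and no nucleus
#' of the spore carries a pigment-functional allele there: the functional
#' allele is dominant, so heterokaryotic spores are pigmented.
#'
#' @param spore A spore element of an [simulate_meiosis()] ascus.
#' @param cross The [cross_spec()] the spore came from (supplies allele
#'   pigmentation flags).
#' @return Logical flag.
#' @export
spore_pigment <- function(spore, cross) {
  stopifnot(inherits(cross, "cross_spec"))
  pig <- vapply(cross$alleles, function(a) a$pigment_functional, NA)
  pig_loci <- unique(vapply(cross$alleles[!is.na(pig)], `[[`, "", "locus_id"))
  pig_loci <- intersect(pig_loci, names(spore$nuclei[[1]]))
  if (!length(pig_loci)) return(TRUE)
  all(vapply(pig_loci, function(lid) {
    any(vapply(spore$nuclei, function(nuc)
      isTRUE(pig[[nuc[[lid]]]]), TRUE))
  }, TRUE))
}
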