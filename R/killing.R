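# Killing engine: distorter/responder survival rule applied per spore.

#' Zygote context of a cross
#'
#' The allele content of the zygote determines which distorters are armed and
#' which trans-activated responders are switched on. Derived deterministically
#' from the cross specification.
#'
#' @param cross A [cross_spec()].
#' @return Object of class `"zygote_context"` with `alleles_present` and
#'   `active_distorters`.
#' @export
zygote_context <- function(cross) {
  stopifnot(inherits(cross, "cross_spec"))
  cc <- compile_cross(cross)
  structure(list(alleles_present = cc$zygote,
                 active_distorters = cc$distorters,
                 cross = cross), class = "zygote_context")
}

#' @export
print.zygote_context <- function(x, ...) {
  cat("<zygote context>\n  alleles:",
      paste(x$alleles_present, collapse = ", "),
      "\n  active distorters:",
      if (length(x$active_distorters))
        paste(x$active_distorters, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Distorters a spore is protected against
#'
#' Union over the spore's alleles (both nuclei, all loci) of their responder
#' coverage, where an allele with a non-empty trans-activator set contributes
#' only if at least one activator allele is present anywhere in the zygote.
#'
#' @param spore A spore of a [simulate_meiosis()] ascus.
#' @param ctx A [zygote_context()].
#' @return Character vector of covered distorter allele ids (restricted to
#'   declared alleles; an id outside the declaration is a configuration
#'   error, caught when the cross is built).
#' @export
effective_responders <- function(spore, ctx) {
  stopifnot(inherits(ctx, "zygote_context"))
  alleles <- ctx$cross$alleles
  carried <- unique(unlist(spore$nuclei, use.names = FALSE))
  bad <- setdiff(carried, names(alleles))
  if (length(bad))
    stop("spore carries undeclared allele id: ", paste(bad, collapse = ", "),
         call. = FALSE)
  covered <- unlist(lapply(carried, function(aid) {
    a <- alleles[[aid]]
    if (length(a$trans_activators) &&
        !any(a$trans_activators %in% ctx$alleles_present)) return(character())
    a$responder_covers
  }), use.names = FALSE)
  unique(covered)
}

#' Apply the spore-killing rule to an ascus
#'
#' A spore survives if and only if every active distorter of the zygote is in
#' its effective responder set; the rule is spore-autonomous (the toxin
#' reaches every spore of the ascus) and one resistant nucleus rescues the
#' whole spore. With a distorter `killing_efficiency` below 1 an unprotected
#' spore escapes that distorter independently with the complementary
#' probability (default efficiency 1: all-or-none death).
#'
#' Pigmentation is set at the same time via [spore_pigment()].
#'
#' @param ascus An [simulate_meiosis()] ascus.
#' @param ctx A [zygote_context()].
#' @return The ascus with `viable` and `pigmented` set on every spore.
#' @export
apply_spore_killing <- function(ascus, ctx) {
  stopifnot(inherits(ascus, "ascus"), inherits(ctx, "zygote_context"))
  alleles <- ctx$cross$alleles
  eff <- vapply(ctx$active_distorters, function(d)
    alleles[[d]]$killing_efficiency, 0)
  ascus$spores <- lapply(ascus$spores, function(sp) {
    covered <- effective_responders(sp, ctx)
    uncovered <- setdiff(ctx$active_distorters, covered)
    p_survive <- prod(1 - eff[uncovered])
    sp$viable <- if (p_survive %in% c(0, 1)) p_survive == 1
                 else stats::runif(1) < p_survive
    sp$pigmented <- spore_pigment(sp, ctx$cross)
    sp
  })
  ascus
}

# ---- vectorised internals shared by simulate_cross ----
# carriesP1/carriesP2: n_spore_groups x n_loci logical matrices saying whether
# the spore carries parent 1's / parent 2's allele at each locus.

# logical matrix (nrow(carries)) x n_distorters: spore covered per distorter
coverage_matrix <- function(cc, carriesP1, carriesP2) {
  nd <- length(cc$distorters)
  out <- matrix(FALSE, nrow(carriesP1), nd)
  if (!nd) return(out)
  for (d in seq_len(nd)) {
    acc <- rep(FALSE, nrow(carriesP1))
    for (j in seq_along(cc$locus_ids)) {
      if (cc$cov1[j, d]) acc <- acc | carriesP1[, j]
      if (cc$cov2[j, d]) acc <- acc | carriesP2[, j]
    }
    out[, d] <- acc
  }
  out
}

# survival probability per spore given coverage (deterministic when all
# efficiencies are 1)
survival_prob <- function(cc, covered) {
  p <- rep(1, nrow(covered))
  for (d in seq_along(cc$distorters))
    p <- p * ifelse(covered[, d], 1, 1 - cc$efficiency[d])
  p
}

# pigment per spore: TRUE unless a pigment locus exists with no functional
# allele carried
pigment_vec <- function(cc, carriesP1, carriesP2) {
  pig <- rep(TRUE, nrow(carriesP1))
  for (j in cc$pig_loci) {
    ok <- (carriesP1[, j] & cc$pig1[j]) | (carriesP2[, j] & cc$pig2[j])
    pig <- pig & ok
  }
  pig
}
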