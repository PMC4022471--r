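#' Define an allele of the spore-killer rule system
#'
#' An allele is the unit on which the killing engine operates. It may carry a
#' distorter ("toxin") activity, a responder ("antitoxin") activity expressed
#' as the set of distorter allele ids it protects a spore against, and an
#' optional trans-activation dependency: if `trans_activators` is non-empty,
#' the responder coverage is effective only when at least one of the listed
#' activator alleles is present anywhere in the zygote (the behaviour of
#' mCherry-Spok2, Spok2-AA and Spok-N with respect to wild-type Spok2).
#'
#' @param id Short unique allele identifier.
#' @param locus_id Identifier of the locus this allele occupies. Absence of a
#'   gene at a locus is itself an allele (e.g. `"Spok2_0"` for the empty
#'   Spok2 locus of strain T).
#' @param distorter_active Logical; does the allele kill spores that do not
#'   resist it?
#' @param responder_covers Character vector of distorter allele ids this
#'   allele protects a spore against (usually including itself).
#' @param trans_activators Character vector of allele ids; if non-empty,
#'   `responder_covers` only takes effect when an activator is present in the
#'   zygote.
#' @param pigment_functional Logical or `NA`. `TRUE`/`FALSE` marks alleles of
#'   a pigmentation locus (e.g. PaPKS1) as functional or null; `NA` (default)
#'   means the allele is irrelevant to pigmentation.
#' @param killing_efficiency Probability that an unprotected spore is actually
#'   killed by this distorter (default 1: killing is all-or-none, as observed).
#' @param selectable_markers Character vector of inert bookkeeping tags
#'   (e.g. `"hygR"`).
#' @return An object of class `"spok_allele"`.
#' @examples
#' allele("Spok1", "spok1", distorter_active = TRUE,
#'        responder_covers = c("Spok1", "Spok2"))
#' @export
allele <- function(id, locus_id, distorter_active = FALSE,
                   responder_covers = character(),
                   trans_activators = character(),
                   pigment_functional = NA,
                   killing_efficiency = 1,
                   selectable_markers = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(locus_id), length(locus_id) == 1L)
  if (!is.numeric(killing_efficiency) || length(killing_efficiency) != 1L ||
      killing_efficiency < 0 || killing_efficiency > 1)
    stop("'killing_efficiency' must be a probability in [0, 1]", call. = FALSE)
  structure(list(
    id = id,
    locus_id = locus_id,
    distorter_active = isTRUE(distorter_active),
    responder_covers = unique(as.character(responder_covers)),
    trans_activators = unique(as.character(trans_activators)),
    pigment_functional = as.logical(pigment_functional),
    killing_efficiency = as.numeric(killing_efficiency),
    selectable_markers = as.character(selectable_markers)
  ), class = "spok_allele")
}

#' @export
print.spok_allele <- function(x, ...) {
  act <- c(if (x$distorter_active) "distorter",
           if (length(x$responder_covers)) "responder")
  if (!length(act)) act <- "inert"
  cat(sprintf("<allele %s @%s: %s>\n", x$id, x$locus_id,
              paste(act, collapse = "+")))
  if (length(x$responder_covers))
    cat("  covers:", paste(x$responder_covers, collapse = ", "), "\n")
  if (length(x$trans_activators))
    cat("  trans-activated by:", paste(x$trans_activators, collapse = ", "), "\n")
  invisible(x)
}

#' Define a locus
#'
#' A locus has a chromosome, a second-division segregation (SDS) probability
#' `sds_prob` used by the phenomenological meiosis mode, and optionally a
#' centromere distance in Morgans used by the mechanistic crossover mode.
#' SDS frequency is the probability that a heterozygous locus segregates at
#' meiosis II (a crossover between the locus and its centromere); it
#' increases with centromere distance up to the asymptote 2/3.
#'
#' @param id Locus identifier.
#' @param chromosome Chromosome name; loci on different chromosomes assort
#'   independently.
#' @param sds_prob SDS probability in [0, 1].
#' @param position_morgans Optional non-negative centromere distance in
#'   Morgans (mechanistic mode only).
#' @return An object of class `"spok_locus"`.
#' @export
locus <- function(id, chromosome, sds_prob, position_morgans = NA_real_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(sds_prob) || length(sds_prob) != 1L || is.na(sds_prob) ||
      sds_prob < 0 || sds_prob > 1)
    stop("'sds_prob' must be a probability in [0, 1]", call. = FALSE)
  if (!is.na(position_morgans) && position_morgans < 0)
    stop("'position_morgans' must be non-negative", call. = FALSE)
  structure(list(id = id, chromosome = as.character(chromosome),
                 sds_prob = as.numeric(sds_prob),
                 position_morgans = as.numeric(position_morgans)),
            class = "spok_locus")
}

#' @export
print.spok_locus <- function(x, ...) {
  cat(sprintf("<locus %s chr%s s=%.3g%s>\n", x$id, x$chromosome, x$sds_prob,
              if (!is.na(x$position_morgans))
                sprintf(" @%.3gM", x$position_morgans) else ""))
  invisible(x)
}

#' Define a parental haplotype
#'
#' @param strain_id Strain name.
#' @param alleles Named character vector mapping locus id to allele id. Every
#'   locus of the cross must have exactly one allele per haplotype.
#' @return An object of class `"spok_haplotype"`.
#' @export
haplotype <- function(strain_id, alleles) {
  stopifnot(is.character(strain_id), length(strain_id) == 1L)
  alleles <- unlist(alleles)
  if (is.null(names(alleles)) || any(!nzchar(names(alleles))))
    stop("'alleles' must be a named (locus id -> allele id) vector", call. = FALSE)
  if (anyDuplicated(names(alleles)))
    stop("haplotype assigns more than one allele to a locus", call. = FALSE)
  structure(list(strain_id = strain_id, alleles = alleles),
            class = "spok_haplotype")
}

#' @export
print.spok_haplotype <- function(x, ...) {
  cat(sprintf("<haplotype %s: %s>\n", x$strain_id,
              paste(names(x$alleles), x$alleles, sep = "=", collapse = "; ")))
  invisible(x)
}
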