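# Cross simulator: many meioses through the killing engine, vectorised.

#' Simulate a cross
#'
#' Runs `n_asci` independent meioses through the meiosis engine and the
#' spore-killing rule, classifies every ascus by surviving-spore count and
#' pigmentation, and (optionally) tabulates every surviving spore.
#' Deterministic given `seed`.
#'
#' @param cross A [cross_spec()].
#' @param n_asci Number of asci (default from the cross spec).
#' @param seed Integer seed (default from the cross spec; recorded in the
#'   output).
#' @param survivors If `TRUE`, build the per-spore survivor table.
#' @return Object of class `"cross_sim"`: list with
#'   \describe{
#'     \item{counts}{an `ascus_counts` data frame: `class` (viable-spore
#'       count class), `n_pigmented`/`n_unpigmented` among viable spores,
#'       `count`; counts sum to `n_asci`.}
#'     \item{survivors}{data frame with one row per surviving spore: ascus
#'       index, spore index, one genotype column per locus (`"a"` if
#'       homokaryotic, `"a/b"` if heterokaryotic), `heterokaryotic` flag
#'       (any locus), `pigmented`, `ascus_class`.}
#'     \item{n_asci, seed, cross_id}{bookkeeping.}
#'   }
#' @examples
#' lib <- spok_strain_library()
#' sim <- simulate_cross(registry_cross("SxT"), n_asci = 2000, seed = 1)
#' print(sim)
#' @export
simulate_cross <- function(cross, n_asci = NULL, seed = NULL, survivors = TRUE) {
  stopifnot(inherits(cross, "cross_spec"))
  n_asci <- as.integer(n_asci %||% cross$n_asci)
  if (is.na(n_asci) || n_asci <= 0) stop("'n_asci' must be positive", call. = FALSE)
  seed <- seed %||% cross$seed
  # seed = NA means "continue the current RNG stream" (used by generators
  # that seed once and draw many simulations)
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)

  cc <- compile_cross(cross)
  codes <- sample_origin_codes(cc, n_asci)
  nl <- length(cc$locus_ids)

  origin <- function(chromatid)
    matrix(.ORIGIN_V[cbind(as.vector(codes), chromatid)], n_asci, nl)

  if (cc$packaging == "binucleate_tetrad") {
    # spore groups: pole 1 (spores 1,2) and pole 2 (spores 3,4); the two
    # spores of a pole hold copies of the same two meiotic products
    groups <- list(list(o1 = origin(1L), o2 = origin(2L), spores = 1:2),
                   list(o1 = origin(3L), o2 = origin(4L), spores = 3:4))
    n_spores <- 4L
  } else {
    groups <- lapply(1:4, function(k)
      list(o1 = origin(k), o2 = origin(k), spores = c(2L * k - 1L, 2L * k)))
    n_spores <- 8L
  }

  viable <- matrix(FALSE, n_asci, n_spores)
  pig <- matrix(TRUE, n_asci, n_spores)
  deterministic <- !length(cc$efficiency) || all(cc$efficiency == 1)
  group_info <- lapply(groups, function(g) {
    carries1 <- g$o1 == 1L | g$o2 == 1L
    carries2 <- g$o1 == 2L | g$o2 == 2L
    covered <- coverage_matrix(cc, carries1, carries2)
    p_survive <- survival_prob(cc, covered)
    pg <- pigment_vec(cc, carries1, carries2)
    for (s in g$spores) {
      viable[, s] <<- if (deterministic) p_survive == 1
                      else stats::runif(n_asci) < p_survive
      pig[, s] <<- pg
    }
    list(carries1 = carries1, carries2 = carries2, het = g$o1 != g$o2)
  })

  n_viable <- rowSums(viable)
  n_pig_viable <- rowSums(viable & pig)

  cls <- ascus_class_label(n_viable)
  tab <- as.data.frame(table(class = cls, n_pigmented = n_pig_viable),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  tab$n_pigmented <- as.integer(tab$n_pigmented)
  counts <- data.frame(class = tab$class,
                       n_pigmented = tab$n_pigmented,
                       n_unpigmented = class_viable_count(tab$class) - tab$n_pigmented,
                       count = tab$Freq, stringsAsFactors = FALSE)
  counts <- counts[order(-class_viable_count(counts$class), counts$n_pigmented), ]
  rownames(counts) <- NULL
  class(counts) <- c("ascus_counts", "data.frame")
  attr(counts, "n_asci") <- n_asci
  attr(counts, "cross_id") <- cross$id
  attr(counts, "seed") <- seed

  surv <- NULL
  if (survivors) {
    rows <- list()
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]; info <- group_info[[gi]]
      geno <- matrix("", n_asci, nl)
      for (j in seq_len(nl))
        geno[, j] <- if (!cc$het[j]) cc$a1[j] else
          ifelse(info$carries1[, j] & info$carries2[, j],
                 paste0(cc$a1[j], "/", cc$a2[j]),
                 ifelse(info$carries1[, j], cc$a1[j], cc$a2[j]))
      hetero <- rowSums(info$het) > 0
      for (s in g$spores) {
        keep <- which(viable[, s])
        if (!length(keep)) next
        df <- data.frame(ascus = keep, spore = s,
                         geno[keep, , drop = FALSE],
                         heterokaryotic = hetero[keep],
                         pigmented = pig[keep, s],
                         ascus_class = cls[keep],
                         stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- df
      }
    }
    surv <- if (length(rows)) do.call(rbind, rows) else
      data.frame(ascus = integer(), spore = integer(),
                 matrix(character(), 0, nl, dimnames = list(NULL, cc$locus_ids)),
                 heterokaryotic = logical(), pigmented = logical(),
                 ascus_class = character())
    names(surv)[3:(2 + nl)] <- cc$locus_ids
    surv <- surv[order(surv$ascus, surv$spore), ]
    rownames(surv) <- NULL
  }

  structure(list(counts = counts, survivors = surv, n_asci = n_asci,
                 seed = seed, cross_id = cross$id, cross = cross),
            class = "cross_sim")
}

ascus_class_label <- function(n_viable)
  ifelse(n_viable == 0, "empty", paste0(n_viable, "-spored"))

class_viable_count <- function(class)
  ifelse(class == "empty", 0L,
         as.integer(sub("-spored", "", class)))

#' Classify a single ascus
#'
#' Maps an ascus with viability assigned to its class (number of viable
#' spores) and pigmentation pattern among the viable spores.
#'
#' @param ascus An ascus processed by [apply_spore_killing()].
#' @return List with `class` (e.g. `"2-spored"`, `"empty"`), `n_viable`,
#'   `n_pigmented` and `n_unpigmented` among viable spores, and a compact
#'   `label`.
#' @export
classify_ascus <- function(ascus) {
  stopifnot(inherits(ascus, "ascus"))
  v <- vapply(ascus$spores, `[[`, TRUE, "viable")
  if (anyNA(v)) stop("viability not assigned; run apply_spore_killing() first",
                     call. = FALSE)
  p <- vapply(ascus$spores, `[[`, TRUE, "pigmented")
  nv <- sum(v); np <- sum(v & p)
  cls <- ascus_class_label(nv)
  list(class = cls, n_viable = nv, n_pigmented = np, n_unpigmented = nv - np,
       label = if (nv == 0) "empty" else
         sprintf("%s (%d pigmented, %d unpigmented)", cls, np, nv - np))
}

#' Percentage of asci in a class
#'
#' Percentages use all asci (including empty ones) as denominator; raw counts
#' stay available in the table so any other convention can be recomputed.
#'
#' @param x A `cross_sim`, `ascus_counts` or `ascus_distribution` object.
#' @param class Class label, e.g. `"2-spored"`.
#' @param n_pigmented Optional restriction on the number of pigmented viable
#'   spores (e.g. 0 for "all survivors unpigmented").
#' @return Percentage in [0, 100].
#' @export
percent_class <- function(x, class, n_pigmented = NULL) {
  if (inherits(x, "cross_sim")) x <- x$counts
  if (inherits(x, "ascus_distribution")) {
    keep <- x$class %in% class
    if (!is.null(n_pigmented)) keep <- keep & x$n_pigmented %in% n_pigmented
    return(100 * sum(x$prob[keep]))
  }
  stopifnot(inherits(x, "ascus_counts"))
  keep <- x$class %in% class
  if (!is.null(n_pigmented)) keep <- keep & x$n_pigmented %in% n_pigmented
  100 * sum(x$count[keep]) / attr(x, "n_asci")
}

#' @export
print.ascus_counts <- function(x, ...) {
  cat(sprintf("Ascus classes for cross %s (n = %d asci%s)\n",
              attr(x, "cross_id") %||% "?", attr(x, "n_asci"),
              if (!is.null(attr(x, "seed")))
                paste0(", seed ", attr(x, "seed")) else ""))
  df <- as.data.frame(x)
  df$percent <- sprintf("%.2f%%", 100 * df$count / attr(x, "n_asci"))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.cross_sim <- function(x, ...) {
  print(x$counts)
  if (!is.null(x$survivors))
    cat(sprintf("%d surviving spores tabulated (%d heterokaryotic)\n",
                nrow(x$survivors), sum(x$survivors$heterokaryotic)))
  invisible(x)
}

#' @export
summary.cross_sim <- function(object, ...) {
  print(object$counts)
  if (!is.null(object$survivors) && nrow(object$survivors)) {
    surv <- object$survivors
    loci <- setdiff(names(surv), c("ascus", "spore", "heterokaryotic",
                                   "pigmented", "ascus_class"))
    cat("\nAllele frequencies among surviving spores:\n")
    for (l in loci) {
      tb <- sort(table(surv[[l]]), decreasing = TRUE)
      cat(sprintf("  %s: %s\n", l,
                  paste(sprintf("%s %.1f%%", names(tb), 100 * tb / sum(tb)),
                        collapse = ", ")))
    }
  }
  invisible(object)
}
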