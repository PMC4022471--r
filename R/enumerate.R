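# Exact ascus-class distribution by exhaustive enumeration over per-locus
# origin vectors. Serves as the analytic oracle for the Monte-Carlo
# simulator: both use the same Markov chain over origin codes, so simulated
# class frequencies must converge to these probabilities.

# transition matrix across one mechanistic interval of delta Morgans:
# Poisson(2*delta) crossover actions, summed until the tail is negligible
mech_transition <- function(delta) {
  if (delta == 0) return(diag(6))
  T <- diag(6) * stats::dpois(0, 2 * delta)
  Mk <- diag(6)
  k <- 0
  repeat {
    k <- k + 1
    Mk <- Mk %*% .CROSSOVER_STEP
    pk <- stats::dpois(k, 2 * delta)
    T <- T + pk * Mk
    if (stats::ppois(k, 2 * delta, lower.tail = FALSE) < 1e-14) break
  }
  T
}

# per-chromosome pieces of the joint law of origin codes at heterozygous
# loci: start distribution at the first het locus and composed transition
# matrices between consecutive het loci (marginalising homozygous loci)
chain_pieces <- function(cc, chain) {
  idx <- chain$idx
  first_dist <- NULL; trans <- list(); het_ids <- character()
  M_acc <- NULL; d <- NULL
  for (k in seq_along(idx)) {
    j <- idx[k]
    T <- if (k == 1) NULL
         else if (cc$mode == "phenomenological")
           origin_transition(cc$sds[j], chain$r_prev[k])
         else mech_transition(cc$pos[j] - cc$pos[idx[k - 1]])
    if (is.null(M_acc)) {
      d <- if (k == 1) {
        if (cc$mode == "phenomenological") origin_init_probs(cc$sds[j])
        else as.vector(mech_transition(cc$pos[j])[1L, ])
      } else as.vector(d %*% T)
      if (cc$het[j]) {
        first_dist <- d
        het_ids <- cc$locus_ids[j]
        M_acc <- diag(6)
      }
    } else {
      M_acc <- M_acc %*% T
      if (cc$het[j]) {
        trans[[length(trans) + 1L]] <- M_acc
        het_ids <- c(het_ids, cc$locus_ids[j])
        M_acc <- diag(6)
      }
    }
  }
  list(first_dist = first_dist, trans = trans, het_ids = het_ids)
}

#' Exact ascus-class distribution of a cross
#'
#' Exhaustively sums over the per-locus FDS/SDS origin assignments (six
#' origin vectors per heterozygous locus, weighted by the same chain law the
#' simulator samples from), applies the killing rule and pigmentation
#' deterministically (or integrating the per-spore survival probability when
#' a killing efficiency is below 1), and returns the exact probability of
#' every (class, pigmentation pattern) cell, plus the expected survivor
#' genotype composition. Feasible for up to three heterozygous loci.
#'
#' @param cross A [cross_spec()].
#' @return Object of class `"ascus_distribution"`: data frame with `class`,
#'   `n_pigmented`, `n_unpigmented`, `prob` (summing to 1), with attribute
#'   `"survivors"` holding the expected survivor genotype classes (per-locus
#'   genotype, heterokaryotic flag, pigment, expected count per ascus, share
#'   among survivors).
#' @examples
#' al <- list(allele("K", "sk", distorter_active = TRUE, responder_covers = "K"),
#'            allele("k0", "sk"))
#' cx <- cross_spec(haplotype("killer", c(sk = "K")),
#'                  haplotype("sens", c(sk = "k0")),
#'                  loci = list(locus("sk", "1", sds_prob = 0.1)), alleles = al)
#' enumerate_cross(cx)  # P(2-spored) = 0.9, P(4-spored) = 0.1
#' @export
enumerate_cross <- function(cross) {
  stopifnot(inherits(cross, "cross_spec"))
  cc <- compile_cross(cross)
  het_idx <- which(cc$het)
  if (length(het_idx) > 3L)
    stop("enumerate_cross supports at most 3 heterozygous loci (got ",
         length(het_idx), ")", call. = FALSE)
  nl <- length(cc$locus_ids)

  pieces <- lapply(cc$chains, function(ch) chain_pieces(cc, ch))
  pieces <- Filter(function(p) !is.null(p$first_dist), pieces)

  grid <- if (length(het_idx))
    as.matrix(expand.grid(rep(list(1:6), length(het_idx))))
  else matrix(integer(), 1, 0)

  config_prob <- function(het_codes) {
    names(het_codes) <- cc$locus_ids[het_idx]
    p <- 1
    for (pc in pieces) {
      codes <- het_codes[pc$het_ids]
      p <- p * pc$first_dist[codes[1]]
      if (length(codes) > 1)
        for (i in 2:length(codes))
          p <- p * pc$trans[[i - 1]][codes[i - 1], codes[i]]
    }
    p
  }

  n_groups <- if (cc$packaging == "binucleate_tetrad") 2L else 4L
  group_chromatids <- if (n_groups == 2L) list(c(1L, 2L), c(3L, 4L)) else
    list(c(1L, 1L), c(2L, 2L), c(3L, 3L), c(4L, 4L))

  cells <- new.env(parent = emptyenv())
  surv <- new.env(parent = emptyenv())
  add <- function(env, key, val) {
    cur <- if (!is.null(env[[key]])) env[[key]] else 0
    env[[key]] <- cur + val
  }

  for (g in seq_len(nrow(grid))) {
    code_row <- rep(1L, nl)
    code_row[het_idx] <- as.integer(grid[g, ])
    pr <- config_prob(grid[g, ])
    if (pr == 0) next

    gr <- lapply(group_chromatids, function(chv) {
      o1 <- .ORIGIN_V[cbind(code_row, chv[1])]
      o2 <- .ORIGIN_V[cbind(code_row, chv[2])]
      carries1 <- matrix(o1 == 1L | o2 == 1L, 1)
      carries2 <- matrix(o1 == 2L | o2 == 2L, 1)
      covered <- coverage_matrix(cc, carries1, carries2)
      list(p_survive = survival_prob(cc, covered),
           pig = pigment_vec(cc, carries1, carries2),
           geno = ifelse(!cc$het, cc$a1,
                         ifelse(carries1[1, ] & carries2[1, ],
                                paste0(cc$a1, "/", cc$a2),
                                ifelse(carries1[1, ], cc$a1, cc$a2))),
           het = any(o1 != o2))
    })

    # viable-count pattern per group: each group holds 2 spores surviving
    # independently with p_survive (deterministic when efficiencies are 1)
    kgrid <- as.matrix(expand.grid(rep(list(0:2), n_groups)))
    kprob <- apply(kgrid, 1, function(ks)
      prod(vapply(seq_len(n_groups), function(i)
        stats::dbinom(ks[i], 2, gr[[i]]$p_survive), 0)))
    for (row in which(kprob > 0)) {
      ks <- kgrid[row, ]
      nv <- sum(ks)
      npig <- sum(ks * vapply(gr, `[[`, TRUE, "pig"))
      key <- paste(ascus_class_label(nv), npig, nv - npig, sep = "\r")
      add(cells, key, pr * kprob[row])
    }
    for (i in seq_len(n_groups)) {
      ev <- pr * 2 * gr[[i]]$p_survive
      if (ev == 0) next
      key <- paste(paste(gr[[i]]$geno, collapse = "\r"),
                   gr[[i]]$het, gr[[i]]$pig, sep = "\r")
      add(surv, key, ev)
    }
  }

  keys <- ls(cells)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(class = parts[, 1],
                    n_pigmented = as.integer(parts[, 2]),
                    n_unpigmented = as.integer(parts[, 3]),
                    prob = vapply(keys, function(k) cells[[k]], 0),
                    stringsAsFactors = FALSE)
  out <- out[order(-class_viable_count(out$class), out$n_pigmented), ]
  rownames(out) <- NULL
  class(out) <- c("ascus_distribution", "data.frame")
  attr(out, "cross_id") <- cross$id

  skeys <- ls(surv)
  if (length(skeys)) {
    sparts <- do.call(rbind, strsplit(skeys, "\r", fixed = TRUE))
    sdf <- data.frame(sparts[, seq_len(nl), drop = FALSE],
                      stringsAsFactors = FALSE)
    names(sdf) <- cc$locus_ids
    sdf$heterokaryotic <- as.logical(sparts[, nl + 1])
    sdf$pigmented <- as.logical(sparts[, nl + 2])
    sdf$expected_per_ascus <- vapply(skeys, function(k) surv[[k]], 0)
    sdf$share <- sdf$expected_per_ascus / sum(sdf$expected_per_ascus)
    sdf <- sdf[order(-sdf$share), ]
    rownames(sdf) <- NULL
  } else sdf <- NULL
  attr(out, "survivors") <- sdf
  out
}

#' @export
print.ascus_distribution <- function(x, ...) {
  cat(sprintf("Exact ascus-class distribution for cross %s\n",
              attr(x, "cross_id") %||% "?"))
  df <- as.data.frame(x)
  df$percent <- sprintf("%.3f%%", 100 * df$prob)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Expected survivor genotype classes of a cross
#'
#' @param x An [enumerate_cross()] result.
#' @return Data frame of survivor genotype classes with expected counts per
#'   ascus and shares among survivors.
#' @export
survivor_distribution <- function(x) {
  stopifnot(inherits(x, "ascus_distribution"))
  attr(x, "survivors")
}
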