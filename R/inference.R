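# Estimators and tests over ascus-count and progeny-genotype data.

#' Estimate second-division segregation frequency from ascus counts
#'
#' For a cross in which exactly one unmasked killer segregates, the killed
#' (2-spored) asci are exactly the FDS asci of the killer locus and the
#' intact (4-spored) asci the SDS ones, so the maximum-likelihood estimate of
#' the SDS frequency is the fraction of 4-spored asci. For a non-killer
#' locus scored directly (e.g. by spore pigmentation order), pass the FDS and
#' SDS ascus counts with `locus_is_killer = FALSE`. Confidence intervals are
#' Clopper-Pearson (exact), appropriate for the small counts typical of
#' tetrad data. Half the SDS frequency, in map units, is the standard
#' tetrad estimate of the locus-centromere distance.
#'
#' If `cross` and `locus_id` are supplied the estimator first checks that the
#' 2-spored fraction is informative for that locus and refuses otherwise:
#' the locus must be heterozygous for a single active distorter whose only
#' protection is itself, and every other active distorter must be silenced by
#' homozygosity or masked by (covered by) the focal killer. For example, the
#' Spok2 locus is not estimable from an SKT20 x S cross (homozygous) nor from
#' an S x T cross (masked by Spok1).
#'
#' @param n_2spored,n_4spored Ascus counts (FDS-like and SDS-like classes for
#'   a killer locus; FDS and SDS counts when `locus_is_killer = FALSE`).
#' @param locus_is_killer Flag, see above.
#' @param conf.level Confidence level (default 0.95).
#' @param cross,locus_id Optional [cross_spec()] and locus id for the
#'   informativeness check.
#' @return Object of class `"sds_estimate"` with `s_hat`, `ci_low`,
#'   `ci_high`, `n_asci`, `map_distance_cM` (= 100 s / 2).
#' @examples
#' estimate_sds(9000, 1000)  # s_hat = 0.10, ~5 cM
#' @export
estimate_sds <- function(n_2spored, n_4spored, locus_is_killer = TRUE,
                         conf.level = 0.95, cross = NULL, locus_id = NULL) {
  stopifnot(n_2spored >= 0, n_4spored >= 0)
  total <- n_2spored + n_4spored
  if (total == 0) stop("no asci counted", call. = FALSE)
  if (!is.null(cross)) {
    if (is.null(locus_id)) stop("'locus_id' required with 'cross'", call. = FALSE)
    assert_sds_estimable(cross, locus_id)
  }
  # for a killer locus the SDS asci are exactly the surviving 4-spored ones;
  # for a directly scored locus the second argument is already the SDS count
  n_sds <- n_4spored
  ci <- stats::binom.test(n_sds, total, conf.level = conf.level)$conf.int
  s_hat <- n_sds / total
  structure(list(s_hat = s_hat, ci_low = ci[1], ci_high = ci[2],
                 n_asci = total, conf.level = conf.level,
                 map_distance_cM = 100 * s_hat / 2),
            class = "sds_estimate")
}

#' @export
print.sds_estimate <- function(x, ...) {
  cat(sprintf(
    "SDS frequency: %.4f (%d%% CI %.4f-%.4f; n = %d asci)\n",
    x$s_hat, round(100 * x$conf.level), x$ci_low, x$ci_high, x$n_asci))
  cat(sprintf("Locus-centromere distance (s/2): %.2f cM\n", x$map_distance_cM))
  invisible(x)
}

#' Check that a locus's SDS frequency is identifiable from killed-ascus counts
#'
#' @param cross A [cross_spec()].
#' @param locus_id Locus to estimate.
#' @return Invisibly `TRUE`; otherwise an error explaining the problem.
#' @export
assert_sds_estimable <- function(cross, locus_id) {
  cc <- compile_cross(cross)
  j <- match(locus_id, cc$locus_ids)
  if (is.na(j)) stop("unknown locus '", locus_id, "'", call. = FALSE)
  if (!cc$het[j])
    stop("locus '", locus_id, "' is homozygous in this cross; ",
         "the 2-spored fraction carries no information about it", call. = FALSE)
  d1 <- cc$a1[j] %in% cc$distorters
  d2 <- cc$a2[j] %in% cc$distorters
  if (d1 == d2)
    stop("locus '", locus_id, "' does not segregate a single active ",
         "distorter", call. = FALSE)
  k <- if (d1) cc$a1[j] else cc$a2[j]
  kd <- match(k, cc$distorters)
  covs <- if (d1) cc$cov2 else cc$cov1 # opposite haplotype's coverage
  if (any(covs[, kd]))
    stop("killer '", k, "' at locus '", locus_id, "' is masked: the ",
         "opposite haplotype carries a responder covering it, so the ",
         "2-spored fraction is uninformative", call. = FALSE)
  k_covers <- if (d1) cc$cov1[j, ] else cc$cov2[j, ]
  for (d in setdiff(cc$distorters, k)) {
    dd <- match(d, cc$distorters)
    jd <- which(cc$a1 == d & cc$a2 == d)
    silenced <- length(jd) > 0 && all(cc$cov1[jd, dd]) # homozygous self-cover

    if (!(silenced || k_covers[dd]))
      stop("a second unmasked distorter ('", d, "') segregates; the ",
           "2-spored fraction is not attributable to locus '", locus_id, "'",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Marker transmission-bias scan
#'
#' Per-marker two-sided exact binomial test of the transmission fraction of
#' one parent's alleles among surviving progeny against the Mendelian 0.5,
#' with Benjamini-Hochberg adjustment across markers; the flagged biased
#' region is the maximal run of consecutive significant markers. This is the
#' scan that locates a spore-killer locus from the distorted transmission of
#' centromere-linked markers (e.g. 50 progeny of an S x T cross showing a
#' strong bias towards T alleles around the chromosome-5 centromere).
#'
#' @param genotypes Matrix or data frame, progeny in rows, markers in
#'   columns, entries coded by parental origin (two levels, e.g. "S"/"T").
#' @param focal Level whose transmission is counted (default the second sorted
#'   level, e.g. "T").
#' @param positions Optional numeric marker positions (defaults to column
#'   order).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param adjust Multiple-testing method (default `"BH"`).
#' @return Object of class `"transmission_scan"`: data frame with per-marker
#'   counts, transmission fraction, raw and adjusted p-values and
#'   significance, with the flagged region in attributes `"region"` (marker
#'   names) and `"region_idx"`.
#' @export
transmission_scan <- function(genotypes, focal = NULL, positions = NULL,
                              alpha = 0.05, adjust = "BH") {
  genotypes <- as.data.frame(genotypes)
  if (!nrow(genotypes) || !ncol(genotypes))
    stop("empty genotype matrix", call. = FALSE)
  levs <- sort(unique(unlist(lapply(genotypes, as.character))))
  levs <- levs[!is.na(levs)]
  if (length(levs) > 2) stop("more than two parental codes found", call. = FALSE)
  focal <- focal %||% levs[min(2L, length(levs))]
  positions <- positions %||% seq_len(ncol(genotypes))
  stopifnot(length(positions) == ncol(genotypes))

  res <- do.call(rbind, lapply(seq_len(ncol(genotypes)), function(j) {
    g <- as.character(genotypes[[j]])
    g <- g[!is.na(g)]
    k <- sum(g == focal)
    n <- length(g)
    p <- stats::binom.test(k, n, p = 0.5)$p.value
    data.frame(marker = names(genotypes)[j], position = positions[j],
               n = n, n_focal = k, fraction = k / n, p = p,
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$position), ]
  res$p_adj <- stats::p.adjust(res$p, method = adjust)
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL

  runs <- rle(res$significant)
  region_idx <- integer()
  if (any(res$significant)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    sig_runs <- which(runs$values)
    best <- sig_runs[which.max(runs$lengths[sig_runs])]
    region_idx <- seq.int(starts[best], ends[best])
  }
  structure(res, class = c("transmission_scan", "data.frame"),
            region_idx = region_idx, region = res$marker[region_idx],
            focal = focal, alpha = alpha)
}

#' @export
print.transmission_scan <- function(x, ...) {
  cat(sprintf("Transmission scan (focal allele '%s', alpha = %g adjusted)\n",
              attr(x, "focal"), attr(x, "alpha")))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  reg <- attr(x, "region")
  cat("Flagged biased region:",
      if (length(reg)) paste(reg, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Goodness of fit of observed ascus counts to an exact distribution
#'
#' Chi-square test of observed class counts against the probabilities of an
#' [enumerate_cross()] distribution (or any named probability vector), with
#' pooling of classes whose expected count is below 5; for small totals an
#' exact multinomial test (sum of the probabilities of all outcome tables no
#' more probable than the observed one) is used instead.
#'
#' @param observed An `ascus_counts` table (or named count vector by class).
#' @param expected An `ascus_distribution` (or named probability vector).
#' @param method `"auto"` (exact when n < 30 or fewer than 2 classes survive
#'   pooling), `"chisq"`, or `"exact"`.
#' @param by `"class"` (default) collapses pigmentation patterns and compares
#'   viable-spore-count classes; `"cell"` compares (class, pigmentation)
#'   cells.
#' @return List with `statistic`, `df`, `p.value`, `method`, `observed`,
#'   `expected` (counts).
#' @export
goodness_of_fit <- function(observed, expected, method = c("auto", "chisq", "exact"),
                            by = c("class", "cell")) {
  method <- match.arg(method)
  by <- match.arg(by)
  key <- function(cls, npig) if (by == "class") cls else paste(cls, npig)
  if (inherits(observed, "ascus_counts")) {
    obs <- tapply(observed$count, key(observed$class, observed$n_pigmented), sum)
  } else obs <- observed
  if (inherits(expected, "ascus_distribution")) {
    exp_p <- tapply(expected$prob, key(expected$class, expected$n_pigmented), sum)
  } else exp_p <- expected
  labels <- union(names(exp_p), names(obs))
  o <- as.numeric(obs[labels]); o[is.na(o)] <- 0
  p <- as.numeric(exp_p[labels]); p[is.na(p)] <- 0
  if (any(p == 0 & o > 0))
    stop("observed counts in classes with zero expected probability: ",
         paste(labels[p == 0 & o > 0], collapse = ", "), call. = FALSE)
  keep <- p > 0
  o <- o[keep]; p <- p[keep]; labels <- labels[keep]
  n <- sum(o)
  p <- p / sum(p)
  e <- n * p

  use_exact <- method == "exact" ||
    (method == "auto" && (n < 30 || sum(e >= 5) < 2))
  if (use_exact && length(p) <= 6 && n <= 200) {
    # exact multinomial: p-value = total probability of outcomes no more
    # likely than the observed one
    obs_lik <- stats::dmultinom(o, prob = p)
    grid <- comp_grid(n, length(p))
    liks <- apply(grid, 1, function(x) stats::dmultinom(x, prob = p))
    pval <- sum(liks[liks <= obs_lik + 1e-12])
    return(list(statistic = NA_real_, df = NA_integer_, p.value = min(pval, 1),
                method = "exact multinomial",
                observed = stats::setNames(o, labels),
                expected = stats::setNames(e, labels)))
  }
  # pool classes with expected < 5 into one
  if (any(e < 5) && sum(e < 5) > 1) {
    pool <- e < 5
    o <- c(o[!pool], sum(o[pool]))
    e <- c(e[!pool], sum(e[pool]))
    labels <- c(labels[!pool], "pooled")
  }
  stat <- sum((o - e)^2 / e)
  df <- length(o) - 1L
  if (df < 1) stop("fewer than two classes after pooling; use method='exact'",
                   call. = FALSE)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       method = "chi-square", observed = stats::setNames(o, labels),
       expected = stats::setNames(e, labels))
}

# all compositions of n into k non-negative parts (small n, k only)
comp_grid <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- list()
  for (i in 0:n) {
    sub <- comp_grid(n - i, k - 1)
    out[[length(out) + 1L]] <- cbind(i, sub)
  }
  do.call(rbind, out)
}
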