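# Recurrent-backcross introgression with selection for a driver locus:
# the scheme used to isolate a spore killer in a near-isogenic background
# (repeated crosses of a driver carrier to a recurrent parent, keeping each
# generation a first-division-segregation ascus survivor that carries the
# driver, so the donor genome shrinks to a segment around the driver).

# ---- interval set helpers (2-column matrices, sorted, non-overlapping) ----
ivl <- function(start = numeric(), end = numeric())
  cbind(start = start, end = end)

ivl_len <- function(x) if (!nrow(x)) 0 else sum(x[, 2] - x[, 1])

ivl_contains <- function(x, pos)
  nrow(x) > 0 && any(x[, 1] <= pos & pos < x[, 2])

ivl_intersect <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(ivl())
  out <- list()
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1]); hi <- pmin(a[i, 2], b[, 2])
    keep <- lo < hi
    if (any(keep)) out[[length(out) + 1L]] <- cbind(lo[keep], hi[keep])
  }
  if (!length(out)) return(ivl())
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

# one full meiosis of a hybrid (mosaic/recurrent) chromosome of length L:
# Poisson(2L) crossovers, each between one chromatid of each pole, no
# interference. Returns per-chromatid ancestry-intervals tracing to the
# hybrid homolog (chromatids 1,2 = pole 1, centromere from the hybrid;
# 3,4 = pole 2, recurrent centromere).
meiosis_chromatids <- function(L) {
  n_co <- stats::rpois(1, 2 * L)
  state <- c(TRUE, TRUE, FALSE, FALSE) # traces to hybrid homolog
  brk <- lapply(1:4, function(i) list(x = 0, s = state[i]))
  if (n_co > 0) {
    xs <- sort(stats::runif(n_co, 0, L))
    a <- sample(1:2, n_co, replace = TRUE)
    b <- sample(3:4, n_co, replace = TRUE)
    for (k in seq_len(n_co)) {
      i <- a[k]; j <- b[k]
      if (state[i] != state[j]) {
        tmp <- state[i]; state[i] <- state[j]; state[j] <- tmp
        brk[[i]]$x <- c(brk[[i]]$x, xs[k]); brk[[i]]$s <- c(brk[[i]]$s, state[i])
        brk[[j]]$x <- c(brk[[j]]$x, xs[k]); brk[[j]]$s <- c(brk[[j]]$s, state[j])
      }
    }
  }
  lapply(brk, function(bl) {
    x <- c(bl$x, L)
    keep <- which(bl$s)
    ivl(x[keep], x[keep + 1L])
  })
}

# donor intervals of each chromatid = chromatid segments tracing to the
# hybrid homolog, intersected with that homolog's donor mosaic
chromatid_donor <- function(parent_donor, L) {
  lapply(meiosis_chromatids(L), ivl_intersect, b = parent_donor)
}

#' Simulate a recurrent-backcross introgression programme
#'
#' Starting from an F1 (one full donor haplotype), each generation crosses
#' the current carrier to the recurrent parent and retains one surviving
#' ascospore that (i) carries the driver allele and (ii) comes from a
#' first-division-segregation ascus at the driver (heterokaryotic SDS
#' survivors are excluded, matching selection for killed asci). Crossovers
#' follow the mechanistic Poisson/no-interference model. The donor genome
#' fraction of the generation-g individual and the length of the residual
#' donor segment containing the driver are tracked per replicate.
#'
#' @param driver A [locus()] with `chromosome` and `position_morgans` set
#'   (centromere at 0).
#' @param genome_map Data frame with columns `chromosome` and
#'   `length_morgans`; the driver's chromosome must be listed. All listed
#'   chromosomes are simulated; unlisted genome is summarised only by the
#'   closed-form expectation `(1/2)^(g+1)`.
#' @param n_generations Number of backcross generations (>= 1).
#' @param n_replicates Independent programme replicates.
#' @param seed Optional integer seed.
#' @param max_tries Meiosis redraws allowed per selection step.
#' @return Object of class `"introgression_sim"`: data frame with columns
#'   `replicate`, `generation` (0 = F1), `donor_fraction` (of the diploid
#'   individual, simulated chromosomes), `donor_fraction_unlinked` (non-driver
#'   chromosomes, `NA` if none), `driver_segment_length` (Morgans) and
#'   `expected_unlinked` (= 0.5^(generation+1)).
#' @examples
#' map <- data.frame(chromosome = c("5", "1"), length_morgans = c(1, 1))
#' sim <- simulate_backcross_program(locus("drv", "5", 0.1, 0.05), map,
#'                                   n_generations = 3, n_replicates = 5,
#'                                   seed = 1)
#' @export
simulate_backcross_program <- function(driver, genome_map, n_generations,
                                       n_replicates = 100, seed = NULL,
                                       max_tries = 10000) {
  stopifnot(inherits(driver, "spok_locus"), n_generations >= 1)
  genome_map <- as.data.frame(genome_map)
  if (!all(c("chromosome", "length_morgans") %in% names(genome_map)))
    stop("'genome_map' needs columns chromosome, length_morgans", call. = FALSE)
  genome_map$chromosome <- as.character(genome_map$chromosome)
  di <- match(driver$chromosome, genome_map$chromosome)
  if (is.na(di)) stop("driver chromosome absent from genome map", call. = FALSE)
  if (is.na(driver$position_morgans) ||
      driver$position_morgans > genome_map$length_morgans[di])
    stop("driver position must lie on its chromosome", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  Ls <- genome_map$length_morgans
  total_L <- sum(Ls)
  pos <- driver$position_morgans
  out <- vector("list", n_replicates)

  for (rep_i in seq_len(n_replicates)) {
    donor <- lapply(Ls, function(L) ivl(0, L)) # F1: full donor haplotype
    rows <- data.frame(replicate = rep_i, generation = 0:n_generations,
                       donor_fraction = NA_real_,
                       donor_fraction_unlinked = NA_real_,
                       driver_segment_length = NA_real_)
    record <- function(g) {
      dl <- vapply(donor, ivl_len, 0)
      rows$donor_fraction[rows$generation == g] <<- sum(dl) / (2 * total_L)
      if (length(Ls) > 1)
        rows$donor_fraction_unlinked[rows$generation == g] <<-
          sum(dl[-di]) / (2 * sum(Ls[-di]))
      seg <- donor[[di]]
      hit <- which(seg[, 1] <= pos & pos < seg[, 2])
      rows$driver_segment_length[rows$generation == g] <<-
        if (length(hit)) seg[hit, 2] - seg[hit, 1] else 0
    }
    record(0)
    for (g in seq_len(n_generations)) {
      # driver chromosome: redraw meioses until the driver segregates at the
      # first division, then keep one chromatid from the driver-carrying pole
      picked <- NULL
      for (try in seq_len(max_tries)) {
        chroms <- chromatid_donor(donor[[di]], Ls[di])
        carries <- vapply(chroms, ivl_contains, TRUE, pos = pos)
        fds <- carries[1] == carries[2] && carries[3] == carries[4]
        if (fds && any(carries)) {
          pole <- if (carries[1]) 1:2 else 3:4
          picked <- chroms[[sample(pole, 1)]]
          break
        }
      }
      if (is.null(picked))
        stop("selection failed: no driver-carrying FDS gamete in ",
             max_tries, " meioses", call. = FALSE)
      donor[[di]] <- picked
      for (ci in setdiff(seq_along(Ls), di)) {
        chroms <- chromatid_donor(donor[[ci]], Ls[ci])
        donor[[ci]] <- chroms[[sample(4, 1)]]
      }
      record(g)
    }
    out[[rep_i]] <- rows
  }
  res <- do.call(rbind, out)
  res$expected_unlinked <- 0.5^(res$generation + 1)
  structure(res, class = c("introgression_sim", "data.frame"),
            driver = driver, genome_map = genome_map, seed = seed)
}

#' @export
print.introgression_sim <- function(x, ...) {
  cat(sprintf("Backcross introgression: %d replicates, %d generations\n",
              max(x$replicate), max(x$generation)))
  print(summary(x))
  invisible(x)
}

#' @export
summary.introgression_sim <- function(object, ...) {
  agg <- do.call(data.frame, stats::aggregate(
    cbind(donor_fraction, driver_segment_length) ~ generation,
    data = as.data.frame(object), FUN = function(v)
      c(mean = mean(v), sd = stats::sd(v))))
  names(agg) <- c("generation", "donor_fraction_mean", "donor_fraction_sd",
                  "driver_segment_mean", "driver_segment_sd")
  agg$expected_unlinked <- 0.5^(agg$generation + 1)
  agg
}
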