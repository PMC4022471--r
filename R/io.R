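# Configuration files (YAML, schema-validated, unknown keys rejected) and
# tabular writers. Tables are TSV with a single header row; percentages are
# always derived client-side from the raw counts.

config_error <- function(...) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

check_keys <- function(x, allowed, required = character(), where = "config") {
  if (!is.list(x)) config_error(where, ": expected a mapping")
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    config_error(where, ": unknown key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(x))
  if (length(missing))
    config_error(where, ": missing required key(s): ",
                 paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Write a cross specification to a YAML config file
#'
#' The same schema [read_cross_config()] consumes, so the reference crosses
#' can be exported and user strains defined by analogy.
#'
#' @param cross A [cross_spec()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cross_config <- function(cross, path) {
  stopifnot(inherits(cross, "cross_spec"))
  hap <- function(h) list(strain_id = h$strain_id, alleles = as.list(h$alleles))
  al <- function(a) {
    out <- list(id = a$id, locus_id = a$locus_id,
                distorter_active = a$distorter_active,
                responder_covers = as.list(a$responder_covers),
                trans_activators = as.list(a$trans_activators))
    if (!is.na(a$pigment_functional)) out$pigment_functional <- a$pigment_functional
    if (a$killing_efficiency != 1) out$killing_efficiency <- a$killing_efficiency
    if (length(a$selectable_markers))
      out$selectable_markers <- as.list(a$selectable_markers)
    out
  }
  lo <- function(l) {
    out <- list(id = l$id, chromosome = l$chromosome, sds_prob = l$sds_prob)
    if (!is.na(l$position_morgans)) out$position_morgans <- l$position_morgans
    out
  }
  cfg <- list(cross = list(
    id = cross$id,
    parent1 = hap(cross$parent1), parent2 = hap(cross$parent2),
    loci = lapply(unname(cross$loci), lo),
    alleles = lapply(unname(cross$alleles), al)
  ))
  if (!is.null(cross$linkage))
    cfg$cross$linkage <- lapply(seq_len(nrow(cross$linkage)), function(i)
      list(locus1 = cross$linkage$locus1[i], locus2 = cross$linkage$locus2[i],
           r = cross$linkage$r[i]))
  cfg$simulation <- list(n_asci = cross$n_asci, packaging = cross$packaging,
                         mode = cross$mode)
  if (!is.null(cross$seed)) cfg$simulation$seed <- cross$seed
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read and validate a cross config file
#'
#' Schema violations (unknown keys, missing fields, invalid references) are
#' reported as `config_error` conditions before any computation runs.
#'
#' @param path YAML file written by [write_cross_config()] or by hand.
#' @return A [cross_spec()].
#' @export
read_cross_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) config_error("cannot parse ", path, ": ",
                                                   conditionMessage(e)))
  check_keys(cfg, c("cross", "simulation", "inference", "output"), "cross")
  cx <- cfg$cross
  check_keys(cx, c("id", "parent1", "parent2", "loci", "alleles", "linkage"),
             c("parent1", "parent2", "loci", "alleles"), "cross")
  mk_hap <- function(h, nm) {
    check_keys(h, c("strain_id", "alleles"), c("strain_id", "alleles"), nm)
    haplotype(h$strain_id, unlist(h$alleles))
  }
  mk_locus <- function(l) {
    check_keys(l, c("id", "chromosome", "sds_prob", "position_morgans"),
               c("id", "chromosome", "sds_prob"), "locus")
    locus(l$id, l$chromosome, l$sds_prob, l$position_morgans %||% NA_real_)
  }
  mk_allele <- function(a) {
    check_keys(a, c("id", "locus_id", "distorter_active", "responder_covers",
                    "trans_activators", "pigment_functional",
                    "killing_efficiency", "selectable_markers"),
               c("id", "locus_id"), "allele")
    allele(a$id, a$locus_id,
           distorter_active = a$distorter_active %||% FALSE,
           responder_covers = unlist(a$responder_covers) %||% character(),
           trans_activators = unlist(a$trans_activators) %||% character(),
           pigment_functional = a$pigment_functional %||% NA,
           killing_efficiency = a$killing_efficiency %||% 1,
           selectable_markers = unlist(a$selectable_markers) %||% character())
  }
  sim <- cfg$simulation %||% list()
  check_keys(sim, c("n_asci", "seed", "packaging", "mode"), where = "simulation")
  tryCatch(
    cross_spec(mk_hap(cx$parent1, "parent1"), mk_hap(cx$parent2, "parent2"),
               loci = lapply(cx$loci, mk_locus),
               alleles = lapply(cx$alleles, mk_allele),
               linkage = if (!is.null(cx$linkage))
                 do.call(rbind, lapply(cx$linkage, as.data.frame)),
               packaging = sim$packaging %||% "binucleate_tetrad",
               n_asci = sim$n_asci %||% 1000L, seed = sim$seed,
               mode = sim$mode %||% "phenomenological", id = cx$id),
    error = function(e) config_error(conditionMessage(e)))
}

#' Write an ascus-class count table as TSV
#' @param counts `ascus_counts` from [simulate_cross()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "ascus_counts"))
  df <- as.data.frame(counts)
  df$n_asci <- attr(counts, "n_asci")
  df$cross_id <- attr(counts, "cross_id") %||% NA
  df$seed <- attr(counts, "seed") %||% NA
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an ascus-class count table written by [write_counts_tsv()]
#' @param path TSV file.
#' @return `ascus_counts` data frame.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- df[c("class", "n_pigmented", "n_unpigmented", "count")]
  class(out) <- c("ascus_counts", "data.frame")
  attr(out, "n_asci") <- df$n_asci[1]
  attr(out, "cross_id") <- df$cross_id[1]
  attr(out, "seed") <- df$seed[1]
  out
}

#' Write a survivor table as TSV
#' @param sim A `cross_sim` (or survivor data frame).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_survivors_tsv <- function(sim, path) {
  surv <- if (inherits(sim, "cross_sim")) sim$survivors else sim
  utils::write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write survivor spore records as JSON lines
#' @param sim A `cross_sim`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spores_jsonl <- function(sim, path) {
  stopifnot(inherits(sim, "cross_sim"))
  con <- file(path, "w")
  on.exit(close(con))
  surv <- sim$survivors
  for (i in seq_len(nrow(surv)))
    writeLines(jsonlite::toJSON(as.list(surv[i, ]), auto_unbox = TRUE), con)
  invisible(path)
}
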