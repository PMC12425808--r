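#' Read phased haplotypes from a VCF
#'
#' Loads phased biallelic SNVs from a VCF file (via the `vcfR` parser) and
#' polarizes alleles: 0 = ancestral, using the `INFO/AA` tag when present
#' and the REF allele otherwise (a logged fallback).  Multiallelic sites,
#' unphased genotypes and sites with missing alleles are dropped with a
#' message.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param region Optional `c(start, end)` 1-based inclusive position
#'   filter.
#' @return A list: `haplotypes` (n x S 0/1 matrix, two rows per diploid),
#'   `positions` (0-based site positions), `dropped` (named counts).
#' @export
read_vcf <- function(path, region = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  pos <- as.numeric(fix[, "POS"])
  keep <- rep(TRUE, length(pos))
  dropped <- c(multiallelic = 0L, unphased = 0L, missing = 0L,
               out_of_region = 0L)
  if (!is.null(region)) {
    inr <- pos >= region[1] & pos <= region[2]
    dropped["out_of_region"] <- sum(!inr)
    keep <- keep & inr
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | nchar(fix[, "REF"]) != 1L | nchar(alt) != 1L
  dropped["multiallelic"] <- sum(multi & keep)
  keep <- keep & !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  phased <- apply(gt, 1, function(g) all(grepl("\\|", g)))
  dropped["unphased"] <- sum(!phased & keep)
  keep <- keep & phased
  miss <- apply(gt, 1, function(g) any(grepl("\\.", g)))
  dropped["missing"] <- sum(miss & keep)
  keep <- keep & !miss
  if (!any(keep)) stop("no usable phased biallelic sites in region")
  gt <- gt[keep, , drop = FALSE]
  pos <- pos[keep]
  ## haplotype matrix: two columns per sample, order preserved
  split_gt <- function(g) as.integer(unlist(strsplit(g, "|", fixed = TRUE)))
  H <- matrix(0L, nrow = 2L * ncol(gt), ncol = nrow(gt))
  for (s in seq_len(nrow(gt))) H[, s] <- split_gt(gt[s, ])
  ## polarization: ancestral from INFO/AA, else REF (logged)
  aa <- vcfR::extract.info(v, element = "AA")[keep]
  ref <- fix[keep, "REF"]; altk <- fix[keep, "ALT"]
  no_aa <- is.na(aa) | !(aa %in% c(ref, altk))
  if (any(no_aa))
    message(sum(no_aa), " sites without usable INFO/AA: REF taken as ",
            "ancestral")
  flip <- !no_aa & aa == altk
  H[, flip] <- 1L - H[, flip]
  seg <- colSums(H) > 0L & colSums(H) < nrow(H)
  list(haplotypes = H[, seg, drop = FALSE], positions = pos[seg] - 1,
       dropped = dropped)
}

#' Read a HapMap-style recombination map
#'
#' Columns: chromosome, position (bp), rate (cM/Mb), cumulative map (cM).
#' The rate column converts to per-base per-generation crossover
#' probability as `1 cM/Mb = 1e-8 / bp`.
#'
#' @param path Path to a whitespace-delimited map file with a header.
#' @return A list of class `recomb_map`: `position` (0-based breakpoints),
#'   `rate` (per-bp per-generation, piecewise constant from each position
#'   to the next), `map_cm` (cumulative map, cM), and `at(x)`.
#' @export
read_recomb_map <- function(path) {
  m <- utils::read.table(path, header = TRUE)
  if (ncol(m) < 3) stop("expected at least 3 columns (chrom, pos, rate)")
  pos <- as.numeric(m[[2]])
  if (is.unsorted(pos)) stop("map positions must be sorted")
  rate <- as.numeric(m[[3]]) * 1e-8
  map_cm <- if (ncol(m) >= 4) as.numeric(m[[4]]) else
    c(0, cumsum(rate[-length(rate)] * diff(pos))) * 100
  out <- list(position = pos - 1, rate = rate, map_cm = map_cm)
  out$at <- function(x) rate[pmax(findInterval(x, out$position), 1L)]
  class(out) <- "recomb_map"
  out
}

#' Total genetic map length implied by a recombination map
#'
#' Integrates the piecewise-constant rate over the map's span; for a
#' well-formed file this reproduces the cumulative map column.
#'
#' @param map A `recomb_map`.
#' @return Length in centimorgans.
#' @export
map_length_cm <- function(map) {
  n <- length(map$position)
  if (n < 2) return(0)
  sum(map$rate[-n] * diff(map$position)) * 100
}

#' Write a JSON provenance record
#'
#' Records the package version, model parameters, chain configuration and
#' seed of a sampling run, for reproducibility.
#'
#' @param path Output path.
#' @param params A [model_params()] object.
#' @param config A [chain_config()] object.
#' @param extra Optional named list of additional fields.
#' @return The path, invisibly.
#' @export
write_provenance <- function(path, params, config, extra = list()) {
  rec <- c(list(
    package = "argthread",
    version = as.character(utils::packageVersion("argthread")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    Ne = params$Ne, mu = params$mu, r = params$r,
    n_samples = config$n_samples, thin = config$thin,
    burn_in = config$burn_in, seed = config$seed), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
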