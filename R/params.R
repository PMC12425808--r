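#' Model parameters for the coalescent with recombination
#'
#' Bundles the three rates the sampler needs: the diploid effective
#' population size `Ne` (individuals), the per-base per-generation mutation
#' rate `mu`, and the per-base per-generation recombination rate `r`.
#' The population-scaled rates `theta = 4*Ne*mu` and `rho = 4*Ne*r` are
#' derived and kept consistent.
#'
#' @param Ne Diploid effective population size, in individuals.
#' @param mu Mutation rate per base pair per generation.
#' @param r Recombination rate per base pair per generation.
#' @return An object of class `model_params` with fields `Ne`, `mu`, `r`,
#'   `theta`, `rho`.
#' @examples
#' p <- model_params(Ne = 1e4, mu = 2e-8, r = 2e-8)
#' p$theta  # 4 * Ne * mu = 8e-4
#' @export
model_params <- function(Ne, mu, r) {
  stopifnot(is.numeric(Ne), is.numeric(mu), is.numeric(r),
            length(Ne) == 1, length(mu) == 1, length(r) == 1)
  if (!(Ne > 0 && mu > 0 && r > 0)) {
    stop("Ne, mu and r must all be strictly positive")
  }
  structure(
    list(Ne = Ne, mu = mu, r = r, theta = 4 * Ne * mu, rho = 4 * Ne * r),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("model_params: Ne =", x$Ne, " mu =", x$mu, " r =", x$r,
      " (theta =", x$theta, ", rho =", x$rho, ")\n")
  invisible(x)
}
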