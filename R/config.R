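#' Pipeline configuration
#'
#' Collects every tunable of the kernel and model pipeline with its
#' default.  Defaults: regularization \code{lambda = 35} (the value the
#' lambda sweep identifies as optimal), uniform integration weights
#' \code{alpha = beta = c(0.25, 0.25, 0.25, 0.25)}, Gaussian bandwidth
#' scale \code{phi_prime = 1}, site window of 40 nt, alignment scores
#' match +1 / mismatch -1 / gap -1, SSR counts kept as counts
#' (\code{ssr_binary = FALSE}), and in leave-one-out evaluation 5
#' sampled negatives per positive.
#'
#' @param lambda Regularization parameter, > 0 (0 allowed only for
#'   strictly positive-definite kernels).
#' @param alpha Four nonnegative weights for the miRNA kernels, in the
#'   order free energy, interaction profile, sequence, SSR.
#' @param beta Four nonnegative weights for the site kernels, in the
#'   order free energy, accessibility, AU content, SSR.
#' @param phi_prime Bandwidth scale of the Gaussian profile kernels.
#' @param site_length Target-site window length in nucleotides.
#' @param nw_match,nw_mismatch,nw_gap Needleman-Wunsch scores.
#' @param ssr_binary Threshold SSR counts to presence/absence.
#' @param ssr_min_repeats Minimum tandem copies for an SSR run.
#' @param accessibility_window Accessibility window in nucleotides.
#' @param negative_ratio Sampled negatives per evaluated positive in
#'   leave-one-out cross-validation (\code{Inf} enumerates all).
#' @param max_positives Cap on the number of positives scored in
#'   leave-one-out cross-validation (\code{Inf} evaluates all).
#' @param iterations Leave-sites-out repetitions.
#' @param provider Folding provider name, \code{"nussinov"} or
#'   \code{"vienna"}.
#' @return A named list of class \code{mirkron_config}.
#' @export
mirkron_config <- function(lambda = 35,
                           alpha = rep(0.25, 4),
                           beta = rep(0.25, 4),
                           phi_prime = 1,
                           site_length = 40L,
                           nw_match = 1, nw_mismatch = -1, nw_gap = -1,
                           ssr_binary = FALSE,
                           ssr_min_repeats = 3L,
                           accessibility_window = 10L,
                           negative_ratio = 5,
                           max_positives = Inf,
                           iterations = 100L,
                           provider = c("nussinov", "vienna")) {
  provider <- match.arg(provider)
  stopifnot(length(alpha) == 4L, length(beta) == 4L,
            all(alpha >= 0), all(beta >= 0),
            sum(alpha) > 0, sum(beta) > 0,
            lambda >= 0, phi_prime > 0, site_length >= 1,
            negative_ratio > 0, max_positives > 0, iterations >= 1)
  structure(list(lambda = lambda, alpha = alpha, beta = beta,
                 phi_prime = phi_prime, site_length = as.integer(site_length),
                 nw_match = nw_match, nw_mismatch = nw_mismatch,
                 nw_gap = nw_gap, ssr_binary = ssr_binary,
                 ssr_min_repeats = as.integer(ssr_min_repeats),
                 accessibility_window = as.integer(accessibility_window),
                 negative_ratio = negative_ratio,
                 max_positives = max_positives,
                 iterations = as.integer(iterations),
                 provider = provider),
            class = "mirkron_config")
}

get_provider <- function(config) {
  switch(config$provider,
         nussinov = nussinov_provider(),
         vienna = vienna_provider())
}
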