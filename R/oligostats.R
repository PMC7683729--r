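# Binomial statistics of partial spin-tagging in a homotrimer. Diluting a
# doubly-site-labelled protein with unlabelled protein and letting monomers
# re-equilibrate yields trimers whose tagged-monomer count is binomial in the
# tagged fraction p; keeping that count at one isolates the intra-monomer
# Gd-Gd distance from the inter-chain background.

#' Probability that a trimer carries k tagged monomers
#'
#' `C(3,k) p^k (1-p)^(3-k)` under independent monomer exchange.
#'
#' @param p Tagged fraction in \[0, 1\].
#' @param k Number of tagged monomers, in 0..3 (vectorized).
#' @return Probability (or vector of probabilities).
#' @export
#' @examples
#' trimer_tag_probability(0.1, 1)  # ~0.243
trimer_tag_probability <- function(p, k) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]", call. = FALSE)
  if (any(!k %in% 0:3))
    stop("k must be in 0..3", call. = FALSE)
  stats::dbinom(k, size = 3L, prob = p)
}

#' Full tagged-monomer distribution of a trimer mix
#'
#' @param p Tagged fraction in \[0, 1\].
#' @return A `trimer_tag_mix`: `p` and `probabilities` for k = 0..3.
#' @export
trimer_tag_mix <- function(p) {
  pr <- trimer_tag_probability(p, 0:3)
  structure(list(tagged_fraction = p,
                 probabilities = stats::setNames(pr, paste0("k", 0:3))),
            class = "trimer_tag_mix")
}

#' @export
print.trimer_tag_mix <- function(x, ...) {
  cat(sprintf("<trimer_tag_mix> tagged fraction %.3f\n", x$tagged_fraction))
  pr <- x$probabilities
  # round to the reporting precision: integer percent for k = 1, 2 and one
  # decimal for k = 3
  cat(sprintf("  k=0: %.1f%%   k=1: %.0f%%   k=2: %.0f%%   k=3: %.1f%%\n",
              100 * pr[1], 100 * pr[2], 100 * pr[3], 100 * pr[4]))
  invisible(x)
}

#' Clean vs. contaminated signal fractions under tag dilution
#'
#' For monomers labelled at two sites, a trimer with exactly one tagged
#' monomer yields a clean intra-monomer distance, while two or more tagged
#' monomers contaminate the signal with inter-chain pairs.
#'
#' @param p Tagged fraction in (0, 1\].
#' @return List with `clean` (exactly one tagged monomer), `contaminated`
#'   (two or more) and `silent` (none).
#' @export
pairwise_signal_fractions <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("p must be in (0, 1]: p = 0 gives no signal", call. = FALSE)
  pr <- trimer_tag_probability(p, 0:3)
  list(clean = pr[2], contaminated = pr[3] + pr[4], silent = pr[1])
}
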