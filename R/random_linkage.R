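# Chance sex-linkage under the binomial null.
#
# At an autosomal locus with allele frequency 1/2, any individual is
# homozygous with probability 1/2 and heterozygous with probability 1/2, so
# the probability that all n sequenced individuals happen to show the ideal
# sex-linked pattern (every female homozygous, every male heterozygous) is
# 0.5^n, and among L independent loci L * 0.5^n are expected to do so by
# chance. These closed forms drive sample-size planning for marker-discovery
# studies.

#' Per-locus probability of chance sex-linkage
#'
#' @param n number of individuals sequenced at the locus (non-negative
#'   integer, vectorized).
#' @param log if `TRUE`, return the natural log probability (useful for very
#'   large `n`).
#' @return `0.5^n` (exactly 1 for `n = 0`).
#' @examples
#' p_spurious(25)   # 2.98e-08
#' p_spurious(12)   # 2.44e-04
#' @export
p_spurious <- function(n, log = FALSE) {
  if (any(n < 0) || any(n != round(n))) {
    stop("`n` must be a non-negative integer")
  }
  lp <- -n * base::log(2)
  if (log) lp else exp(lp)
}

#' Expected number of spuriously sex-linked loci
#'
#' @inheritParams p_spurious
#' @param L number of loci examined (non-negative, vectorized).
#' @return `L * 0.5^n`.
#' @examples
#' expected_spurious(12, 42772)  # ~10.4
#' @export
expected_spurious <- function(n, L) {
  if (any(L < 0)) stop("`L` must be non-negative")
  L * p_spurious(n)
}

#' Minimum sample size to control chance sex-linkage
#'
#' Smallest number of individuals `n` for which fewer than `max_expected`
#' of `L` loci are expected to show a chance sex-linked pattern, i.e. the
#' smallest integer with `L * 0.5^n < max_expected` (strict inequality),
#' found by integer search.
#'
#' @param L number of loci examined (>= 1).
#' @param max_expected tolerated expected count of spurious loci (> 0).
#' @return Integer sample size.
#' @examples
#' min_sample_size(42772)  # 16
#' @export
min_sample_size <- function(L, max_expected = 1) {
  stopifnot(L >= 1, max_expected > 0)
  n <- 0L
  while (expected_spurious(n, L) >= max_expected) n <- n + 1L
  n
}

#' Planning grid of expected spurious sex-linked loci
#'
#' Full cross of [expected_spurious()] over sample sizes and locus counts,
#' for planning how many individuals a marker-discovery study needs.
#'
#' @param n_values sample sizes (non-negative integers).
#' @param L_values locus counts.
#' @param max_expected threshold passed to [min_sample_size()] for the per-L
#'   minimal sample size annotation.
#' @return Data frame of class `planning_grid` with columns `n`, `L`,
#'   `expected` (rows sorted by `L` then `n`); attribute `min_n` holds the
#'   per-L minimal sample size.
#' @export
planning_grid <- function(n_values, L_values, max_expected = 1) {
  if (!length(n_values) || !length(L_values)) stop("empty grid axes")
  n_values <- sort(unique(n_values))
  L_values <- sort(unique(L_values))
  g <- expand.grid(n = n_values, L = L_values, KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$L, g$n), , drop = FALSE]
  g$expected <- expected_spurious(g$n, g$L)
  rownames(g) <- NULL
  attr(g, "min_n") <- data.frame(
    L = L_values,
    min_n = vapply(L_values, min_sample_size, integer(1),
                   max_expected = max_expected))
  class(g) <- c("planning_grid", "data.frame")
  g
}

#' @export
plot.planning_grid <- function(x, ...) {
  Ls <- unique(x$L)
  ns <- unique(x$n)
  mat <- matrix(x$expected[order(x$L, x$n)], nrow = length(ns))
  graphics::matplot(ns, mat, type = "l", lty = 1, log = "y",
                    xlab = "individuals sequenced (n)",
                    ylab = "expected spurious sex-linked loci", ...)
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topright", legend = format(Ls, big.mark = ","),
                   col = seq_along(Ls), lty = 1, title = "loci (L)",
                   cex = 0.8, bty = "n")
  invisible(x)
}
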