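#' Cochran-Armitage trend test of sex x genotype
#'
#' Tests for a monotone trend in genotype class frequencies between the two
#' sexes. With column scores \eqn{s_j}, female counts \eqn{n_{fj}}, male
#' counts \eqn{n_{mj}}, row totals \eqn{N_f, N_m} and column totals
#' \eqn{c_j} (grand total \eqn{N}), the trend statistic is
#' \deqn{T = \sum_j s_j (n_{fj} N_m - n_{mj} N_f)/N,}
#' and the chi-square form is \eqn{\chi^2 = T^2 / \mathrm{Var}(T)} with the
#' margins-fixed null variance
#' \deqn{\mathrm{Var}(T) = \frac{N_f N_m}{N^2}\left(\sum_j s_j^2 c_j -
#'   \frac{(\sum_j s_j c_j)^2}{N}\right),}
#' referred to a chi-square distribution with 1 df. Under perfect separation
#' the statistic equals the total count \eqn{N}. The statistic is invariant
#' to affine rescaling of the scores.
#'
#' @param counts 2 x k integer matrix, rows = (female, male) — row names
#'   `FEMALE`/`MALE` are honoured if present — columns = ordered genotype
#'   classes. Build from a dataset with [sex_genotype_counts()].
#' @param scores strictly increasing numeric scores, one per column. Default
#'   `0:(k-1)`: SNP-allele dosage `(0, 1, 2)` for REF_HOM/HET/ALT_HOM,
#'   `(0, 1)` for ABSENT/PRESENT.
#' @param locus_id optional label carried into the result.
#' @return Object of class `trend_test`: list with `chi2`, `df` (= 1),
#'   `p_value` (upper tail), `statistic` (the signed \eqn{T}), `direction`
#'   (`"male"` when males carry the higher scores, `"female"` otherwise,
#'   `"none"` for no trend), `scores`, `counts`, and `undefined` (`TRUE` when
#'   the score variance is degenerate, e.g. all mass in one column; then
#'   `chi2` and `p_value` are `NA`).
#' @examples
#' counts <- rbind(FEMALE = c(23, 0, 0), MALE = c(0, 54, 0))
#' cochran_armitage(counts)  # perfect separation: chi2 = 77
#' @export
cochran_armitage <- function(counts, scores = NULL, locus_id = NULL) {
  counts <- .check_counts(counts)
  k <- ncol(counts)
  if (is.null(scores)) scores <- seq_len(k) - 1
  if (length(scores) != k || any(diff(scores) <= 0)) {
    stop("`scores` must be strictly increasing with one score per column")
  }
  nf <- sum(counts[1L, ]); nm <- sum(counts[2L, ])
  N <- nf + nm
  cj <- colSums(counts)
  T_stat <- sum(scores * (counts[1L, ] * nm - counts[2L, ] * nf)) / N
  varT <- (nf * nm / N^2) * (sum(scores^2 * cj) - sum(scores * cj)^2 / N)
  undefined <- varT <= 0 || nf == 0 || nm == 0
  chi2 <- if (undefined) NA_real_ else T_stat^2 / varT
  p <- if (undefined) NA_real_ else stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  mean_f <- if (nf > 0) sum(scores * counts[1L, ]) / nf else NA_real_
  mean_m <- if (nm > 0) sum(scores * counts[2L, ]) / nm else NA_real_
  direction <- if (undefined || isTRUE(all.equal(mean_f, mean_m))) "none"
               else if (mean_m > mean_f) "male" else "female"
  structure(list(locus_id = locus_id, chi2 = chi2, df = 1L, p_value = p,
                 statistic = T_stat, direction = direction, scores = scores,
                 counts = counts, undefined = undefined),
            class = "trend_test")
}

.check_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L) stop("`counts` must have two rows (female, male)")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers")
  }
  rn <- toupper(rownames(counts))
  if (!is.null(rownames(counts)) && all(c("FEMALE", "MALE") %in% rn)) {
    counts <- counts[match(c("FEMALE", "MALE"), rn), , drop = FALSE]
  }
  if (sum(counts) == 0) stop("`counts` is empty")
  counts
}

#' @export
print.trend_test <- function(x, ...) {
  cat("Cochran-Armitage trend test",
      if (!is.null(x$locus_id)) paste0(" [", x$locus_id, "]"), "\n", sep = "")
  if (x$undefined) {
    cat("  degenerate table: statistic undefined\n")
  } else {
    cat(sprintf("  chi2 = %.4g, df = 1, p = %.4g (direction: %s)\n",
                x$chi2, x$p_value, x$direction))
  }
  invisible(x)
}

#' Permutation p-value for the trend test
#'
#' Monte-Carlo companion to the asymptotic test: sex labels are permuted
#' across individuals (holding genotypes fixed) and the chi-square trend
#' statistic recomputed, giving
#' \eqn{p = (1 + \#\{\chi^2_{perm} \ge \chi^2_{obs}\})/(n_{perm}+1)}.
#'
#' @inheritParams cochran_armitage
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#' @return Object of class `trend_test` with `p_value` the permutation
#'   p-value and fields `n_perm` and `seed` recorded.
#' @export
permutation_p <- function(counts, scores = NULL, n_perm = 999, seed = 1) {
  counts <- .check_counts(counts)
  k <- ncol(counts)
  if (is.null(scores)) scores <- seq_len(k) - 1
  stopifnot(n_perm >= 1)
  obs <- cochran_armitage(counts, scores)
  if (obs$undefined) {
    obs$n_perm <- n_perm; obs$seed <- seed
    return(obs)
  }
  geno <- rep(seq_len(k), times = colSums(counts))
  nf <- sum(counts[1L, ])
  n <- length(geno)
  exceed <- with_seed(seed, {
    e <- 0L
    for (b in seq_len(n_perm)) {
      fem <- sample.int(n, nf)
      perm <- rbind(tabulate(geno[fem], nbins = k),
                    tabulate(geno[-fem], nbins = k))
      st <- cochran_armitage(perm, scores)
      if (!st$undefined && st$chi2 >= obs$chi2 - 1e-12) e <- e + 1L
    }
    e
  })
  obs$p_value <- (1 + exceed) / (n_perm + 1)
  obs$n_perm <- n_perm
  obs$seed <- seed
  obs
}

#' Tabulate sex x genotype counts for a locus
#'
#' @param dataset a [genotype_dataset()].
#' @param locus_id one locus id.
#' @return 2 x k count matrix (rows `FEMALE`, `MALE`). SNP columns are
#'   `REF_HOM`, `HET`, `ALT_HOM` over non-missing calls; PA columns are
#'   `ABSENT`, `PRESENT` with unsequenced fragments counted as absent.
#'   Samples of unknown sex are excluded.
#' @export
sex_genotype_counts <- function(dataset, locus_id) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  i <- match(locus_id, dataset$loci$locus_id)
  if (is.na(i)) stop("unknown locus: ", locus_id)
  calls <- dataset$calls[i, ]
  sex <- dataset$samples$sex
  keep <- sex %in% c("FEMALE", "MALE")
  calls <- calls[keep]; sex <- sex[keep]
  if (dataset$marker_type == "SNP") {
    classes <- .SNP_CALLS
    f <- factor(calls, levels = classes)
  } else {
    classes <- c("ABSENT", "PRESENT")
    f <- factor(ifelse(is.na(calls) | calls == "ABSENT", "ABSENT", "PRESENT"),
                levels = classes)
  }
  m <- rbind(FEMALE = table(f[sex == "FEMALE"]),
             MALE = table(f[sex == "MALE"]))
  m <- matrix(as.integer(m), nrow = 2,
              dimnames = list(c("FEMALE", "MALE"), classes))
  m
}

#' Trend tests for a set of loci
#'
#' @param dataset a [genotype_dataset()].
#' @param loci locus ids to test (default: all).
#' @param n_perm if > 0, also compute a permutation p-value per locus.
#' @param seed seed for the permutation null.
#' @return Data frame: `locus_id`, `chi2`, `df`, `p_value`, `direction`,
#'   `p_bonferroni` (informational), and `p_perm` when `n_perm > 0`.
#' @export
trend_test_table <- function(dataset, loci = NULL, n_perm = 0, seed = 1) {
  if (is.null(loci)) loci <- dataset$loci$locus_id
  rows <- lapply(loci, function(id) {
    counts <- sex_genotype_counts(dataset, id)
    tt <- cochran_armitage(counts, locus_id = id)
    out <- data.frame(locus_id = id, chi2 = tt$chi2, df = tt$df,
                      p_value = tt$p_value, direction = tt$direction,
                      stringsAsFactors = FALSE)
    if (n_perm > 0) {
      out$p_perm <- permutation_p(counts, n_perm = n_perm, seed = seed)$p_value
    }
    out
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- pmin(1, res$p_value * nrow(res))
  res
}
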