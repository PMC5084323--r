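#' Pairwise Hamming distance matrix over loci
#'
#' For each pair of individuals, the fraction of jointly non-missing loci at
#' which their genotype calls differ (pairwise-complete denominator). Pairs
#' sharing fewer than `min_overlap` called loci get an undefined (`NA`)
#' distance.
#'
#' @param dataset a [genotype_dataset()].
#' @param loci locus ids to use (default: all). Must be non-empty.
#' @param min_overlap minimum number of jointly called loci for a defined
#'   distance (>= 1).
#' @return Object of class `hamming_matrix`: list with `distances` (symmetric
#'   matrix, zero diagonal), `overlap` (counts of jointly non-missing loci)
#'   and `sample_ids`.
#' @export
hamming_matrix <- function(dataset, loci = NULL, min_overlap = 1) {
  stopifnot(inherits(dataset, "genotype_dataset"), min_overlap >= 1)
  if (is.null(loci)) loci <- dataset$loci$locus_id
  if (!length(loci)) stop("empty locus subset")
  idx <- match(loci, dataset$loci$locus_id)
  if (anyNA(idx)) stop("unknown locus id(s): ",
                       paste(loci[is.na(idx)], collapse = ", "))
  m <- dataset$calls[idx, , drop = FALSE]
  nonmiss <- !is.na(m)
  overlap <- crossprod(nonmiss)
  agree <- matrix(0, ncol(m), ncol(m))
  lv <- unique(m[nonmiss])
  for (v in lv) {
    ind <- !is.na(m) & m == v
    agree <- agree + crossprod(ind)
  }
  d <- (overlap - agree) / overlap
  d[overlap < min_overlap] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- dimnames(overlap) <- list(dataset$samples$sample_id,
                                           dataset$samples$sample_id)
  structure(list(distances = d, overlap = overlap,
                 sample_ids = dataset$samples$sample_id),
            class = "hamming_matrix")
}

#' @export
print.hamming_matrix <- function(x, ...) {
  cat(sprintf("hamming_matrix: %d samples; mean defined distance %.3f\n",
              length(x$sample_ids),
              mean(x$distances[upper.tri(x$distances)], na.rm = TRUE)))
  invisible(x)
}

#' Summarize Hamming distances within each sex
#'
#' Mean, standard error (sd over the within-sex pairwise distances divided by
#' the square root of the number of pairs), minimum and maximum of the
#' distances among same-sex individuals, plus per-sample mean own-sex
#' distances and an outlier flag. A sample is flagged when its mean distance
#' to own-sex individuals exceeds `outlier_mult` times the sex's median mean
#' distance — candidate sex-reversed or recombinant individuals.
#'
#' @param hm a [hamming_matrix()].
#' @param samples sample table aligned with `hm` (needs `sample_id`, `sex`).
#' @param outlier_mult multiplier on the per-sex median mean own-sex distance.
#' @return Object of class `concordance_summary`: list with `by_sex` (one row
#'   per sex; `NA` statistics for a sex with fewer than two samples) and
#'   `sample_stats` (`sample_id`, `sex`, `mean_own_sex_dist`, `outlier`).
#' @export
summarize_by_sex <- function(hm, samples, outlier_mult = 2) {
  stopifnot(inherits(hm, "hamming_matrix"))
  idx <- match(hm$sample_ids, samples$sample_id)
  if (anyNA(idx)) stop("samples table does not cover every sample in the matrix")
  sex <- samples$sex[idx]
  by_sex <- list()
  stats_rows <- list()
  for (s in c("FEMALE", "MALE")) {
    ii <- which(sex == s)
    if (length(ii) < 2) {
      by_sex[[s]] <- data.frame(sex = s, n = length(ii), n_pairs = 0L,
                                mean = NA_real_, se = NA_real_,
                                min = NA_real_, max = NA_real_)
      if (length(ii)) {
        stats_rows[[s]] <- data.frame(sample_id = hm$sample_ids[ii], sex = s,
                                      mean_own_sex_dist = NA_real_,
                                      outlier = NA, stringsAsFactors = FALSE)
      }
      next
    }
    sub <- hm$distances[ii, ii, drop = FALSE]
    pairs <- sub[upper.tri(sub)]
    pairs <- pairs[!is.na(pairs)]
    np <- length(pairs)
    by_sex[[s]] <- data.frame(
      sex = s, n = length(ii), n_pairs = np,
      mean = mean(pairs),
      se = if (np > 1) stats::sd(pairs) / sqrt(np) else NA_real_,
      min = min(pairs), max = max(pairs))
    own_mean <- vapply(seq_along(ii), function(j) {
      mean(sub[j, -j], na.rm = TRUE)
    }, numeric(1))
    med <- stats::median(own_mean, na.rm = TRUE)
    stats_rows[[s]] <- data.frame(sample_id = hm$sample_ids[ii], sex = s,
                                  mean_own_sex_dist = own_mean,
                                  outlier = own_mean > outlier_mult * med,
                                  stringsAsFactors = FALSE)
  }
  out <- list(by_sex = do.call(rbind, c(by_sex, make.row.names = FALSE)),
              sample_stats = do.call(rbind, c(stats_rows, make.row.names = FALSE)),
              outlier_mult = outlier_mult)
  class(out) <- "concordance_summary"
  out
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("Within-sex Hamming distance summary:\n")
  print(x$by_sex, row.names = FALSE, digits = 3)
  n_out <- sum(x$sample_stats$outlier, na.rm = TRUE)
  if (n_out) {
    cat("outliers (> ", x$outlier_mult, "x sex median own-sex distance): ",
        paste(x$sample_stats$sample_id[which(x$sample_stats$outlier)],
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Rank candidate loci by degree of sex-linkage
#'
#' Scores each locus by how close it comes to the ideal pattern of the
#' heterogametic system: for SNP loci under XY,
#' `(homogametic ref-hom proportion + heterogametic het proportion)/2`
#' averaged over evaluable cohorts; for PA loci,
#' `(linked-sex presence + (1 - other-sex presence))/2`. Ties are broken by
#' the trend-test chi-square, then by locus id, so the ordering is
#' deterministic.
#'
#' @param candidates a [discover_candidates()] table (or any proportions
#'   table with the same columns).
#' @param tests optional [trend_test_table()] result supplying `chi2`.
#' @param system `"XY"` or `"ZW"`.
#' @return Data frame `locus_id`, `score`, `chi2`, ordered best first.
#' @export
rank_loci <- function(candidates, tests = NULL, system = c("XY", "ZW")) {
  system <- match.arg(system)
  stopifnot(is.data.frame(candidates))
  if ("f_ref_hom" %in% names(candidates)) {
    hom_ref <- if (system == "XY") candidates$f_ref_hom else candidates$m_ref_hom
    het_het <- if (system == "XY") candidates$m_het else candidates$f_het
    row_score <- (hom_ref + het_het) / 2
  } else {
    linked <- if (system == "XY") candidates$m_present else candidates$f_present
    other <- if (system == "XY") candidates$f_present else candidates$m_present
    row_score <- (linked + (1 - other)) / 2
  }
  row_score[!candidates$evaluable] <- NA
  score <- vapply(split(row_score, candidates$locus_id), mean,
                  numeric(1), na.rm = TRUE)
  res <- data.frame(locus_id = names(score), score = unname(score),
                    stringsAsFactors = FALSE)
  res$chi2 <- if (!is.null(tests)) {
    tests$chi2[match(res$locus_id, tests$locus_id)]
  } else NA_real_
  ord <- order(-res$score, -ifelse(is.na(res$chi2), -Inf, res$chi2),
               res$locus_id)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call genotypic sex from top-ranked sex-linked loci
#'
#' Majority vote across the `k` best loci. Under XY, a call carrying the SNP
#' allele (`HET` or `ALT_HOM`; `PRESENT` for PA markers) votes male and
#' `REF_HOM` (`ABSENT`) votes female; ZW swaps the vote labels. The called
#' sex is the strict majority of non-missing votes, `AMBIGUOUS` on a tie or
#' when every locus is missing. Concordance is counted against the phenotypic
#' sex recorded in the sample table (`NA` counts for unknown-sex samples).
#'
#' @param dataset a [genotype_dataset()].
#' @param top_loci ordered locus ids (best first), e.g. from [rank_loci()].
#' @param k number of loci to use (`k >= 1`, at most `length(top_loci)`).
#' @param system `"XY"` or `"ZW"`.
#' @return Data frame of class `sex_calls`: `sample_id`, `phenotypic_sex`,
#'   `called_sex`, `n_loci_used`, `n_concordant`, `n_discordant`,
#'   `n_missing`, `concordant` (logical: called sex agrees with phenotype).
#' @export
call_genotypic_sex <- function(dataset, top_loci, k = 3,
                               system = c("XY", "ZW")) {
  system <- match.arg(system)
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (k < 1) stop("k must be at least 1")
  if (k > length(top_loci)) stop("k exceeds the number of supplied loci")
  use <- top_loci[seq_len(k)]
  idx <- match(use, dataset$loci$locus_id)
  if (anyNA(idx)) stop("unknown locus id(s): ",
                       paste(use[is.na(idx)], collapse = ", "))
  m <- dataset$calls[idx, , drop = FALSE]
  if (dataset$marker_type == "SNP") {
    vote <- ifelse(is.na(m), NA_character_,
                   ifelse(m == "REF_HOM", "hom_sex", "het_sex"))
  } else {
    vote <- ifelse(is.na(m), NA_character_,
                   ifelse(m == "PRESENT", "het_sex", "hom_sex"))
  }
  hom_label <- if (system == "XY") "FEMALE" else "MALE"
  het_label <- if (system == "XY") "MALE" else "FEMALE"
  n_het <- colSums(vote == "het_sex", na.rm = TRUE)
  n_hom <- colSums(vote == "hom_sex", na.rm = TRUE)
  called <- ifelse(n_het > n_hom, het_label,
                   ifelse(n_hom > n_het, hom_label, "AMBIGUOUS"))
  pheno <- dataset$samples$sex
  pheno_vote <- ifelse(pheno == hom_label, "hom_sex",
                       ifelse(pheno == het_label, "het_sex", NA))
  conc <- vapply(seq_len(ncol(m)), function(j) {
    if (is.na(pheno_vote[j])) return(NA_integer_)
    sum(vote[, j] == pheno_vote[j], na.rm = TRUE)
  }, integer(1))
  n_missing <- colSums(is.na(vote))
  res <- data.frame(sample_id = dataset$samples$sample_id,
                    phenotypic_sex = pheno,
                    called_sex = unname(called),
                    n_loci_used = k,
                    n_concordant = conc,
                    n_discordant = ifelse(is.na(conc), NA_integer_,
                                          k - n_missing - conc),
                    n_missing = unname(n_missing),
                    concordant = ifelse(pheno == "UNKNOWN", NA,
                                        called == pheno),
                    stringsAsFactors = FALSE)
  class(res) <- c("sex_calls", "data.frame")
  res
}
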