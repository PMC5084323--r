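#' Run the full sex-linked marker discovery pipeline
#'
#' Fits the whole analysis to a genotype dataset: per-cohort sex-stratified
#' genotype proportions, the XY/ZW filter criteria, Cochran-Armitage trend
#' tests of sex x genotype for every candidate locus, Hamming-distance
#' concordance among individuals at the candidate loci, locus ranking and
#' majority-vote genotypic-sex calls from the top `k` loci, plus the
#' chance-sex-linkage context (`L * 0.5^n`) for the dataset's own size.
#'
#' @param dataset a [genotype_dataset()].
#' @param cohort_by sample-table column defining discovery cohorts analyzed
#'   separately and compared afterwards (e.g. `"life_stage"`), or `NULL`.
#' @param criteria a [filter_criteria()].
#' @param system `"auto"` (default: pick the system — XY or ZW — with more
#'   candidate loci, XY on a tie), `"XY"` or `"ZW"`.
#' @param k number of top-ranked loci used for genotypic-sex calling.
#' @param min_overlap minimum jointly called loci for a defined Hamming
#'   distance.
#' @param outlier_mult own-sex mean-distance multiplier flagging outlier
#'   individuals (see [summarize_by_sex()]).
#' @param n_perm permutations per candidate trend test (0 = asymptotic only).
#' @param seed seed for the permutation null.
#' @return Object of class `sexlink_scan`: list with elements `system`,
#'   `candidates` (per locus x cohort verdicts), `candidate_loci` (ids
#'   passing in at least one cohort), `tests`, `ranking`, `hamming`,
#'   `concordance`, `sex_calls`, `random_linkage` (`n`, `L`, `p_spurious`,
#'   `expected_spurious`), `criteria`, `k`, and the call.
#' @examples
#' cfg <- sim_config(n_females = 20, n_males = 20,
#'                   loci = list(locus_sim_spec("SL1"), locus_sim_spec("SL2"),
#'                               locus_sim_spec("SL3")),
#'                   n_autosomal = 50, seed = 42)
#' fit <- sexlink_scan(simulate_dataset(cfg)$dataset)
#' fit
#' @export
sexlink_scan <- function(dataset, cohort_by = NULL,
                         criteria = filter_criteria(),
                         system = c("auto", "XY", "ZW"), k = 3,
                         min_overlap = 1, outlier_mult = 2, n_perm = 0,
                         seed = 1) {
  system <- match.arg(system)
  stopifnot(inherits(dataset, "genotype_dataset"))
  cand <- discover_candidates(dataset, cohort_by = cohort_by,
                              criteria = criteria)
  if (dataset$marker_type == "SNP") {
    xy_loci <- unique(cand$locus_id[cand$xy_cross %in% c("all", "some")])
    zw_loci <- unique(cand$locus_id[cand$zw_cross %in% c("all", "some")])
  } else {
    xy_loci <- unique(cand$locus_id[cand$male_cross %in% c("all", "some")])
    zw_loci <- unique(cand$locus_id[cand$female_cross %in% c("all", "some")])
  }
  if (system == "auto") {
    system <- if (length(zw_loci) > length(xy_loci)) "ZW" else "XY"
  }
  loci <- if (system == "XY") xy_loci else zw_loci

  tests <- if (length(loci)) {
    trend_test_table(dataset, loci, n_perm = n_perm, seed = seed)
  } else NULL
  ranking <- if (length(loci)) {
    rank_loci(cand[cand$locus_id %in% loci, , drop = FALSE], tests,
              system = system)
  } else NULL
  hm <- conc <- calls <- NULL
  if (length(loci)) {
    hm <- hamming_matrix(dataset, loci, min_overlap = min_overlap)
    conc <- summarize_by_sex(hm, dataset$samples, outlier_mult = outlier_mult)
    k_use <- min(k, nrow(ranking))
    calls <- call_genotypic_sex(dataset, ranking$locus_id, k = k_use,
                                system = system)
  }
  n_sexed <- sum(dataset$samples$sex %in% c("FEMALE", "MALE"))
  rl <- list(n = n_sexed, L = nrow(dataset$loci),
             p_spurious = p_spurious(n_sexed),
             expected_spurious = expected_spurious(n_sexed,
                                                   nrow(dataset$loci)))
  structure(list(system = system, candidates = cand, candidate_loci = loci,
                 tests = tests, ranking = ranking, hamming = hm,
                 concordance = conc, sex_calls = calls, random_linkage = rl,
                 criteria = criteria, k = k, marker_type = dataset$marker_type,
                 samples = dataset$samples, call = match.call()),
            class = "sexlink_scan")
}

#' @export
print.sexlink_scan <- function(x, ...) {
  cat(sprintf("sexlink_scan: %d candidate %s loci (%s system) out of %d examined\n",
              length(x$candidate_loci), x$marker_type, x$system,
              x$random_linkage$L))
  cat(sprintf("chance-linkage context: n = %d sexed individuals, E[spurious] = %.3g\n",
              x$random_linkage$n, x$random_linkage$expected_spurious))
  if (length(x$candidate_loci)) {
    top <- utils::head(x$ranking$locus_id, x$k)
    cat("top-ranked loci: ", paste(top, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.sexlink_scan <- function(object, ...) {
  out <- list(system = object$system,
              n_candidates = length(object$candidate_loci),
              ranking = object$ranking, tests = object$tests,
              concordance = object$concordance,
              random_linkage = object$random_linkage)
  if (!is.null(object$sex_calls)) {
    sc <- object$sex_calls
    known <- sc$phenotypic_sex %in% c("FEMALE", "MALE")
    out$n_discordant_individuals <-
      sum(sc$called_sex[known] != "AMBIGUOUS" & !sc$concordant[known],
          na.rm = TRUE)
    out$n_ambiguous <- sum(sc$called_sex == "AMBIGUOUS")
    out$sex_calls <- sc
  }
  class(out) <- "summary.sexlink_scan"
  out
}

#' @export
print.summary.sexlink_scan <- function(x, ...) {
  cat(sprintf("Sex-linkage scan (%s system): %d candidate loci\n",
              x$system, x$n_candidates))
  if (!is.null(x$ranking)) {
    cat("\nLocus ranking (sex-linkage score, trend chi2):\n")
    print(utils::head(x$ranking, 10), row.names = FALSE, digits = 4)
  }
  if (!is.null(x$concordance)) {
    cat("\n")
    print(x$concordance)
  }
  if (!is.null(x$sex_calls)) {
    cat(sprintf("\nGenotypic-sex calls: %d discordant with phenotype, %d ambiguous\n",
                x$n_discordant_individuals, x$n_ambiguous))
  }
  cat(sprintf("\nExpected chance sex-linked loci at n = %d, L = %d: %.3g\n",
              x$random_linkage$n, x$random_linkage$L,
              x$random_linkage$expected_spurious))
  invisible(x)
}

#' Predict genotypic sex for new samples
#'
#' Applies the fitted scan's top-`k` ranked loci to a new genotype dataset
#' (e.g. individuals genotyped later at the discovered markers) via
#' [call_genotypic_sex()].
#'
#' @param object a [sexlink_scan()] fit with at least one candidate locus.
#' @param newdata a [genotype_dataset()] containing the scan's top loci.
#' @param k number of loci to vote with (default: the fit's `k`).
#' @param ... unused.
#' @return A `sex_calls` data frame (see [call_genotypic_sex()]).
#' @export
predict.sexlink_scan <- function(object, newdata, k = NULL, ...) {
  if (is.null(object$ranking) || !nrow(object$ranking)) {
    stop("scan found no candidate loci; nothing to predict with")
  }
  if (is.null(k)) k <- min(object$k, nrow(object$ranking))
  call_genotypic_sex(newdata, object$ranking$locus_id, k = k,
                     system = object$system)
}

#' Plot the Hamming concordance heatmap of a scan
#'
#' Image of the pairwise Hamming distance matrix at the candidate loci,
#' samples grouped by phenotypic sex (females first), low distances dark —
#' sex-reversed or recombinant individuals appear as bright stripes within
#' their own-sex block.
#'
#' @param x a [sexlink_scan()] with candidates.
#' @param ... passed to [graphics::image()].
#' @export
plot.sexlink_scan <- function(x, ...) {
  if (is.null(x$hamming)) stop("no candidate loci: nothing to plot")
  d <- x$hamming$distances
  ord <- order(factor(x$samples$sex, levels = c("FEMALE", "MALE", "UNKNOWN")),
               x$samples$sample_id)
  d <- d[ord, ord]
  n <- nrow(d)
  graphics::image(seq_len(n), seq_len(n), t(d[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(25, "viridis"),
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("Hamming distance, %d candidate loci",
                                 length(x$candidate_loci)), ...)
  nf <- sum(x$samples$sex == "FEMALE")
  graphics::abline(v = nf + 0.5, h = n - nf + 0.5, col = "white", lwd = 2)
  graphics::box()
  invisible(x)
}

#' Write scan results as TSV tables
#'
#' Writes the candidate table, trend tests, locus ranking, Hamming matrix,
#' within-sex summaries and sex calls to a directory, plus a `manifest.tsv`
#' recording package version, thresholds and options for provenance. Reruns
#' of the same fitted object produce identical files.
#'
#' @param scan a [sexlink_scan()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sexlink_results <- function(scan, dir) {
  stopifnot(inherits(scan, "sexlink_scan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(scan$candidates, "candidates.tsv")
  if (!is.null(scan$tests)) wt(scan$tests, "trend_tests.tsv")
  if (!is.null(scan$ranking)) wt(scan$ranking, "locus_ranking.tsv")
  if (!is.null(scan$hamming)) {
    d <- as.data.frame(scan$hamming$distances)
    d <- cbind(sample_id = rownames(scan$hamming$distances), d)
    wt(d, "hamming_distances.tsv")
  }
  if (!is.null(scan$concordance)) {
    wt(scan$concordance$by_sex, "concordance_by_sex.tsv")
    wt(scan$concordance$sample_stats, "sample_concordance.tsv")
  }
  if (!is.null(scan$sex_calls)) wt(scan$sex_calls, "sex_calls.tsv")
  manifest <- data.frame(
    key = c("package_version", "system", "k",
            names(unclass(scan$criteria)),
            "n_sexed", "n_loci", "expected_spurious"),
    value = c(as.character(utils::packageVersion("sexlinkr")), scan$system,
              scan$k, vapply(unclass(scan$criteria), format, character(1)),
              scan$random_linkage$n, scan$random_linkage$L,
              format(scan$random_linkage$expected_spurious)),
    stringsAsFactors = FALSE)
  wt(manifest, "manifest.tsv")
  invisible(paths)
}
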