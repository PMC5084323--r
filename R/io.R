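# Tabular genotype formats.
#
# two_row_dart: each SNP locus occupies two consecutive rows (REF allele row
#   then SNP allele row) with per-sample 0/1 scores; decoded per pair as
#   (1,0) -> REF_HOM, (0,1) -> ALT_HOM, (1,1) -> HET, (0,0)/blank -> missing.
# pa_matrix: one row per PA locus, per-sample 1/0 (= PRESENT/ABSENT), blank
#   -> missing.
# long: one record per (locus, sample) with an explicit call token; "NA" or
#   an empty field is missing.

.delim_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a genotype table
#'
#' Reads one of the three supported plain-text genotype layouts into a
#' [genotype_dataset()].
#'
#' @param path path to a CSV (`.csv`) or TSV file.
#' @param format `"two_row_dart"` (SNP loci as consecutive REF/SNP 0-1 score
#'   row pairs, DArT-style), `"pa_matrix"` (PA loci, one 0/1 row per locus) or
#'   `"long"` (`locus_id`, `sample_id`, `call` records with explicit tokens).
#' @param sample_table optional path to, or data frame of, a sample table with
#'   columns `sample_id`, `sex`, `population`, `life_stage`,
#'   `replicate_group` (see [read_sample_table()]). Every sample column in the
#'   genotype file must resolve to a row; without a table all samples get
#'   `UNKNOWN` sex.
#' @param marker_type for `format = "long"` with no informative call tokens
#'   (all missing): the marker type to assume.
#' @param sep field separator; default inferred from the file extension.
#' @return A [genotype_dataset()].
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path,
                                format = c("two_row_dart", "pa_matrix", "long"),
                                sample_table = NULL, marker_type = NULL,
                                sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .delim_for(path, sep)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())
  samples_df <- NULL
  if (!is.null(sample_table)) {
    samples_df <- if (is.character(sample_table)) {
      read_sample_table(sample_table)
    } else {
      as.data.frame(sample_table, stringsAsFactors = FALSE)
    }
  }

  build_samples <- function(ids) {
    if (is.null(samples_df)) {
      return(data.frame(sample_id = ids,
                        sex = rep("UNKNOWN", length(ids)),
                        population = rep(NA_character_, length(ids)),
                        life_stage = rep("OTHER", length(ids)),
                        replicate_group = rep(NA_character_, length(ids)),
                        stringsAsFactors = FALSE))
    }
    idx <- match(ids, samples_df$sample_id)
    if (anyNA(idx)) {
      stop("unresolvable sample_id(s): ", paste(ids[is.na(idx)], collapse = ", "))
    }
    samples_df[idx, , drop = FALSE]
  }

  if (format == "long") {
    need <- c("locus_id", "sample_id", "call")
    if (!all(need %in% names(tab))) {
      stop("long format requires columns: ", paste(need, collapse = ", "))
    }
    call <- tab$call
    call[call %in% c("", "NA")] <- NA_character_
    known <- unique(call[!is.na(call)])
    mt <- if (all(known %in% .SNP_CALLS) && length(known)) "SNP"
          else if (all(known %in% .PA_CALLS) && length(known)) "PA"
          else if (!length(known)) {
            if (is.null(marker_type)) "SNP" else marker_type
          } else stop("unknown call token(s): ",
                      paste(setdiff(known, c(.SNP_CALLS, .PA_CALLS)), collapse = ", "))
    loci_ids <- unique(tab$locus_id)
    sample_ids <- unique(tab$sample_id)
    if (anyDuplicated(tab[c("locus_id", "sample_id")])) {
      stop("duplicated (locus_id, sample_id) record(s) in long table")
    }
    m <- matrix(NA_character_, length(loci_ids), length(sample_ids),
                dimnames = list(loci_ids, sample_ids))
    m[cbind(match(tab$locus_id, loci_ids), match(tab$sample_id, sample_ids))] <- call
    return(genotype_dataset(m,
                            data.frame(locus_id = loci_ids,
                                       marker_type = rep(mt, length(loci_ids)),
                                       stringsAsFactors = FALSE),
                            build_samples(sample_ids)))
  }

  meta_cols <- intersect(c("locus_id", "allele", "sequence"), names(tab))
  sample_ids <- setdiff(names(tab), meta_cols)

  if (format == "pa_matrix") {
    if (!"locus_id" %in% names(tab)) stop("pa_matrix requires a locus_id column")
    sc <- as.matrix(tab[, sample_ids, drop = FALSE])
    bad <- setdiff(unique(sc[sc != ""]), c("0", "1"))
    if (length(bad)) stop("unknown PA score token(s): ", paste(bad, collapse = ", "))
    m <- ifelse(sc == "1", "PRESENT", ifelse(sc == "0", "ABSENT", NA_character_))
    dimnames(m) <- list(tab$locus_id, sample_ids)
    loci <- data.frame(locus_id = tab$locus_id,
                       marker_type = rep("PA", nrow(tab)),
                       stringsAsFactors = FALSE)
    if ("sequence" %in% names(tab)) {
      loci$ref_sequence <- ifelse(tab$sequence == "", NA_character_, tab$sequence)
    }
    return(genotype_dataset(m, loci, build_samples(sample_ids)))
  }

  # two_row_dart
  if (!all(c("locus_id", "allele") %in% names(tab))) {
    stop("two_row_dart requires locus_id and allele columns")
  }
  if (nrow(tab) %% 2 != 0) stop("two_row_dart must have an even number of rows")
  ref_rows <- if (nrow(tab)) seq(1, nrow(tab), by = 2) else integer(0)
  snp_rows <- ref_rows + 1L
  if (length(ref_rows)) {
    if (!all(tab$locus_id[ref_rows] == tab$locus_id[snp_rows])) {
      stop("row pairs must share one locus_id")
    }
    if (!all(toupper(tab$allele[ref_rows]) == "REF") ||
        !all(toupper(tab$allele[snp_rows]) == "SNP")) {
      stop("each locus needs a REF row followed by a SNP row")
    }
  }
  score <- function(rows) {
    sc <- as.matrix(tab[rows, sample_ids, drop = FALSE])
    bad <- setdiff(unique(sc[sc != ""]), c("0", "1"))
    if (length(bad)) stop("unknown score token(s): ", paste(bad, collapse = ", "))
    sc
  }
  r <- score(ref_rows)
  s <- score(snp_rows)
  m <- matrix(NA_character_, length(ref_rows), length(sample_ids),
              dimnames = list(tab$locus_id[ref_rows], sample_ids))
  m[r == "1" & s == "0"] <- "REF_HOM"
  m[r == "0" & s == "1"] <- "ALT_HOM"
  m[r == "1" & s == "1"] <- "HET"
  # (0,0) and blank stay missing: an unsequenced locus is absent data for SNPs
  loci <- data.frame(locus_id = tab$locus_id[ref_rows],
                     marker_type = rep("SNP", length(ref_rows)),
                     stringsAsFactors = FALSE)
  if ("sequence" %in% names(tab)) {
    loci$ref_sequence <- ifelse(tab$sequence[ref_rows] == "", NA_character_,
                                tab$sequence[ref_rows])
    loci$alt_sequence <- ifelse(tab$sequence[snp_rows] == "", NA_character_,
                                tab$sequence[snp_rows])
  }
  genotype_dataset(m, loci, build_samples(sample_ids))
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]: the written file parses back to an
#' equal dataset under the same format.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path (`.csv` for comma-separated, else tab-separated).
#' @param format layout; `"two_row_dart"` and `"pa_matrix"` are restricted to
#'   SNP and PA datasets respectively, `"long"` handles both.
#' @param sep field separator override.
#' @return Invisibly, `path`.
#' @export
write_genotype_table <- function(dataset, path,
                                 format = c("two_row_dart", "pa_matrix", "long"),
                                 sep = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  format <- match.arg(format)
  sep <- .delim_for(path, sep)
  ids <- dataset$samples$sample_id

  if (format == "long") {
    calls <- dataset$calls
    out <- data.frame(
      locus_id = rep(dataset$loci$locus_id, times = length(ids)),
      sample_id = rep(ids, each = nrow(dataset$loci)),
      call = ifelse(is.na(as.vector(calls)), "NA", as.vector(calls)),
      stringsAsFactors = FALSE)
  } else if (format == "pa_matrix") {
    if (dataset$marker_type != "PA") stop("pa_matrix format requires a PA dataset")
    sc <- ifelse(is.na(dataset$calls), "",
                 ifelse(dataset$calls == "PRESENT", "1", "0"))
    out <- data.frame(locus_id = dataset$loci$locus_id,
                      sequence = ifelse(is.na(dataset$loci$ref_sequence), "",
                                        dataset$loci$ref_sequence),
                      stringsAsFactors = FALSE, check.names = FALSE)
    out <- cbind(out, as.data.frame(sc, stringsAsFactors = FALSE))
    names(out) <- c("locus_id", "sequence", ids)
  } else {
    if (dataset$marker_type != "SNP") stop("two_row_dart format requires a SNP dataset")
    n <- nrow(dataset$loci)
    ref_sc <- ifelse(is.na(dataset$calls), "",
                     ifelse(dataset$calls == "ALT_HOM", "0", "1"))
    snp_sc <- ifelse(is.na(dataset$calls), "",
                     ifelse(dataset$calls == "REF_HOM", "0", "1"))
    out <- data.frame(locus_id = rep(dataset$loci$locus_id, each = 2),
                      allele = rep(c("REF", "SNP"), n),
                      sequence = as.vector(rbind(
                        ifelse(is.na(dataset$loci$ref_sequence), "",
                               dataset$loci$ref_sequence),
                        ifelse(is.na(dataset$loci$alt_sequence), "",
                               dataset$loci$alt_sequence))),
                      stringsAsFactors = FALSE)
    sc <- matrix("", 2 * n, length(ids), dimnames = list(NULL, ids))
    if (n) {
      sc[seq(1, 2 * n, 2), ] <- ref_sc
      sc[seq(2, 2 * n, 2), ] <- snp_sc
    }
    out <- cbind(out, as.data.frame(sc, stringsAsFactors = FALSE,
                                    check.names = FALSE))
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table
#'
#' @param path CSV/TSV with columns `sample_id`, `sex`, and optionally
#'   `population`, `life_stage`, `replicate_group`.
#' @param sep field separator override.
#' @return Data frame with the five canonical sample columns.
#' @export
read_sample_table <- function(path, sep = NULL) {
  sep <- .delim_for(path, sep)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"))
  if (!all(c("sample_id", "sex") %in% names(tab))) {
    stop("sample table requires sample_id and sex columns")
  }
  tab$sex <- toupper(tab$sex)
  if (!"population" %in% names(tab)) tab$population <- NA_character_
  if (!"life_stage" %in% names(tab)) tab$life_stage <- "OTHER"
  tab$life_stage <- toupper(tab$life_stage)
  if (!"replicate_group" %in% names(tab)) tab$replicate_group <- NA_character_
  tab[, c("sample_id", "sex", "population", "life_stage", "replicate_group")]
}

#' Write a sample table
#' @param samples data frame of sample records (as in a [genotype_dataset()]).
#' @param path output path.
#' @param sep field separator override.
#' @return Invisibly, `path`.
#' @export
write_sample_table <- function(samples, path, sep = NULL) {
  utils::write.table(samples, path, sep = .delim_for(path, sep), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Collapse technical replicates to consensus samples
#'
#' Samples sharing a `replicate_group` label are merged into one consensus
#' sample named after the group: at each locus, if every non-missing replicate
#' call agrees that call passes through; a disagreement, or all replicates
#' missing, yields a missing consensus call. Scoring consistency across
#' replicate pairs is the usual DArT-style quality summary, reported here per
#' group and overall as the proportion of agreeing loci among loci where at
#' least two replicates are non-missing.
#'
#' @param dataset a [genotype_dataset()] with `replicate_group` set for at
#'   least one group of samples.
#' @return A list with `dataset` (replicates collapsed, other samples
#'   untouched) and `concordance`, a data frame with one row per group plus an
#'   `"overall"` row (`n_compared`, `n_agree`, `concordance`).
#' @export
collapse_replicates <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  grp <- dataset$samples$replicate_group
  groups <- unique(grp[!is.na(grp)])
  if (!length(groups)) stop("no replicate_group labels present")

  calls <- dataset$calls
  keep_order <- integer(0)
  new_cols <- list()
  new_samples <- list()
  conc <- data.frame(group = character(), n_compared = integer(),
                     n_agree = integer(), stringsAsFactors = FALSE)
  consumed <- rep(FALSE, ncol(calls))

  for (j in seq_len(ncol(calls))) {
    if (consumed[j]) next
    g <- grp[j]
    if (is.na(g)) {
      new_cols[[length(new_cols) + 1L]] <- calls[, j]
      new_samples[[length(new_samples) + 1L]] <- dataset$samples[j, , drop = FALSE]
      next
    }
    members <- which(!is.na(grp) & grp == g)
    consumed[members] <- TRUE
    sub <- calls[, members, drop = FALSE]
    n_nm <- rowSums(!is.na(sub))
    # number of distinct non-missing calls per locus
    n_distinct <- apply(sub, 1L, function(r) length(unique(r[!is.na(r)])))
    consensus <- rep(NA_character_, nrow(sub))
    ok <- n_nm >= 1L & n_distinct == 1L
    consensus[ok] <- apply(sub[ok, , drop = FALSE], 1L,
                           function(r) r[!is.na(r)][1L])
    compared <- n_nm >= 2L
    conc <- rbind(conc, data.frame(group = g,
                                   n_compared = sum(compared),
                                   n_agree = sum(compared & n_distinct == 1L),
                                   stringsAsFactors = FALSE))
    rec <- dataset$samples[members[1L], , drop = FALSE]
    rec$sample_id <- g
    rec$replicate_group <- NA_character_
    new_cols[[length(new_cols) + 1L]] <- consensus
    new_samples[[length(new_samples) + 1L]] <- rec
  }

  conc <- rbind(conc, data.frame(group = "overall",
                                 n_compared = sum(conc$n_compared),
                                 n_agree = sum(conc$n_agree),
                                 stringsAsFactors = FALSE))
  conc$concordance <- ifelse(conc$n_compared > 0,
                             conc$n_agree / conc$n_compared, NA_real_)
  m <- do.call(cbind, new_cols)
  samples <- do.call(rbind, new_samples)
  rownames(samples) <- NULL
  list(dataset = genotype_dataset(m, dataset$loci, samples),
       concordance = conc)
}
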