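# Evaluation of OTU partitions against known species composition:
# overmerging, percentage of expected OTUs, oversplitting, improvement
# over a fixed cut-off, species loss, and cross-amplicon concordance.

#' Percentage of expected OTUs retrieved
#'
#' With one reference sequence per species, a perfect clustering returns
#' one OTU per species; this reports `100 * n_otus / n_species`.
#'
#' @param n_species Ground-truth number of distinct species.
#' @param n_otus Number of OTUs obtained.
#' @return Percentage.
#' @export
pct_expected_otus <- function(n_species, n_otus) {
  if (n_species <= 0) stop("n_species must be positive")
  100 * n_otus / n_species
}

#' Overmerging percentage
#'
#' The fraction of species erroneously merged into an already-occupied
#' OTU: `100 * (n_species - n_otus) / n_species`, the complement of
#' [pct_expected_otus()]. Valid when each species contributes one
#' reference sequence, so `n_otus <= n_species`.
#'
#' @inheritParams pct_expected_otus
#' @return Percentage in \[0, 100\].
#' @export
overmerging_pct <- function(n_species, n_otus) {
  if (n_species <= 0) stop("n_species must be positive")
  if (n_otus > n_species) {
    stop("n_otus (", n_otus, ") exceeds n_species (", n_species,
         "); overmerging assumes one sequence per species")
  }
  100 * (n_species - n_otus) / n_species
}

#' Oversplitting percentage
#'
#' Reads of one species spread over several OTUs. Each species occupying
#' k > 1 OTUs contributes k - 1 surplus OTUs (an OTU is counted once per
#' species it contains); the result is `100 * surplus / total OTUs`.
#'
#' @param partition An `OTUPartition` over reads.
#' @param truth Named character vector mapping every clustered read id to
#'   its true species.
#' @return Percentage.
#' @export
oversplitting_pct <- function(partition, truth) {
  reads <- unlist(partition$otus, use.names = FALSE)
  if (!all(reads %in% names(truth))) {
    stop("truth does not cover all clustered reads")
  }
  otu_of <- rep(names(partition$otus), lengths(partition$otus))
  names(otu_of) <- reads
  per_species <- tapply(otu_of, truth[reads],
                        function(o) length(unique(o)))
  surplus <- sum(pmax(0L, per_species - 1L))
  100 * surplus / length(partition$otus)
}

#' Improvement of dynamic clustering over a fixed cut-off
#'
#' `100 * (n_otus_dynamic - n_otus_default) / n_species_correct`: positive
#' when the dynamic cut-offs recover more of the true species than the
#' fixed default.
#'
#' @param n_otus_dynamic OTUs under the dynamic lookup.
#' @param n_otus_default OTUs under the fixed default cut-off.
#' @param n_species_correct Correct number of species.
#' @return Percentage (may be negative).
#' @export
improvement_pct <- function(n_otus_dynamic, n_otus_default,
                            n_species_correct) {
  if (n_species_correct <= 0) stop("n_species_correct must be positive")
  100 * (n_otus_dynamic - n_otus_default) / n_species_correct
}

#' Species lost to overmerging in one sample
#'
#' Detectable species (those with at least one surviving read) minus the
#' number of OTUs, floored at zero: how many species the clustering could
#' not resolve.
#'
#' @inheritParams oversplitting_pct
#' @return Non-negative integer.
#' @export
species_loss <- function(partition, truth) {
  reads <- unlist(partition$otus, use.names = FALSE)
  if (!all(reads %in% names(truth))) {
    stop("truth does not cover all clustered reads")
  }
  detectable <- length(unique(truth[reads]))
  max(0L, detectable - length(partition$otus))
}

#' Evaluation report for one clustering run
#'
#' @param n_species Ground-truth species count.
#' @param n_otus OTUs under the evaluated (dynamic) clustering.
#' @param n_otus_default Optional OTUs under the fixed default cut-off,
#'   enabling the improvement column.
#' @param partition,truth Optional partition + truth for the
#'   oversplitting column.
#' @return One-row data.frame with columns `n_species`, `n_otus`,
#'   `pct_expected`, `overmerge_pct`, and where computable
#'   `oversplit_pct` and `improvement_pct`.
#' @export
eval_report <- function(n_species, n_otus, n_otus_default = NULL,
                        partition = NULL, truth = NULL) {
  out <- data.frame(
    n_species = n_species,
    n_otus = n_otus,
    pct_expected = pct_expected_otus(n_species, n_otus),
    overmerge_pct = overmerging_pct(n_species, n_otus))
  out$oversplit_pct <- if (!is.null(partition) && !is.null(truth)) {
    oversplitting_pct(partition, truth)
  } else NA_real_
  out$improvement_pct <- if (!is.null(n_otus_default)) {
    improvement_pct(n_otus, n_otus_default, n_species)
  } else NA_real_
  out
}

#' Cross-amplicon OTU-count concordance
#'
#' Compares the number of OTUs one sample yields under different amplicons:
#' emits every amplicon pair per sample (long form) plus the per-sample
#' standard deviation (n - 1 denominator) of counts across amplicons.
#' Samples with a missing count are skipped with a warning.
#'
#' @param counts Numeric matrix or data.frame, one row per sample, one
#'   column per amplicon, of OTU counts.
#' @return List with `pairs` (data.frame `sample`, `amplicon_a`,
#'   `amplicon_b`, `otus_a`, `otus_b`) and `sd` (named per-sample standard
#'   deviations).
#' @export
amplicon_concordance <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need >= 2 amplicons")
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("amplicon", seq_len(ncol(counts)))
  }
  incomplete <- apply(counts, 1L, anyNA)
  if (any(incomplete)) {
    warning("skipping sample(s) with missing counts: ",
            paste(rownames(counts)[incomplete], collapse = ", "))
    counts <- counts[!incomplete, , drop = FALSE]
  }
  combos <- utils::combn(colnames(counts), 2L)
  pairs <- do.call(rbind, lapply(rownames(counts), function(s) {
    data.frame(sample = s,
               amplicon_a = combos[1L, ],
               amplicon_b = combos[2L, ],
               otus_a = counts[s, combos[1L, ]],
               otus_b = counts[s, combos[2L, ]],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(pairs = pairs, sd = apply(counts, 1L, stats::sd))
}
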