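# Per-column conservation profiling of family alignments.
#
# Each alignment column is scored in bits: 2 - Shannon entropy of its
# nucleotide frequencies, so 2 marks a fully conserved position and 0 a
# maximally variable one. Frequencies are computed over non-gap A/C/G/T
# residues only (N and ambiguity codes are excluded); columns with no
# residue coverage in a family carry NA rather than a score.

# Split aligned strings into a residues-by-columns character matrix.
seq_char_matrix <- function(seqs) {
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE,
         dimnames = list(names(seqs), NULL))
}

#' Nucleotide frequencies of one alignment column
#'
#' @param family_seqs Named character vector of aligned sequences (one
#'   family).
#' @param column_index 1-based column, in `[1, W]`.
#' @return Numeric vector of frequencies over A, C, G, T summing to 1, with
#'   attribute `coverage` (count of non-gap A/C/G/T residues). For an
#'   all-gap column the frequencies are NA and coverage is 0.
#' @export
column_frequencies <- function(family_seqs, column_index) {
  w <- nchar(family_seqs[1L])
  if (column_index < 1L || column_index > w) {
    stop("column_index ", column_index, " outside [1, ", w, "]")
  }
  col <- substr(family_seqs, column_index, column_index)
  counts <- vapply(c("A", "C", "G", "T"), function(b) sum(col == b),
                   numeric(1))
  cov <- sum(counts)
  freqs <- if (cov > 0) counts / cov else rep(NA_real_, 4L)
  names(freqs) <- c("A", "C", "G", "T")
  attr(freqs, "coverage") <- cov
  freqs
}

#' Conservation bit-score profile of a family alignment
#'
#' Scores every alignment column as `2 + sum_b q_b log2 q_b` (with
#' `0 log 0 := 0`), i.e. 2 minus the column's Shannon entropy in bits,
#' where `q_b` is the frequency of nucleotide `b` among the column's
#' non-gap residues.
#'
#' @param family_seqs Named character vector of aligned sequences.
#' @param family Optional family label carried on the profile.
#' @return An object of class `ConservationProfile`: list with `family`,
#'   `scores` (length-W numeric in \[0, 2\], NA where the column has no
#'   residue coverage), `coverage` (per-column residue counts) and `W`.
#' @export
bit_score_profile <- function(family_seqs, family = NULL) {
  stopifnot(length(family_seqs) >= 1L)
  w <- unique(nchar(family_seqs))
  if (length(w) != 1L) stop("sequences differ in width")
  m <- seq_char_matrix(family_seqs)
  scores <- numeric(w)
  coverage <- integer(w)
  for (b in c("A", "C", "G", "T")) {
    coverage <- coverage + colSums(m == b)
  }
  for (j in seq_len(w)) {
    if (coverage[j] == 0L) {
      scores[j] <- NA_real_
      next
    }
    counts <- c(sum(m[, j] == "A"), sum(m[, j] == "C"),
                sum(m[, j] == "G"), sum(m[, j] == "T"))
    q <- counts[counts > 0] / coverage[j]
    scores[j] <- 2 + sum(q * log2(q))
  }
  structure(list(family = family, scores = scores, coverage = coverage,
                 W = w),
            class = "ConservationProfile")
}

#' @export
print.ConservationProfile <- function(x, ...) {
  cat("ConservationProfile", if (!is.null(x$family)) paste0("[", x$family, "]"),
      ": W =", x$W, ", mean score",
      format(mean(x$scores, na.rm = TRUE), digits = 4), "\n")
  invisible(x)
}

#' Alignment-wide mean conservation score
#'
#' The per-alignment summary `2 - (1/W) sum_l H_l`, averaging the
#' per-column scores over covered columns.
#'
#' @param profile A [bit_score_profile()].
#' @return Single numeric in \[0, 2\].
#' @export
mean_bit_score <- function(profile) {
  mean(profile$scores, na.rm = TRUE)
}

#' Moving-average smoothing of a conservation profile
#'
#' Averages scores over a sliding window (default 30 nt, the width used for
#' the per-family conservation plots). Edge windows are truncated to the
#' available columns so the output length equals W; NA (uncovered) columns
#' are dropped from the window average and stay NA in the output.
#'
#' @param profile A `ConservationProfile`.
#' @param window Window width in columns (default 30).
#' @return A smoothed `ConservationProfile`.
#' @export
smoothed_profile <- function(profile, window = 30L) {
  stopifnot(window >= 1L)
  w <- profile$W
  if (window > w) stop("window (", window, ") exceeds profile width (", w, ")")
  left <- floor((window - 1L) / 2L)
  right <- floor(window / 2L)
  s <- profile$scores
  out <- vapply(seq_len(w), function(i) {
    win <- s[max(1L, i - left):min(w, i + right)]
    if (is.na(s[i]) || all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
  structure(list(family = profile$family, scores = out,
                 coverage = profile$coverage, W = w),
            class = "ConservationProfile")
}

#' Bit-score complement
#'
#' Replaces every score by `2 - score`, so high values mark variable
#' positions; applying it twice restores the original profile.
#'
#' @param profile A `ConservationProfile`.
#' @return A `ConservationProfile` of complements.
#' @export
complement_profile <- function(profile) {
  structure(list(family = profile$family, scores = 2 - profile$scores,
                 coverage = profile$coverage, W = profile$W),
            class = "ConservationProfile")
}

#' Families-by-positions conservation matrix
#'
#' Computes the bit-score profile of every family in the database and
#' stacks them into a families x positions matrix, the data behind a
#' conservation heatmap. Cells where a family has no residue coverage at a
#' position are NA (rendered black / "not covered" in heatmaps).
#'
#' @param db A filtered [reference_db()].
#' @return Numeric matrix, one row per family, one column per alignment
#'   position, values in \[0, 2\] or NA.
#' @export
heatmap_matrix <- function(db) {
  fams <- names(db$family_index)
  m <- matrix(NA_real_, nrow = length(fams), ncol = db$alignment_width,
              dimnames = list(fams, as.character(seq_len(db$alignment_width))))
  for (fam in fams) {
    m[fam, ] <- bit_score_profile(db$seqs[db$family_index[[fam]]],
                                  family = fam)$scores
  }
  m
}

#' Write a conservation matrix as TSV
#'
#' Header row of 1-based positions, one row per family, `NA` for positions
#' without coverage.
#'
#' @param mat A [heatmap_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_heatmap_tsv <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     col.names = NA, na = "NA")
  invisible(path)
}
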