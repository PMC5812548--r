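# Pairwise one-gap distances on aligned sequences and average-neighbor
# (average-linkage) agglomerative clustering into OTUs.

# Core distance on integer-encoded columns (see encode_aligned).
onegap_core <- function(ea, eb, count_ends = TRUE) {
  if (!count_ends) {
    nza <- which(ea != 0L)
    nzb <- which(eb != 0L)
    if (!length(nza) || !length(nzb)) stop("zero compared positions")
    lo <- max(nza[1L], nzb[1L])
    hi <- min(nza[length(nza)], nzb[length(nzb)])
    if (lo > hi) stop("zero compared positions")
    ea <- ea[lo:hi]
    eb <- eb[lo:hi]
  }
  # skip columns where both are gapped, and columns with N/ambiguity codes
  keep <- !(ea == 0L & eb == 0L) & ea != 5L & eb != 5L
  ea <- ea[keep]
  eb <- eb[keep]
  if (!length(ea)) stop("zero compared positions")
  gap <- ea == 0L | eb == 0L # exactly one of the two gapped, after filtering
  n_runs <- if (any(gap)) {
    r <- rle(gap)
    sum(r$values)
  } else 0L
  base <- !gap
  diffs <- sum(ea[base] != eb[base]) + n_runs
  positions <- sum(base) + n_runs
  diffs / positions
}

#' One-gap pairwise distance between two aligned sequences
#'
#' The distance used throughout: columns where both sequences are gapped
#' are skipped; a maximal run of columns where exactly one sequence is
#' gapped counts as a single difference over a single compared position
#' (an indel of any length is one event); base-base columns contribute one
#' compared position each, a difference when the bases mismatch. Columns
#' containing N or another ambiguity code in either sequence are excluded.
#' The distance is differences / compared positions. With
#' `count_ends = FALSE`, leading and trailing gap overhangs are skipped
#' entirely.
#'
#' @param a,b Aligned sequences of equal width (gapped strings).
#' @param count_ends Count terminal gap runs as differences (default TRUE,
#'   the usual default of one-gap distance calculators).
#' @return Distance in \[0, 1\].
#' @export
onegap_distance <- function(a, b, count_ends = TRUE) {
  if (nchar(a) != nchar(b)) {
    stop("sequences differ in width: ", nchar(a), " vs ", nchar(b))
  }
  onegap_core(encode_aligned(normalize_residues(a)),
              encode_aligned(normalize_residues(b)),
              count_ends)
}

#' All pairwise one-gap distances
#'
#' @param seqs Named character vector of >= 2 aligned sequences of one
#'   width.
#' @param count_ends Passed to [onegap_distance()].
#' @return An object of class `DistanceMatrix`: list with `ids` (sorted
#'   seq_ids) and `d`, the symmetric distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(seqs, count_ends = TRUE) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  ids <- sort(names(seqs))
  seqs <- normalize_residues(seqs[ids])
  enc <- lapply(seqs, encode_aligned)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- tryCatch(onegap_core(enc[[i]], enc[[j]], count_ends),
                      error = function(e) {
                        stop("pair ", ids[i], " / ", ids[j], ": ",
                             conditionMessage(e))
                      })
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  structure(list(ids = ids, d = d), class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat("DistanceMatrix:", length(x$ids), "sequences\n")
  invisible(x)
}

#' Write a distance matrix as 3-column TSV
#'
#' Column (phylip-free) dialect: `id1<TAB>id2<TAB>distance`, one line per
#' unordered pair.
#'
#' @param dm A [pairwise_distances()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_tsv <- function(dm, path) {
  n <- length(dm$ids)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cat(dm$ids[i], dm$ids[j], format(dm$d[i, j], digits = 10),
          sep = "\t", file = con)
      cat("\n", file = con)
    }
  }
  invisible(path)
}

# Construct an OTUPartition from a list of member-id vectors.
# Clusters are ordered by their smallest member id; OTU ids are zero-padded.
make_partition <- function(member_list, cutoff, prefix = "OTU") {
  member_list <- lapply(member_list, sort)
  ord <- order(vapply(member_list, `[[`, character(1), 1L))
  member_list <- member_list[ord]
  width <- max(3L, nchar(length(member_list)))
  names(member_list) <- sprintf("%s%0*d", prefix, width,
                                seq_along(member_list))
  structure(list(cutoff = cutoff, otus = member_list),
            class = "OTUPartition")
}

#' @export
print.OTUPartition <- function(x, ...) {
  cat("OTUPartition:", length(x$otus), "OTUs over",
      sum(lengths(x$otus)), "sequences at cutoff",
      format(x$cutoff), "\n")
  invisible(x)
}

#' Number of OTUs in a partition
#'
#' @param partition An `OTUPartition`.
#' @return Integer count.
#' @export
n_otus <- function(partition) length(partition$otus)

#' Average-neighbor clustering of a distance matrix
#'
#' Agglomerative average-linkage clustering: repeatedly merge the pair of
#' clusters with the smallest mean inter-cluster distance (arithmetic mean
#' over all cross-pairs) while that mean does not exceed the cut-off. When
#' two pairs tie on the minimal mean, the pair whose smallest member seq_id
#' sorts first is merged, making the partition independent of input order.
#'
#' @param dm A [pairwise_distances()] result.
#' @param cutoff Distance cut-off in \[0, 1\].
#' @return An `OTUPartition` (list with `cutoff` and `otus`, a named list
#'   of member-id vectors partitioning the ids).
#' @export
average_neighbor_cluster <- function(dm, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  ids <- dm$ids
  n <- length(ids)
  if (n == 1L) return(make_partition(list(ids), cutoff))
  eps <- 1e-12
  S <- dm$d                     # sums of cross-pair distances
  sizes <- rep(1L, n)
  members <- as.list(ids)
  minid <- ids                  # smallest member id per cluster
  active <- rep(TRUE, n)
  repeat {
    act <- which(active)
    if (length(act) < 2L) break
    means <- S[act, act, drop = FALSE] /
      tcrossprod(as.numeric(sizes[act]))
    means[!upper.tri(means)] <- Inf
    m <- min(means)
    if (m > cutoff + eps) break
    cand <- which(means <= m + eps, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      # tie rule: lexicographic on the sorted pair of cluster min-ids
      keys <- apply(cand, 1L, function(rc) {
        paste(sort(c(minid[act[rc[1L]]], minid[act[rc[2L]]])),
              collapse = "\r")
      })
      cand <- cand[order(keys)[1L], , drop = FALSE]
    }
    i <- act[cand[1L, 1L]]
    j <- act[cand[1L, 2L]]
    S[i, ] <- S[i, ] + S[j, ]
    S[, i] <- S[i, ]
    S[i, i] <- 0
    sizes[i] <- sizes[i] + sizes[j]
    members[[i]] <- c(members[[i]], members[[j]])
    minid[i] <- min(minid[i], minid[j])
    active[j] <- FALSE
  }
  make_partition(members[active], cutoff)
}

#' Write an OTU partition in mothur list dialect
#'
#' One line: `label<TAB>numOtus<TAB>memberA,memberB<TAB>...`.
#'
#' @param partition An `OTUPartition`.
#' @param path Output path.
#' @param label Cut-off label; defaults to the partition's cutoff.
#' @return Invisibly, `path`.
#' @export
write_otu_list <- function(partition, path, label = NULL) {
  if (is.null(label)) label <- format(partition$cutoff)
  line <- paste(c(label, length(partition$otus),
                  vapply(partition$otus, paste, character(1),
                         collapse = ",")),
                collapse = "\t")
  writeLines(line, path)
  invisible(path)
}

#' Write an OTU partition as long-form TSV
#'
#' Two columns, `otu_id<TAB>seq_id`, one row per member.
#'
#' @param partition An `OTUPartition`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_otu_long <- function(partition, path) {
  df <- data.frame(
    otu_id = rep(names(partition$otus), lengths(partition$otus)),
    seq_id = unlist(partition$otus, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
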