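#' Reference databases of aligned type-strain sequences
#'
#' A `ReferenceDB` holds a globally aligned set of 16S rRNA sequences (one
#' type strain, hence one gene copy, per species) together with their
#' taxonomic lineages and a family index. It is the container consumed by
#' conservation profiling, amplicon extraction, cut-off training and the
#' synthetic-data generator.
#'
#' @param seqs Named character vector of gapped sequences, all of one width.
#' @param taxonomy A data.frame as returned by [read_taxonomy()] covering
#'   every id in `seqs`.
#' @return An object of class `ReferenceDB` with elements `ids`, `seqs`,
#'   `taxonomy`, `alignment_width` and `family_index` (named list mapping
#'   family name to member seq_ids; sequences without a family label are
#'   indexed under `"unclassified"`).
#' @export
reference_db <- function(seqs, taxonomy) {
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequences must carry unique names")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    main_w <- widths[1L]
    off <- ids[widths != main_w]
    stop("ragged alignment: expected width ", main_w, " but ",
         paste0(off, " has width ", widths[widths != main_w],
                collapse = "; "))
  }
  missing <- setdiff(ids, taxonomy$seq_id)
  if (length(missing)) {
    stop("sequence id(s) missing from taxonomy: ",
         paste(missing, collapse = ", "))
  }
  taxonomy <- taxonomy[match(ids, taxonomy$seq_id), , drop = FALSE]
  rownames(taxonomy) <- NULL
  fam <- taxonomy$family
  fam[is.na(fam) | !nzchar(fam)] <- "unclassified"
  db <- structure(
    list(ids = ids,
         seqs = seqs,
         taxonomy = taxonomy,
         alignment_width = if (length(seqs)) unname(widths[1L]) else 0L,
         family_index = split(ids, fam)),
    class = "ReferenceDB")
  db
}

#' @export
print.ReferenceDB <- function(x, ...) {
  cat("ReferenceDB:", length(x$ids), "sequences,",
      length(x$family_index), "families, alignment width",
      x$alignment_width, "\n")
  invisible(x)
}

#' @export
length.ReferenceDB <- function(x) length(x$ids)

# Subset a ReferenceDB to a set of ids, preserving the original order.
subset_db <- function(db, ids) {
  keep <- db$ids[db$ids %in% ids]
  reference_db(db$seqs[keep], db$taxonomy[db$taxonomy$seq_id %in% keep, ,
                                          drop = FALSE])
}

#' Load a reference database from aligned FASTA + taxonomy
#'
#' @param aligned_fasta_path Aligned (uniform-width) FASTA of the reference
#'   sequences; `U` is normalized to `T` and both `-` and `.` are gaps.
#' @param taxonomy_path Taxonomy file mapping every FASTA id to a lineage
#'   (see [read_taxonomy()]).
#' @return A [reference_db()] object. The `species` column of the taxonomy
#'   (seventh lineage field) is used as the species name where present;
#'   otherwise the sequence id stands in, which is adequate for
#'   one-type-strain-per-species references.
#' @export
load_reference <- function(aligned_fasta_path, taxonomy_path) {
  seqs <- read_aligned_fasta(aligned_fasta_path)
  tax <- read_taxonomy(taxonomy_path)
  blank <- !nzchar(tax$species)
  tax$species[blank] <- tax$seq_id[blank]
  reference_db(seqs, tax)
}

#' Drop small and unclassifiable families
#'
#' Retains only families with at least `min_species` members, optionally
#' removing families whose name marks a pending or unresolved
#' classification. Type-strain references index one sequence per species,
#' so family size counts species.
#'
#' @param db A [reference_db()].
#' @param min_species Minimum family size to retain (default 3).
#' @param drop_unclassified Drop families whose name matches
#'   `unclassified_patterns` (default TRUE).
#' @param unclassified_patterns Case-insensitive substrings marking pending
#'   classification.
#' @return A filtered `ReferenceDB` (possibly empty).
#' @export
filter_families <- function(db, min_species = 3L, drop_unclassified = TRUE,
                            unclassified_patterns = c("unclassified",
                                                      "incertae sedis")) {
  sizes <- lengths(db$family_index)
  keep_fams <- names(sizes)[sizes >= min_species]
  if (drop_unclassified && length(keep_fams)) {
    bad <- Reduce(`|`, lapply(unclassified_patterns, function(p) {
      grepl(p, keep_fams, ignore.case = TRUE, fixed = FALSE)
    }))
    keep_fams <- keep_fams[!bad]
  }
  ids <- unlist(db$family_index[keep_fams], use.names = FALSE)
  if (!length(ids)) {
    return(reference_db(db$seqs[0], db$taxonomy[0, , drop = FALSE]))
  }
  subset_db(db, ids)
}

#' Curate a reference to one representative per within-cut-off group
#'
#' Within each family, clusters the sequences at the given cut-off (on the
#' full-length alignment or a specified amplicon) and keeps exactly one
#' representative per cluster: the lexicographically smallest seq_id, so the
#' result does not depend on database order. Re-clustering a curated
#' database at the same cut-off then yields one OTU per retained sequence.
#'
#' @param db A [reference_db()].
#' @param cutoff Distance cut-off in \[0, 1\] used to define "too similar".
#' @param spec Optional [amplicon_spec()] on which similarity is judged;
#'   defaults to the full-length alignment.
#' @param region_map Region map used to resolve region-range specs.
#' @return A curated `ReferenceDB` (full-length sequences of the retained
#'   representatives).
#' @export
curate_database <- function(db, cutoff, spec = NULL, region_map = NULL) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  view <- if (is.null(spec) || identical(spec$kind, "full-length")) {
    db
  } else {
    extract_amplicon(db, spec, region_map)
  }
  keep <- character(0)
  for (fam in names(view$family_index)) {
    ids <- view$family_index[[fam]]
    if (length(ids) == 1L) {
      keep <- c(keep, ids)
      next
    }
    dm <- pairwise_distances(view$seqs[ids])
    part <- average_neighbor_cluster(dm, cutoff)
    keep <- c(keep, vapply(part$otus, function(m) sort(m)[1L], character(1)))
  }
  # sequences dropped during amplicon extraction never compete; keep them out
  subset_db(db, keep)
}

#' Randomly subsample each family to a maximum size
#'
#' @param db A [reference_db()].
#' @param max_species Maximum family size after subsampling (default 7).
#' @param seed Integer seed; the draw is uniform without replacement and
#'   reproducible for a fixed seed.
#' @return A subsampled `ReferenceDB`.
#' @export
subsample_families <- function(db, max_species = 7L, seed) {
  stopifnot(max_species >= 1L)
  ids <- with_seed(seed, {
    unlist(lapply(names(db$family_index), function(fam) {
      members <- db$family_index[[fam]]
      if (length(members) <= max_species) members
      else sample(members, max_species)
    }), use.names = FALSE)
  })
  subset_db(db, ids)
}
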