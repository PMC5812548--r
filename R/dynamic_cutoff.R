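# Lookup-table training and taxonomy-aware dynamic OTU clustering.
#
# Training: per taxon (default family), extract the amplicon from the
# reference alignment, compute all pairwise one-gap distances, take the
# lower 2.5th-percentile distance as that taxon's clustering cut-off, and
# clamp it into [1%, 3%]. Execution: group reads by assigned taxon and
# cluster each group at its trained cut-off; unclassified reads and reads
# of taxa absent from the table fall back to the default cut-off.

# Nearest-rank lower percentile of a distance multiset: the ceil(p/100*n)-th
# order statistic (1-based) of the ascending sort.
nearest_rank_percentile <- function(x, p) {
  x <- sort(x)
  idx <- max(1L, ceiling(p / 100 * length(x)))
  x[idx]
}

#' Train a per-taxon cut-off lookup table for an amplicon
#'
#' For every taxon at the chosen rank: the amplicon fragment is extracted
#' from each member sequence, all pairwise one-gap distances are computed
#' and ordered, and the distance at the lower `percentile` (nearest-rank by
#' default; treating the smallest distances as within-species outliers) is
#' taken as the taxon's cut-off, clamped into `[clamp[1], clamp[2]]`. Taxa
#' left with fewer than two usable fragments are omitted with a warning.
#'
#' @param db A filtered [reference_db()] (>= 3 species per taxon is the
#'   intended regime; smaller taxa still train but on very few pairs).
#' @param spec An [amplicon_spec][amplicon_region_range].
#' @param percentile Lower percentile of the ordered distances (default
#'   2.5).
#' @param clamp Length-2 numeric, the cut-off floor and ceiling (default
#'   `c(0.01, 0.03)`, i.e. 1% and 3%).
#' @param level Taxonomic rank keying the table (default `"family"`; any
#'   of domain ... genus).
#' @param region_map Region map for resolving region-range specs.
#' @param default_cutoff Cut-off used at execution time for taxa absent
#'   from the table and for unclassified reads (default 0.03, i.e. 97%
#'   similarity).
#' @param interpolate Use linear interpolation (type-7 quantile) instead of
#'   the nearest-rank order statistic (default FALSE).
#' @param count_ends Passed to [onegap_distance()].
#' @return An object of class `LookupTable`: list with `level`, `amplicon`,
#'   `amplicon_width`, `percentile`, `clamp`, `default_cutoff` and `rows`,
#'   a data.frame with columns `taxon`, `n_species`, `n_pairs`,
#'   `raw_percentile_distance`, `cutoff`.
#' @export
train_lookup <- function(db, spec, percentile = 2.5,
                         clamp = c(0.01, 0.03), level = "family",
                         region_map = NULL, default_cutoff = 0.03,
                         interpolate = FALSE, count_ends = TRUE) {
  if (!length(db$ids)) stop("empty reference database")
  stopifnot(length(clamp) == 2L, clamp[1L] <= clamp[2L],
            level %in% RANKS)
  view <- extract_amplicon(db, spec, region_map)
  lab <- view$taxonomy[[level]]
  lab[is.na(lab) | !nzchar(lab)] <- "unclassified"
  groups <- split(view$ids, lab)
  rows <- lapply(sort(names(groups)), function(taxon) {
    ids <- groups[[taxon]]
    if (length(ids) < 2L) {
      warning("taxon ", taxon,
              " has < 2 usable fragments after extraction; omitted")
      return(NULL)
    }
    dm <- pairwise_distances(view$seqs[ids], count_ends = count_ends)
    dists <- dm$d[upper.tri(dm$d)]
    raw <- if (interpolate) {
      unname(stats::quantile(dists, percentile / 100, type = 7))
    } else {
      nearest_rank_percentile(dists, percentile)
    }
    data.frame(taxon = taxon,
               n_species = length(ids),
               n_pairs = length(dists),
               raw_percentile_distance = raw,
               cutoff = min(max(raw, clamp[1L]), clamp[2L]),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(taxon = character(0), n_species = integer(0),
                       n_pairs = integer(0),
                       raw_percentile_distance = numeric(0),
                       cutoff = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(rows) <- NULL
  structure(list(level = level, amplicon = spec,
                 amplicon_width = view$alignment_width,
                 percentile = percentile, clamp = clamp,
                 default_cutoff = default_cutoff, rows = rows),
            class = "LookupTable")
}

#' @export
print.LookupTable <- function(x, ...) {
  cat("LookupTable (", x$level, ", amplicon ", format(x$amplicon), "): ",
      nrow(x$rows), " taxa, cutoffs in [",
      format(x$clamp[1L]), ", ", format(x$clamp[2L]),
      "], default ", format(x$default_cutoff), "\n", sep = "")
  invisible(x)
}

#' Write / read a lookup table as TSV
#'
#' The file carries a `#key value` metadata header block (level, amplicon,
#' amplicon_width, percentile, clamp, default_cutoff) followed by a header
#' line and one row per taxon.
#'
#' @param lookup A [train_lookup()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lookup <- function(lookup, path) {
  meta <- c(paste("#level", lookup$level),
            paste("#amplicon", format(lookup$amplicon)),
            paste("#amplicon_width", lookup$amplicon_width),
            paste("#percentile", format(lookup$percentile)),
            paste("#clamp", paste(format(lookup$clamp), collapse = ":")),
            paste("#default_cutoff", format(lookup$default_cutoff)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(c("taxon", "n_species", "n_pairs", "raw_percentile",
                     "cutoff"), collapse = "\t"), con)
  if (nrow(lookup$rows)) {
    utils::write.table(lookup$rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_lookup
#' @export
read_lookup <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- strsplit(sub("^#", "", m), " ", fixed = TRUE)[[1L]]
    meta[[kv[1L]]] <- paste(kv[-1L], collapse = " ")
  }
  body <- lines[!grepl("^#", lines)]
  rows <- if (length(body) > 1L) {
    utils::read.delim(text = body, stringsAsFactors = FALSE)
  } else {
    data.frame(taxon = character(0), n_species = integer(0),
               n_pairs = integer(0), raw_percentile = numeric(0),
               cutoff = numeric(0), stringsAsFactors = FALSE)
  }
  names(rows) <- c("taxon", "n_species", "n_pairs",
                   "raw_percentile_distance", "cutoff")
  clamp <- as.numeric(strsplit(meta$clamp, ":", fixed = TRUE)[[1L]])
  structure(list(level = meta$level,
                 amplicon = parse_amplicon(meta$amplicon),
                 amplicon_width = as.integer(meta$amplicon_width),
                 percentile = as.numeric(meta$percentile),
                 clamp = clamp,
                 default_cutoff = as.numeric(meta$default_cutoff),
                 rows = rows),
            class = "LookupTable")
}

#' Assign reads to taxa from a classification with confidences
#'
#' A read joins the taxon named at `level` in its lineage when that label
#' is non-empty, not literally "unclassified", and its bootstrap confidence
#' (where printed) reaches `confidence_threshold`; otherwise it enters the
#' unclassified bucket. Classifications without confidences assign all
#' labelled reads.
#'
#' @param taxonomy Path to a taxonomy file, or a data.frame from
#'   [read_taxonomy()].
#' @param level Rank to group by (default `"family"`).
#' @param confidence_threshold Minimum bootstrap confidence in percent
#'   (default 80).
#' @param read_ids Optional full roster of read ids; reads missing from the
#'   taxonomy are placed in the unclassified bucket with a warning.
#' @return List with `assignments` (named list taxon -> read ids),
#'   `unclassified` (read ids) and `unclassified_fraction`.
#' @export
assign_taxa <- function(taxonomy, level = "family",
                        confidence_threshold = 80, read_ids = NULL) {
  tax <- if (is.character(taxonomy)) read_taxonomy(taxonomy) else taxonomy
  if (!is.null(read_ids)) {
    missing <- setdiff(read_ids, tax$seq_id)
    if (length(missing)) {
      warning(length(missing), " read(s) missing from taxonomy; ",
              "treated as unclassified")
    }
    tax <- tax[tax$seq_id %in% read_ids, , drop = FALSE]
  } else {
    missing <- character(0)
  }
  lab <- tax[[level]]
  conf <- tax[[paste0(level, "_conf")]]
  ok <- !is.na(lab) & nzchar(lab) &
    !grepl("^unclassified", lab, ignore.case = TRUE) &
    (is.na(conf) | conf >= confidence_threshold)
  assignments <- split(tax$seq_id[ok], lab[ok])
  unclassified <- c(tax$seq_id[!ok], missing)
  total <- nrow(tax) + length(missing)
  list(assignments = assignments,
       unclassified = unclassified,
       unclassified_fraction = if (total) length(unclassified) / total else 0)
}

#' Cluster reads into OTUs with taxon-dependent cut-offs
#'
#' For each taxon present in the lookup table, its reads are clustered by
#' [average_neighbor_cluster()] at that taxon's trained cut-off. Reads of
#' taxa absent from the table (novel families) and unclassified reads are
#' clustered at the table's default cut-off — the unclassified bucket as a
#' single pooled group. OTU ids are globally unique, prefixed by taxon.
#'
#' @param reads Named character vector of reads aligned to the same
#'   coordinate system (and width) as the lookup's amplicon.
#' @param assignment An [assign_taxa()] result covering the reads.
#' @param lookup A [train_lookup()] table.
#' @param count_ends Passed to [onegap_distance()].
#' @return An `OTUPartition` over all reads, with cutoff label
#'   `"dynamic"`.
#' @export
dynamic_cluster <- function(reads, assignment, lookup, count_ends = TRUE) {
  widths <- unique(nchar(reads))
  if (length(widths) > 1L) stop("reads differ in width")
  if (!is.null(lookup$amplicon_width) && length(widths) &&
      widths != lookup$amplicon_width) {
    stop("read width ", widths, " does not match the lookup amplicon width ",
         lookup$amplicon_width)
  }
  groups <- assignment$assignments
  groups <- groups[lengths(groups) > 0L]
  if (length(assignment$unclassified)) {
    groups <- c(groups, list(unclassified = assignment$unclassified))
  }
  covered <- unlist(groups, use.names = FALSE)
  if (!setequal(covered, names(reads))) {
    stop("assignment does not cover the read set exactly")
  }
  otus <- list()
  for (taxon in names(groups)) {
    ids <- groups[[taxon]]
    cut <- if (taxon %in% lookup$rows$taxon) {
      lookup$rows$cutoff[match(taxon, lookup$rows$taxon)]
    } else {
      lookup$default_cutoff
    }
    part <- if (length(ids) == 1L) {
      make_partition(list(ids), cut, prefix = paste0(taxon, "_OTU"))
    } else {
      dm <- pairwise_distances(reads[ids], count_ends = count_ends)
      p <- average_neighbor_cluster(dm, cut)
      make_partition(p$otus, cut, prefix = paste0(taxon, "_OTU"))
    }
    otus <- c(otus, part$otus)
  }
  structure(list(cutoff = "dynamic", otus = otus), class = "OTUPartition")
}

#' Remove rare OTUs
#'
#' Drops OTUs whose total read count is strictly below
#' `min_fraction * depth` — by default below 0.1% of the sample's
#' subsampling depth (e.g. at depth 25 000: OTUs with 24 or fewer reads go,
#' 25 stay).
#'
#' @param partition An `OTUPartition`.
#' @param read_counts Optional named numeric of per-read counts (for
#'   dereplicated reads); default counts every member once.
#' @param min_fraction Minimum fraction of `depth` an OTU must hold
#'   (default 0.001).
#' @param depth Subsampling depth of the sample (reads per sample).
#' @return The filtered `OTUPartition`.
#' @export
filter_rare_otus <- function(partition, read_counts = NULL,
                             min_fraction = 0.001, depth) {
  stopifnot(depth > 0)
  totals <- vapply(partition$otus, function(m) {
    if (is.null(read_counts)) length(m) else sum(read_counts[m])
  }, numeric(1))
  keep <- totals >= min_fraction * depth
  structure(list(cutoff = partition$cutoff, otus = partition$otus[keep]),
            class = "OTUPartition")
}
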