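# Amplicon definitions: hypervariable-region maps, region-range and
# sliding-window amplicon specifications, and column extraction.
#
# All coordinates are 1-based inclusive alignment columns. A region-range
# amplicon Vi-Vj spans Vi.start..Vj.end, i.e. it includes the conserved
# stretches between the variable regions, as a real contiguous amplicon
# would.

#' Construct a hypervariable-region map
#'
#' @param regions A data.frame with columns `region`, `start`, `end`
#'   (1-based inclusive), ordered 5' to 3' and non-overlapping. The
#'   conventional nine 16S regions are named V1..V9.
#' @return An object of class `RegionMap`.
#' @export
region_map <- function(regions) {
  stopifnot(is.data.frame(regions),
            all(c("region", "start", "end") %in% names(regions)))
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (any(regions$start < 1L) || any(regions$end < regions$start)) {
    stop("region coordinates must satisfy 1 <= start <= end")
  }
  if (nrow(regions) > 1L &&
      any(regions$start[-1L] <= regions$end[-nrow(regions)])) {
    stop("regions must be ordered and non-overlapping")
  }
  rownames(regions) <- regions$region
  structure(regions, class = c("RegionMap", "data.frame"))
}

#' Read a region map from a TSV or YAML file
#'
#' TSV format: `region<TAB>start<TAB>end` with a header line. YAML format:
#' a mapping `region: [start, end]`.
#'
#' @param path Path to the map file.
#' @return A [region_map()].
#' @export
read_region_map <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML region maps requires the 'yaml' package")
    }
    y <- yaml::read_yaml(path)
    df <- data.frame(region = names(y),
                     start = vapply(y, function(v) as.integer(v[[1L]]), 1L),
                     end = vapply(y, function(v) as.integer(v[[2L]]), 1L),
                     stringsAsFactors = FALSE)
    return(region_map(df))
  }
  region_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Default 16S rRNA hypervariable-region map
#'
#' Approximate V1-V9 boundaries on the Escherichia coli 16S rRNA gene
#' numbering, the customary reference coordinate system for 16S amplicons.
#' These are a shipped convention, not gospel: when working against a
#' specific reference alignment, supply a map in that alignment's column
#' coordinates instead (see [read_region_map()]).
#'
#' @return A [region_map()] of nine regions.
#' @export
default_region_map <- function() {
  read_region_map(system.file("extdata", "ecoli_v_regions.tsv",
                              package = "dynotu", mustWork = TRUE))
}

#' Amplicon specifications
#'
#' An `AmpliconSpec` names the slice of the gene an amplicon covers: a
#' contiguous range of hypervariable regions (e.g. V3-V4), a fixed
#' coordinate window, or the full-length gene.
#'
#' @param from,to Region names, e.g. `"V3"`, `"V4"` (from must not come
#'   after to).
#' @return An object of class `AmpliconSpec`.
#' @export
amplicon_region_range <- function(from, to = from) {
  structure(list(kind = "region-range", region_range = c(from, to),
                 window = NULL),
            class = "AmpliconSpec")
}

#' @rdname amplicon_region_range
#' @param start,end 1-based inclusive alignment columns, `start <= end`.
#' @export
amplicon_window <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(start >= 1L, end >= start)
  structure(list(kind = "window", region_range = NULL,
                 window = c(start, end)),
            class = "AmpliconSpec")
}

#' @rdname amplicon_region_range
#' @export
amplicon_full_length <- function() {
  structure(list(kind = "full-length", region_range = NULL, window = NULL),
            class = "AmpliconSpec")
}

#' Parse an amplicon specification from command-line syntax
#'
#' Accepts `"V3-V4"` or `"V4"` (region range), `"201:700"` (window) or
#' `"full-length"`.
#'
#' @param text Specification string.
#' @return An `AmpliconSpec`.
#' @export
parse_amplicon <- function(text) {
  text <- trimws(text)
  if (tolower(text) %in% c("full-length", "full", "fulllength")) {
    return(amplicon_full_length())
  }
  if (grepl("^[0-9]+:[0-9]+$", text)) {
    se <- as.integer(strsplit(text, ":", fixed = TRUE)[[1L]])
    return(amplicon_window(se[1L], se[2L]))
  }
  if (grepl("^V[0-9]+(-V[0-9]+)?$", text, ignore.case = TRUE)) {
    rr <- strsplit(toupper(text), "-", fixed = TRUE)[[1L]]
    return(amplicon_region_range(rr[1L], rr[length(rr)]))
  }
  stop("cannot parse amplicon specification: '", text, "'")
}

#' @export
format.AmpliconSpec <- function(x, ...) {
  switch(x$kind,
         "full-length" = "full-length",
         "region-range" = if (x$region_range[1L] == x$region_range[2L]) {
           x$region_range[1L]
         } else paste(x$region_range, collapse = "-"),
         "window" = paste(x$window, collapse = ":"))
}

#' @export
print.AmpliconSpec <- function(x, ...) {
  cat("AmpliconSpec:", format(x), "\n")
  invisible(x)
}

# Resolve a spec to (start, end) alignment columns.
resolve_amplicon <- function(spec, region_map = NULL, alignment_width = NULL) {
  switch(spec$kind,
         "full-length" = {
           stopifnot(!is.null(alignment_width))
           c(1L, as.integer(alignment_width))
         },
         "window" = spec$window,
         "region-range" = {
           if (is.null(region_map)) region_map <- default_region_map()
           rr <- spec$region_range
           if (!all(rr %in% region_map$region)) {
             stop("region(s) not in map: ",
                  paste(setdiff(rr, region_map$region), collapse = ", "))
           }
           i <- match(rr[1L], region_map$region)
           j <- match(rr[2L], region_map$region)
           if (i > j) stop("region range must be ordered: ", rr[1L], "-", rr[2L])
           c(region_map$start[i], region_map$end[j])
         })
}

#' Contiguous combinations of k adjacent hypervariable regions
#'
#' For k regions out of nine there are `10 - k` contiguous combinations;
#' e.g. for seven: V1-V7, V2-V8 and V3-V9.
#'
#' @param map A [region_map()].
#' @param k Number of adjacent regions, in `[1, nrow(map)]`.
#' @return List of region-range `AmpliconSpec`s, in order.
#' @export
region_combinations <- function(map, k) {
  n <- nrow(map)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]")
  lapply(seq_len(n - k + 1L), function(i) {
    amplicon_region_range(map$region[i], map$region[i + k - 1L])
  })
}

#' Fixed-length sliding windows across a span
#'
#' Enumerates windows of a fixed length advancing by `step` (default 50 bp),
#' starting at `span_start`; windows running past `span_end` are not
#' emitted. Over positions 1-1450 this yields 24 windows of 300 nt
#' (1-300 ... 1151-1450) and 20 of 500 nt (1-500 ... 951-1450).
#'
#' @param span_start,span_end 1-based inclusive span bounds.
#' @param length Window length in columns.
#' @param step Start-to-start shift (default 50).
#' @return List of window `AmpliconSpec`s.
#' @export
sliding_windows <- function(span_start, span_end, length, step = 50L) {
  stopifnot(step >= 1L)
  if (length > span_end - span_start + 1L) {
    stop("window length ", length, " exceeds span ",
         span_end - span_start + 1L)
  }
  starts <- seq.int(span_start, span_end - length + 1L, by = step)
  lapply(starts, function(s) amplicon_window(s, s + length - 1L))
}

#' Extract an amplicon from a reference database
#'
#' Restricts every sequence to the spec's alignment columns (a region range
#' spans from the first region's start to the last region's end, including
#' intervening conserved stretches). Sequences that are entirely gaps over
#' the window are dropped with a message; families emptied by that drop are
#' removed with a warning.
#'
#' @param db A [reference_db()].
#' @param spec An [amplicon_spec][amplicon_region_range].
#' @param region_map Region map for resolving region ranges (defaults to
#'   [default_region_map()]).
#' @return A `ReferenceDB` whose `alignment_width` is the window width.
#' @export
extract_amplicon <- function(db, spec, region_map = NULL) {
  se <- resolve_amplicon(spec, region_map, db$alignment_width)
  if (se[1L] < 1L || se[2L] > db$alignment_width) {
    stop("amplicon ", paste(se, collapse = ":"),
         " outside alignment bounds [1, ", db$alignment_width, "]")
  }
  sub <- substr(db$seqs, se[1L], se[2L])
  names(sub) <- db$ids
  all_gap <- !grepl("[ACGTN]", sub)
  if (any(all_gap)) {
    message(sum(all_gap), " sequence(s) dropped: no residues in window ",
            paste(se, collapse = ":"))
    before <- names(db$family_index)
    sub <- sub[!all_gap]
    tax <- db$taxonomy[db$taxonomy$seq_id %in% names(sub), , drop = FALSE]
    out <- reference_db(sub, tax)
    lost <- setdiff(before, names(out$family_index))
    if (length(lost)) {
      warning("family(ies) emptied by amplicon extraction: ",
              paste(lost, collapse = ", "))
    }
    return(out)
  }
  reference_db(sub, db$taxonomy)
}
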