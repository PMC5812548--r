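# Synthetic reference databases and read sets with controlled family- and
# region-specific divergence.
#
# Species within a family are independent mutants of one random ancestor
# (a star phylogeny): at each site, with the region's substitution
# probability r, the base is replaced by one of the other three uniformly.
# The star model gives a closed-form expected pairwise distance between
# two species, 2r(1-r) + (2/3)r^2, used as an oracle by the test suite.
# Indels are not simulated, so alignment width stays uniform.

BASES <- c("A", "C", "G", "T")

# Per-column substitution rates from a region map + named region rates.
column_rates <- function(width, region_map, region_rates,
                         background_rate = 0) {
  rates <- rep(background_rate, width)
  for (r in names(region_rates)) {
    i <- match(r, region_map$region)
    if (is.na(i)) stop("rate given for unknown region: ", r)
    rates[region_map$start[i]:region_map$end[i]] <- region_rates[[r]]
  }
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  rates
}

# Mutate integer-coded bases (1..4) in place with per-site probabilities.
mutate_codes <- function(codes, rates) {
  hit <- which(stats::runif(length(codes)) < rates)
  if (length(hit)) {
    codes[hit] <- (codes[hit] - 1L +
                     sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L
  }
  codes
}

#' Expected pairwise distance between two star-phylogeny mutants
#'
#' Two species derived independently from one ancestor with per-site
#' substitution probability `rate` (uniform replacement over the other
#' three bases) differ at a site with probability
#' `2 r (1 - r) + (2/3) r^2`.
#'
#' @param rate Per-site substitution probability.
#' @return Expected per-site distance.
#' @export
expected_star_distance <- function(rate) {
  2 * rate * (1 - rate) + (2 / 3) * rate^2
}

#' Simulate one family of aligned species sequences
#'
#' Draws a random ancestor and derives `n_species` independent mutants
#' with region-specific substitution probabilities.
#'
#' @param ancestor_length Alignment width in columns.
#' @param n_species Number of species (one sequence each).
#' @param region_rates Named numeric, per-region substitution probability
#'   per site; regions absent from the vector use `background_rate`.
#' @param region_map A [region_map()] locating the regions.
#' @param seed Integer seed; all randomness is reproducible.
#' @param family Family name used in ids and lineages.
#' @param background_rate Substitution probability outside the named
#'   regions (default 0).
#' @return List with `seqs` (named character vector, ids
#'   `<family>_sp01`...) and `taxonomy` (data.frame in
#'   [read_taxonomy()] layout, species = sequence id).
#' @export
simulate_family <- function(ancestor_length, n_species, region_rates,
                            region_map, seed, family = "FamilyA",
                            background_rate = 0) {
  rates <- column_rates(ancestor_length, region_map, region_rates,
                        background_rate)
  seqs <- with_seed(seed, {
    ancestor <- sample.int(4L, ancestor_length, replace = TRUE)
    vapply(seq_len(n_species), function(i) {
      paste(BASES[mutate_codes(ancestor, rates)], collapse = "")
    }, character(1))
  })
  ids <- sprintf("%s_sp%02d", family, seq_len(n_species))
  names(seqs) <- ids
  tax <- parse_lineage_strings(
    ids,
    sprintf("Bacteria;SimPhylum;SimClass;SimOrder;%s;%s_genus;%s;",
            family, family, ids))
  list(seqs = seqs, taxonomy = tax)
}

#' Simulate a multi-family reference database
#'
#' Families are independent star phylogenies spanning a gradient of
#' divergence: by default family f applies `variable_rates[f]` in every
#' hypervariable region and `background_rate` in the conserved stretches,
#' emulating reference databases in which different families diverge at
#' different rates in different regions.
#'
#' @param n_families Number of families (default 10).
#' @param species_per_family Species per family; scalar or vector of
#'   length `n_families` (default 8).
#' @param region_map A [region_map()] (default [default_region_map()]).
#' @param alignment_width Alignment width; defaults to the map's last
#'   region end plus a 77-column conserved tail (1542 with the default
#'   map, the E. coli 16S gene length).
#' @param variable_rates Per-family substitution rate applied to every
#'   region; default an even gradient from 0.005 to 0.08, spanning
#'   families more conserved and more divergent than the 3% convention.
#' @param per_family_region_rates Optional named list family -> named
#'   region-rate vector, overriding `variable_rates` for full control.
#' @param background_rate Rate outside the variable regions (default
#'   0.002; conserved stretches of 16S diverge little within a family).
#' @param seed Integer seed.
#' @return A [reference_db()].
#' @export
simulate_reference <- function(n_families = 10L, species_per_family = 8L,
                               region_map = default_region_map(),
                               alignment_width = NULL,
                               variable_rates = NULL,
                               per_family_region_rates = NULL,
                               background_rate = 0.002, seed = 1L) {
  if (is.null(alignment_width)) {
    alignment_width <- max(region_map$end) + 77L
  }
  stopifnot(alignment_width >= max(region_map$end))
  fams <- sprintf("Family%02d", seq_len(n_families))
  if (length(species_per_family) == 1L) {
    species_per_family <- rep(species_per_family, n_families)
  }
  if (is.null(per_family_region_rates)) {
    if (is.null(variable_rates)) {
      variable_rates <- seq(0.005, 0.08, length.out = n_families)
    }
    per_family_region_rates <- lapply(variable_rates, function(r) {
      stats::setNames(rep(r, nrow(region_map)), region_map$region)
    })
    names(per_family_region_rates) <- fams
  }
  seqs <- character(0)
  tax <- NULL
  for (i in seq_len(n_families)) {
    fam <- simulate_family(alignment_width, species_per_family[i],
                           per_family_region_rates[[i]], region_map,
                           seed = seed + i, family = fams[i],
                           background_rate = background_rate)
    seqs <- c(seqs, fam$seqs)
    tax <- rbind(tax, fam$taxonomy)
  }
  reference_db(seqs, tax)
}

#' Simulate amplicon reads from a reference database
#'
#' Each read is its species' amplicon fragment with independent per-base
#' substitution errors at `error_rate` (gap columns untouched); the truth
#' table maps every read to its source species, and the taxonomy file
#' carries the true lineage with confidence 100.
#'
#' @param db A [reference_db()] (full-length).
#' @param spec Amplicon to sequence; NULL for full-length.
#' @param reads_per_species Reads generated per species (default 10).
#' @param error_rate Per-base substitution probability (default 0.001).
#' @param seed Integer seed.
#' @param region_map Region map for resolving region-range specs.
#' @return List with `reads` (named character, aligned to the amplicon
#'   window), `truth` (named character read -> species seq_id) and
#'   `taxonomy` (data.frame in [read_taxonomy()] layout with confidence
#'   100 at every rank).
#' @export
simulate_reads <- function(db, spec = NULL, reads_per_species = 10L,
                           error_rate = 0.001, seed = 1L,
                           region_map = NULL) {
  view <- if (is.null(spec) || identical(spec$kind, "full-length")) {
    db
  } else {
    extract_amplicon(db, spec, region_map)
  }
  reads <- with_seed(seed, {
    out <- character(0)
    for (id in view$ids) {
      codes <- encode_aligned(view$seqs[[id]])
      resi <- which(codes >= 1L & codes <= 4L)
      for (k in seq_len(reads_per_species)) {
        c2 <- codes
        c2[resi] <- mutate_codes(codes[resi], rep(error_rate, length(resi)))
        chars <- strsplit(view$seqs[[id]], "", fixed = TRUE)[[1L]]
        chars[resi] <- BASES[c2[resi]]
        out[sprintf("%s_r%03d", id, k)] <- paste(chars, collapse = "")
      }
    }
    out
  })
  truth <- stats::setNames(
    rep(view$ids, each = reads_per_species),
    names(reads))
  src <- view$taxonomy[match(truth, view$taxonomy$seq_id), , drop = FALSE]
  lineages <- sprintf("%s(100);%s(100);%s(100);%s(100);%s(100);%s(100);",
                      src$domain, src$phylum, src$class, src$order,
                      src$family, src$genus)
  tax <- parse_lineage_strings(names(reads), lineages)
  list(reads = reads, truth = truth, taxonomy = tax)
}
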