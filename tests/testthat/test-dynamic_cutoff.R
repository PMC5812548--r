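test_that("trained cut-offs are clamped into [1%, 3%]", {
  # all pairwise distances 0.05 -> raw 0.05 -> cutoff capped at 0.03
  high <- constant_distance_family(3, 25, 1000, family = "FamHi")
  # all pairwise distances 0.004 -> raw 0.004 -> cutoff floored at 0.01
  low <- constant_distance_family(3, 2, 1000, family = "FamLo")
  for (f in list(high, low)) {
    d <- pairwise_distances(f$seqs)$d
    expect_equal(unique(d[upper.tri(d)]),
                 2 * ifelse(grepl("Hi", names(f$seqs)[1]), 25, 2) / 1000)
  }
  db <- bind_families(high, low)
  lt <- train_lookup(db, amplicon_full_length())
  rows <- lt$rows[order(lt$rows$taxon), ]
  expect_equal(rows$taxon, c("FamHi", "FamLo"))
  expect_equal(rows$raw_percentile_distance, c(0.05, 0.004))
  expect_equal(rows$cutoff, c(0.03, 0.01))
  expect_equal(rows$n_pairs, c(3L, 3L))
  expect_true(all(lt$rows$cutoff >= lt$clamp[1] &
                    lt$rows$cutoff <= lt$clamp[2]))
})

test_that("nearest-rank percentile matches the sort-and-index oracle", {
  # worked case: ordered {0.012, 0.020, 0.025}, p = 2.5 -> first statistic
  expect_equal(dynotu:::nearest_rank_percentile(c(0.02, 0.012, 0.025), 2.5),
               0.012)
  set.seed(33)
  for (rep in 1:200) {
    x <- runif(sample(1:60, 1), 0, 0.2)
    p <- runif(1, 0.5, 99.5)
    # type-1 quantile is the inverse-ECDF nearest-rank definition
    expect_equal(dynotu:::nearest_rank_percentile(x, p),
                 unname(quantile(x, p / 100, type = 1)))
  }
})

test_that("raising divergence never lowers the trained raw percentile", {
  widths <- 1000
  raws <- vapply(c(1, 3, 6, 12, 24), function(n_mut) {
    fam <- constant_distance_family(4, n_mut, widths, family = "FamZ")
    lt <- train_lookup(bind_families(fam), amplicon_full_length())
    lt$rows$raw_percentile_distance
  }, numeric(1))
  expect_true(all(diff(raws) > 0))
})

test_that("interpolated percentile mode matches stats::quantile type 7", {
  fam <- constant_distance_family(4, 5, 1000, family = "FamQ")
  dm <- pairwise_distances(fam$seqs)
  dists <- dm$d[upper.tri(dm$d)]
  lt <- train_lookup(bind_families(fam), amplicon_full_length(),
                     interpolate = TRUE)
  expect_equal(lt$rows$raw_percentile_distance,
               unname(quantile(dists, 0.025, type = 7)))
})

test_that("lookup tables survive a TSV round trip", {
  db <- simulate_reference(n_families = 3, species_per_family = 4,
                           seed = 21)
  lt <- train_lookup(db, amplicon_window(201, 700), level = "family")
  path <- tempfile(fileext = ".tsv")
  write_lookup(lt, path)
  back <- read_lookup(path)
  expect_equal(back$level, lt$level)
  expect_equal(back$default_cutoff, lt$default_cutoff)
  expect_equal(back$clamp, lt$clamp)
  expect_equal(back$amplicon_width, lt$amplicon_width)
  expect_equal(back$rows$taxon, lt$rows$taxon)
  expect_equal(back$rows$cutoff, lt$rows$cutoff, tolerance = 1e-6)
})

test_that("training at other ranks groups by that rank", {
  db <- simulate_reference(n_families = 4, species_per_family = 3,
                           seed = 5)
  lt_order <- train_lookup(db, amplicon_window(101, 600), level = "order")
  expect_equal(lt_order$rows$taxon, "SimOrder")
  expect_equal(lt_order$rows$n_species, 12L)
})

test_that("assign_taxa honors labels, confidences and missing reads", {
  tax <- dynotu:::parse_lineage_strings(
    c("r1", "r2", "r3", "r4"),
    c("Bacteria(100);P(100);C(100);O(100);Enterobacteriaceae(100);G(99);",
      "Bacteria(100);P(100);C(100);O(100);Lachnospiraceae(60);G(40);",
      "Bacteria;P;C;O;Enterobacteriaceae;G;",
      "Bacteria(90);P(90);C(88);O(85);unclassified;"))
  asg <- assign_taxa(tax, level = "family", confidence_threshold = 80)
  expect_equal(asg$assignments$Enterobacteriaceae, c("r1", "r3"))
  # r2 confident below threshold, r4 literally unclassified
  expect_setequal(asg$unclassified, c("r2", "r4"))
  expect_equal(asg$unclassified_fraction, 0.5)
  # reads absent from the taxonomy fall into the unclassified bucket
  expect_warning(
    asg2 <- assign_taxa(tax, read_ids = c("r1", "r2", "r3", "r4", "r9")),
    "missing")
  expect_true("r9" %in% asg2$unclassified)
  expect_equal(asg2$unclassified_fraction, 3 / 5)
})

test_that("all-unclassified input reduces to the default pipeline", {
  db <- simulate_reference(n_families = 2, species_per_family = 4,
                           variable_rates = c(0.04, 0.06), seed = 3)
  spec <- amplicon_window(401, 900)
  sim <- simulate_reads(db, spec, reads_per_species = 3, error_rate = 0,
                        seed = 8)
  lt <- train_lookup(db, spec)
  asg <- list(assignments = list(),
              unclassified = names(sim$reads),
              unclassified_fraction = 1)
  got <- dynamic_cluster(sim$reads, asg, lt)
  ref <- average_neighbor_cluster(pairwise_distances(sim$reads),
                                  lt$default_cutoff)
  expect_identical(partition_sets(got), partition_sets(ref))
})

test_that("a lookup of all-default cutoffs matches the per-taxon default run", {
  db <- simulate_reference(n_families = 3, species_per_family = 4,
                           variable_rates = c(0.03, 0.05, 0.07), seed = 13)
  spec <- amplicon_window(201, 900)
  sim <- simulate_reads(db, spec, reads_per_species = 3, error_rate = 0.001,
                        seed = 14)
  lt <- train_lookup(db, spec)
  lt$rows$cutoff <- lt$default_cutoff
  asg <- assign_taxa(sim$taxonomy)
  got <- dynamic_cluster(sim$reads, asg, lt)
  for (fam in names(asg$assignments)) {
    ids <- asg$assignments[[fam]]
    ref <- average_neighbor_cluster(pairwise_distances(sim$reads[ids]),
                                    lt$default_cutoff)
    fam_sets <- Filter(function(s) s[1] %in% ids, partition_sets(got))
    expect_identical(fam_sets, partition_sets(ref))
  }
  # reads are conserved: every read lands in exactly one OTU
  expect_setequal(unlist(got$otus), names(sim$reads))
})

test_that("family cutoff below default splits what the default merges", {
  # two reads 2% apart: split at a trained 1% cutoff, merged at 3%
  fam <- constant_distance_family(2, 10, 1000, family = "FamT")
  reads <- fam$seqs
  names(reads) <- c("read1", "read2")
  expect_equal(onegap_distance(reads[[1]], reads[[2]]), 0.02)
  asg <- list(assignments = list(FamT = names(reads)),
              unclassified = character(0), unclassified_fraction = 0)
  lt <- structure(list(level = "family", amplicon = amplicon_full_length(),
                       amplicon_width = 1000L, percentile = 2.5,
                       clamp = c(0.01, 0.03), default_cutoff = 0.03,
                       rows = data.frame(taxon = "FamT", n_species = 2,
                                         n_pairs = 1,
                                         raw_percentile_distance = 0.008,
                                         cutoff = 0.01)),
                  class = "LookupTable")
  split_run <- dynamic_cluster(reads, asg, lt)
  expect_equal(n_otus(split_run), 2L)
  lt$rows$cutoff <- 0.03
  merged_run <- dynamic_cluster(reads, asg, lt)
  expect_equal(n_otus(merged_run), 1L)
})

test_that("reads of the wrong width are rejected", {
  lt <- structure(list(level = "family", amplicon = amplicon_window(1, 10),
                       amplicon_width = 10L, percentile = 2.5,
                       clamp = c(0.01, 0.03), default_cutoff = 0.03,
                       rows = data.frame()), class = "LookupTable")
  reads <- c(r1 = "ACGTACGT", r2 = "ACGTACGA")
  asg <- list(assignments = list(), unclassified = names(reads),
              unclassified_fraction = 1)
  expect_error(dynamic_cluster(reads, asg, lt), "width")
})

test_that("rare-OTU filtering applies the strict sub-threshold rule", {
  otus <- list(big = sprintf("a%03d", 1:25), small = sprintf("b%03d", 1:24))
  p <- structure(list(cutoff = 0.03, otus = otus), class = "OTUPartition")
  # at depth 25000 the 0.1% threshold is 25 reads: 24 goes, 25 stays
  kept <- filter_rare_otus(p, depth = 25000)
  expect_equal(names(kept$otus), "big")
  # min_fraction 0 is the identity
  expect_equal(filter_rare_otus(p, min_fraction = 0, depth = 25000)$otus,
               p$otus)
  one <- structure(list(cutoff = 0.03, otus = list(all = sprintf("r%d", 1:50))),
                   class = "OTUPartition")
  expect_length(filter_rare_otus(one, depth = 25000)$otus, 1L)
})
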