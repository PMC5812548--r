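test_that("load_reference builds a family-indexed db and normalizes residues", {
  seqs <- c(s1 = "ACGU-GCUAA", s2 = "acgt.gctaa", s3 = "ACGTTGCTAA")
  lineages <- c(
    s1 = "Bacteria(100);P1;C1;O1;FamA;G1;",
    s2 = "Bacteria;P1;C1;O1;FamA;G1;",
    s3 = "Bacteria;P1;C1;O1;FamB;G2;")
  files <- write_toy_reference(seqs, lineages)
  db <- load_reference(files$fasta, files$tax)
  expect_s3_class(db, "ReferenceDB")
  expect_equal(db$alignment_width, 10L)
  expect_length(db$ids, 3L)
  # U -> T, case folded; '-' and '.' both kept as gap characters
  expect_equal(unname(db$seqs[["s1"]]), "ACGT-GCTAA")
  expect_equal(unname(db$seqs[["s2"]]), "ACGT.GCTAA")
  expect_named(db$family_index, c("FamA", "FamB"))
  expect_setequal(db$family_index$FamA, c("s1", "s2"))
})

test_that("load_reference rejects ids missing from taxonomy, naming them", {
  seqs <- c(s1 = "ACGT", seqX = "ACGT")
  files <- write_toy_reference(seqs, c(s1 = "Bacteria;P;C;O;F;G;"))
  expect_error(load_reference(files$fasta, files$tax), "seqX")
})

test_that("load_reference rejects ragged alignments with the offending id", {
  seqs <- c(s1 = "ACGTACGTAC", s2 = "ACGTACGTA")
  lineages <- c(s1 = "B;P;C;O;F;G;", s2 = "B;P;C;O;F;G;")
  files <- write_toy_reference(seqs, lineages)
  expect_error(load_reference(files$fasta, files$tax),
               "ragged.*s2|s2.*ragged")
})

test_that("filter_families applies the minimum-size and pending rules", {
  fams <- lapply(c(FamA = 2L, FamB = 3L, FamC = 5L), function(n) {
    constant_distance_family(n, 1L, 50L)
  })
  for (f in names(fams)) {
    names(fams[[f]]$seqs) <- sub("FamX", f, names(fams[[f]]$seqs))
    fams[[f]]$taxonomy$seq_id <- sub("FamX", f, fams[[f]]$taxonomy$seq_id)
    fams[[f]]$taxonomy$family <- f
    fams[[f]]$taxonomy$species <- fams[[f]]$taxonomy$seq_id
  }
  db <- bind_families(fams$FamA, fams$FamB, fams$FamC)

  kept <- filter_families(db, min_species = 3)
  expect_setequal(names(kept$family_index), c("FamB", "FamC"))
  expect_equal(unname(lengths(kept$family_index)[c("FamB", "FamC")]),
               c(3L, 5L))

  # min_species = 1 leaves the database unchanged
  expect_equal(filter_families(db, min_species = 1)$ids, db$ids)

  # filtering is idempotent
  expect_equal(filter_families(kept, min_species = 3)$ids, kept$ids)
})

test_that("filter_families drops pending-classification families by name", {
  fam <- constant_distance_family(4L, 1L, 50L)
  fam$taxonomy$family <- "Unclassified_Bacteroidales"
  fam2 <- constant_distance_family(4L, 1L, 50L, family = "FamOK")
  db <- bind_families(fam, fam2)
  kept <- filter_families(db, min_species = 3, drop_unclassified = TRUE)
  expect_named(kept$family_index, "FamOK")
  kept_all <- filter_families(db, min_species = 3, drop_unclassified = FALSE)
  expect_length(kept_all$family_index, 2L)
})

test_that("curate_database keeps one deterministic representative per cluster", {
  # d(A,B) = 0.01, d(A,C) = 0.10, d(B,C) = 0.11 over width 100
  base <- strsplit(paste(rep("A", 100), collapse = ""), "")[[1]]
  sA <- base
  sB <- base; sB[1] <- "C"
  sC <- base; sC[11:20] <- "G"
  seqs <- c(rA = paste(sA, collapse = ""),
            rB = paste(sB, collapse = ""),
            rC = paste(sC, collapse = ""))
  tax <- dynotu:::parse_lineage_strings(
    names(seqs), rep("B;P;C;O;FamA;G;x;", 3))
  tax$species <- names(seqs)
  db <- reference_db(seqs, tax)
  expect_equal(onegap_distance(seqs[["rA"]], seqs[["rB"]]), 0.01)
  expect_equal(onegap_distance(seqs[["rA"]], seqs[["rC"]]), 0.10)

  cur <- curate_database(db, cutoff = 0.03)
  # {rA,rB} collapse; lexicographically smallest id represents the cluster
  expect_setequal(cur$ids, c("rA", "rC"))

  # cutoff 0: only identical sequences collapse, so everything is retained
  expect_setequal(curate_database(db, cutoff = 0)$ids, db$ids)

  # idempotence: re-clustering the curated db at the same cutoff yields one
  # OTU per retained sequence
  dm <- pairwise_distances(cur$seqs)
  expect_equal(n_otus(average_neighbor_cluster(dm, 0.03)), length(cur$ids))
})

test_that("subsample_families caps family sizes reproducibly", {
  fam <- constant_distance_family(23L, 1L, 100L, family = "Big")
  small <- constant_distance_family(5L, 1L, 100L, family = "Small")
  db <- bind_families(fam, small)
  sub1 <- subsample_families(db, max_species = 7, seed = 11)
  sub2 <- subsample_families(db, max_species = 7, seed = 11)
  expect_equal(lengths(sub1$family_index)[["Big"]], 7L)
  expect_equal(lengths(sub1$family_index)[["Small"]], 5L)
  expect_identical(sub1$ids, sub2$ids)
  expect_equal(sub1$alignment_width, db$alignment_width)
  # index stays consistent with the retained sequences
  expect_setequal(unlist(sub1$family_index), sub1$ids)
  # a different seed may pick different members but the same sizes
  sub3 <- subsample_families(db, max_species = 7, seed = 12)
  expect_equal(lengths(sub3$family_index), lengths(sub1$family_index))
})
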