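# In-code fixtures and independent oracles used across the suite.

# A random symmetric distance matrix over n sequences with sorted ids.
rand_dm <- function(n, max_d = 1) {
  ids <- sort(sprintf("s%02d", sample(99, n)))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- runif(n * (n - 1) / 2, 0, max_d)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  structure(list(ids = ids, d = d), class = "DistanceMatrix")
}

# Exhaustive average-linkage reference: recomputes every cluster-pair mean
# from the raw matrix at each step (no incremental updates), with the same
# tie rule (lexicographic on the sorted pair of cluster minimum ids).
naive_average_cluster <- function(dm, cutoff) {
  members <- as.list(dm$ids)
  eps <- 1e-12
  repeat {
    n <- length(members)
    if (n < 2) break
    best <- NULL
    best_mean <- Inf
    best_key <- NULL
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        m <- mean(dm$d[members[[i]], members[[j]]])
        key <- paste(sort(c(min(members[[i]]), min(members[[j]]))),
                     collapse = "\r")
        if (m < best_mean - eps ||
            (abs(m - best_mean) <= eps && key < best_key)) {
          best_mean <- m
          best <- c(i, j)
          best_key <- key
        }
      }
    }
    if (best_mean > cutoff + eps) break
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members[[best[2]]] <- NULL
  }
  canonical_sets(members)
}

# Canonical form of a partition: sorted member sets, ordered by smallest id.
canonical_sets <- function(sets) {
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, `[[`, character(1), 1))])
}

partition_sets <- function(partition) canonical_sets(partition$otus)

# A gap-free family in which every species carries `n_mut` private
# substitutions at disjoint sites, so every pairwise distance is exactly
# 2 * n_mut / width.
constant_distance_family <- function(n_species, n_mut, width,
                                     family = "FamX") {
  stopifnot(n_species * n_mut <= width)
  ancestor <- rep("A", width)
  seqs <- vapply(seq_len(n_species), function(i) {
    s <- ancestor
    sites <- ((i - 1) * n_mut + 1):(i * n_mut)
    s[sites] <- "C"
    paste(s, collapse = "")
  }, character(1))
  ids <- sprintf("%s_sp%02d", family, seq_len(n_species))
  names(seqs) <- ids
  tax <- dynotu:::parse_lineage_strings(
    ids, sprintf("Bacteria;P;C;O;%s;%s_g;%s;", family, family, ids))
  list(seqs = seqs, taxonomy = tax)
}

# Assemble several families (as returned by constant_distance_family or
# simulate_family) into one ReferenceDB.
bind_families <- function(...) {
  fams <- list(...)
  reference_db(do.call(c, lapply(fams, `[[`, "seqs")),
               do.call(rbind, lapply(fams, `[[`, "taxonomy")))
}

# Small single-region map spanning a whole toy alignment.
toy_map <- function(width) {
  region_map(data.frame(region = "V1", start = 1L, end = as.integer(width)))
}

# Write a tiny aligned FASTA + taxonomy pair into tempfiles.
write_toy_reference <- function(seqs, lineages) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), fa)
  tx <- tempfile(fileext = ".tax")
  writeLines(paste0(names(lineages), "\t", lineages), tx)
  list(fasta = fa, tax = tx)
}
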