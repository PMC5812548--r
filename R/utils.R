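# Internal helpers shared across modules.

RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

# Character -> integer encoding used by the distance kernel.
# 0 = gap ('-' or '.'), 1..4 = A,C,G,T, 5 = anything else (N, ambiguity).
.CODE <- {
  x <- rep(5L, 256L)
  x[utf8ToInt("-") + 1L] <- 0L
  x[utf8ToInt(".") + 1L] <- 0L
  x[utf8ToInt("A") + 1L] <- 1L
  x[utf8ToInt("C") + 1L] <- 2L
  x[utf8ToInt("G") + 1L] <- 3L
  x[utf8ToInt("T") + 1L] <- 4L
  x
}

encode_aligned <- function(s) {
  .CODE[utf8ToInt(s) + 1L]
}

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

normalize_residues <- function(x) {
  chartr("uU", "TT", toupper(x))
}

#' Read an aligned FASTA file
#'
#' Reads a gapped (aligned) FASTA file into a named character vector of
#' uppercase sequences with U normalized to T. Identifiers are truncated at
#' the first whitespace, matching common 16S reference conventions.
#'
#' @param path Path to a FASTA file whose records all share one width.
#' @return Named character vector of aligned sequences.
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- normalize_residues(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs
}

#' Write an aligned FASTA file
#'
#' @param seqs Named character vector of aligned sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_aligned_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Parse a taxonomy file
#'
#' Parses the two-column taxonomy dialect used by common 16S classifiers:
#' one line per sequence, `seqID<TAB>Domain(conf);Phylum(conf);...;` with
#' parenthesised bootstrap confidences optional. Up to seven ranks are read
#' (domain through genus, plus an optional trailing species label).
#'
#' @param path Path to the taxonomy file.
#' @return A data.frame with columns `seq_id`, one column per rank
#'   (`domain` ... `genus`, `species`), and matching `<rank>_conf` numeric
#'   columns (NA where no confidence was printed).
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    stop("malformed taxonomy line(s): ", paste(which(bad), collapse = ", "))
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  lineages <- vapply(parts, `[[`, character(1), 2L)
  parse_lineage_strings(ids, lineages)
}

# Split "Bacteria(100);Proteobacteria(98);...;" into rank labels + confidences.
parse_lineage_strings <- function(ids, lineages) {
  ranks <- c(RANKS, "species")
  labs <- matrix("", nrow = length(ids), ncol = length(ranks),
                 dimnames = list(NULL, ranks))
  confs <- matrix(NA_real_, nrow = length(ids), ncol = length(ranks),
                  dimnames = list(NULL, paste0(ranks, "_conf")))
  fields <- strsplit(sub(";$", "", lineages), ";", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    f <- f[nzchar(f)]
    k <- min(length(f), length(ranks))
    if (k == 0L) next
    m <- regmatches(f[1:k], regexec("^(.*?)\\(([0-9.]+)\\)$", f[1:k]))
    for (j in 1:k) {
      if (length(m[[j]]) == 3L) {
        labs[i, j] <- m[[j]][2L]
        confs[i, j] <- as.numeric(m[[j]][3L])
      } else {
        labs[i, j] <- f[j]
      }
    }
  }
  out <- data.frame(seq_id = ids, labs, confs,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a taxonomy file
#'
#' Inverse of [read_taxonomy()]: writes `seqID<TAB>lineage;` lines, with
#' confidences in parentheses where present.
#'
#' @param tax A data.frame as returned by [read_taxonomy()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_taxonomy <- function(tax, path) {
  ranks <- intersect(c(RANKS, "species"), names(tax))
  lines <- vapply(seq_len(nrow(tax)), function(i) {
    fields <- character(0)
    for (r in ranks) {
      lab <- tax[[r]][i]
      if (!nzchar(lab)) break
      cf <- tax[[paste0(r, "_conf")]]
      fields <- c(fields, if (!is.null(cf) && !is.na(cf[i])) {
        sprintf("%s(%s)", lab, format(cf[i], trim = TRUE))
      } else lab)
    }
    paste0(tax$seq_id[i], "\t", paste0(fields, collapse = ";"), ";")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
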