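# Internal helpers shared across modules.

# Run code with a fixed RNG seed and restore the caller's RNG state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")

# DNA string <-> integer codes 0:3 (A,C,G,T); anything else becomes NA
encode_dna <- function(x) {
  m <- match(strsplit(x, "", fixed = TRUE)[[1]], BASES) - 1L
  m
}

decode_dna <- function(codes) {
  paste(BASES[codes + 1L], collapse = "")
}

random_dna <- function(length) {
  paste(sample(BASES, length, replace = TRUE), collapse = "")
}

# reverse complement handling IUPAC ambiguity codes
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split semicolon-delimited taxonomy paths
split_path <- function(path) strsplit(path, ";", fixed = TRUE)

path_rank <- function(path, rank) {
  vapply(split_path(path), function(p) {
    if (length(p) >= rank) p[[rank]] else NA_character_
  }, character(1))
}

# Canonical form of a partition: group labels renumbered in order of first
# appearance, so two partitions are identical iff their canonical vectors are.
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# union-find connected components for a symmetric logical adjacency matrix
components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (j in which(adj[i, ])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  canonical_partition(roots)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
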