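# Independent oracles and fixture builders used across the suite.

BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(L) paste(sample(BASES4, L, replace = TRUE), collapse = "")

# substitute n random positions (never to the same base)
sub_mutate <- function(s, n) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample(length(x), n)
  for (p in pos) x[p] <- sample(setdiff(BASES4, x[p]), 1)
  paste(x, collapse = "")
}

rc_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGTRY", "TGCAYR", x), "")[[1]]), collapse = "")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# reads data.frame builder
reads_df <- function(seqs, sample_id = "s1", counts = 1) {
  seqs <- rep(seqs, counts)
  data.frame(id = sprintf("r%04d", seq_along(seqs)),
             sample_id = sample_id, sequence = seqs,
             stringsAsFactors = FALSE)
}

# Exhaustive chimera oracle: plain loops over all more-abundant parent pairs
# and breakpoints, the published vote rule, and a gapped single-parent
# rescue via utils::adist.  Mirrors the documented decision rule with none
# of the prefix-sum / candidate-prescreen machinery.
chimera_oracle <- function(seqs, abund, min_div = 0.8, min_score = 0.28,
                           abskew = 2, xn = 8, dn = 1.4) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  flag <- logical(n)
  if (n < 3) return(flag)
  for (q in seq_len(n)) {
    cand <- which(abund >= abskew * abund[q] & abund > abund[q] &
                    seq_len(n) != q)
    if (length(cand) < 2) next
    best_single <- max(vapply(cand, function(p)
      sum(chars[[q]] == chars[[p]]), integer(1)))
    best <- list(tot = -1)
    for (t in seq_len(L - 1)) {
      for (A in cand) for (B in cand) {
        if (A == B) next
        tot <- sum(chars[[q]][1:t] == chars[[A]][1:t]) +
          sum(chars[[q]][(t + 1):L] == chars[[B]][(t + 1):L])
        if (tot > best$tot) best <- list(tot = tot, A = A, B = B, t = t)
      }
    }
    if (best$tot < 0) next
    id_single <- 100 * best_single / L
    id_chim <- 100 * best$tot / L
    if (!(id_chim > id_single && id_chim - id_single >= min_div)) next
    a <- chars[[best$A]]; b <- chars[[best$B]]; qq <- chars[[q]]
    votes <- function(cols, model, other) {
      y <- sum(qq[cols] == model[cols] & model[cols] != other[cols])
      no <- sum(qq[cols] == other[cols] & model[cols] != other[cols])
      ab <- sum(model[cols] != other[cols] & qq[cols] != model[cols] &
                  qq[cols] != other[cols])
      if (y + no + ab == 0) 0 else y / (y + xn * no + dn * ab)
    }
    h <- min(votes(1:best$t, a, b), votes((best$t + 1):L, b, a))
    if (h < min_score) next
    gapped <- max(vapply(cand, function(p)
      100 * (L - utils::adist(seqs[q], seqs[p])[1, 1]) / L, numeric(1)))
    if (id_chim - max(id_single, gapped) < min_div) next
    flag[q] <- TRUE
  }
  flag
}

# connected components of the <= d edit-distance graph via igraph + adist
component_oracle <- function(seqs, d) {
  D <- utils::adist(seqs)
  g <- igraph::graph_from_adjacency_matrix(D <= d, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# noisy copy of an aligned sequence: substitution errors plus homopolymer
# deletions rendered as gap characters (what a multiple alignment of
# pyrosequencing reads presents to the distance machinery)
noisy_aligned <- function(s, sub_rate = 0.001, indel_rate = 0.002) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(x)) < sub_rate)
  for (p in hit) x[p] <- sample(setdiff(BASES4, x[p]), 1)
  r <- rle(x)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  long <- which(r$lengths >= 3)
  for (g in long) {
    if (stats::runif(1) < indel_rate * r$lengths[g]) {
      pos <- which(run_id == g)[1]
      x[pos] <- "-"
    }
  }
  paste(x, collapse = "")
}
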