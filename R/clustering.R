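# Single-linkage amplicon clustering at a local edit-distance threshold,
# MOTU filtering and representative-sequence selection.

#' Number of differences between two sequences
#'
#' Levenshtein edit distance (mismatches plus indels), the "d differences"
#' used to link amplicons during clustering.
#'
#' @param a,b DNA strings.
#' @return integer distance.
#' @export
#' @examples
#' seq_distance("ACGT", "ACGA")  # 1
#' seq_distance("ACGT", "AGT")   # 1 (one deletion)
seq_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  edit_distance_cpp(a, b)
}

#' Cluster amplicons into MOTUs by single-linkage chaining
#'
#' Links every pair of amplicons at edit distance <= `d` and grows clusters
#' breadth-first from the most abundant unassigned amplicon, so MOTUs are
#' exactly the connected components of the d-difference graph, output in
#' seed-abundance order.
#'
#' @param amplicons an `amplicon_set` (dereplicated, abundance-sorted,
#'   chimera-free).
#' @param d local threshold in differences (default 2).
#' @return list of class `motu_set`: `motus` (data.frame `motu_id`,
#'   `seed_sequence`, `total_reads`, `n_samples_present`), `counts` (MOTU x
#'   sample matrix), `membership` (data.frame `motu_id`, `amplicon_id`) and
#'   the input `amplicons`.
#' @export
swarm_cluster <- function(amplicons, d = 2) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  if (d < 0) stop("d must be >= 0")
  amp <- amplicons$amplicons
  if (nrow(amp) == 0) stop("no amplicons to cluster")
  labels <- swarm_components_cpp(amp$sequence, as.integer(d))
  n_motu <- max(labels)
  ids <- sprintf("motu%05d", seq_len(n_motu))
  counts <- rowsum(amplicons$counts, group = labels, reorder = TRUE)
  counts <- matrix(as.integer(counts), nrow = n_motu,
                   dimnames = list(ids, colnames(amplicons$counts)))
  seed_idx <- vapply(seq_len(n_motu),
                     function(k) which(labels == k)[1], integer(1))
  motus <- data.frame(
    motu_id = ids,
    seed_sequence = amp$sequence[seed_idx],
    total_reads = as.integer(rowSums(counts)),
    n_samples_present = as.integer(rowSums(counts > 0)),
    stringsAsFactors = FALSE)
  structure(list(
    motus = motus, counts = counts,
    membership = data.frame(motu_id = ids[labels],
                            amplicon_id = amp$amplicon_id,
                            stringsAsFactors = FALSE),
    amplicons = amplicons),
    class = "motu_set")
}

subset_motus <- function(motus, keep) {
  ids <- motus$motus$motu_id[keep]
  structure(list(
    motus = motus$motus[keep, , drop = FALSE],
    counts = motus$counts[keep, , drop = FALSE],
    membership = motus$membership[motus$membership$motu_id %in% ids, ,
                                  drop = FALSE],
    amplicons = motus$amplicons),
    class = "motu_set")
}

#' Split MOTUs into abundant and rare sets
#'
#' A MOTU is retained when it occurs in at least `min_samples` samples and
#' totals at least `min_reads` reads; the rare remainder is kept for later
#' meta-reference reassignment.
#'
#' @param motus a `motu_set`.
#' @param min_samples occurrence threshold (default 3).
#' @param min_reads abundance threshold (default 10).
#' @return list with `retained` and `rare`, both `motu_set`s.
#' @export
abundance_occurrence_filter <- function(motus, min_samples = 3,
                                        min_reads = 10) {
  stopifnot(inherits(motus, "motu_set"))
  keep <- motus$motus$n_samples_present >= min_samples &
    motus$motus$total_reads >= min_reads
  list(retained = subset_motus(motus, keep),
       rare = subset_motus(motus, !keep))
}

#' Select a representative sequence per MOTU
#'
#' The MOTU's most abundant (seed) sequence is used as a prefix to search
#' the untrimmed reads for longer sequences of the same MOTU; among the
#' prefix-matching reads of maximal length the most abundant unique sequence
#' is chosen (lexicographic on ties).  When no longer read exists the seed
#' itself is returned.
#'
#' @param motus a `motu_set` (seed sequences of trim length).
#' @param untrimmed_reads data.frame of retained, untrimmed reads (`id`,
#'   `sample_id`, `sequence`, primer still present).
#' @param primers primer set used to locate the insert.
#' @return `motus` with a `representative` column added to `$motus`.
#' @export
select_representative <- function(motus, untrimmed_reads,
                                  primers = foram_primers()) {
  stopifnot(inherits(motus, "motu_set"))
  trim_len <- nchar(motus$motus$seed_sequence[1])
  pos <- regexpr(primers$forward, untrimmed_reads$sequence, fixed = TRUE)
  ok <- pos > 0
  start <- pos + attr(pos, "match.length")
  inserts <- substring(untrimmed_reads$sequence[ok], start[ok])
  tab <- table(inserts)
  uniq <- names(tab)
  ab <- as.integer(tab)
  prefix <- substr(uniq, 1, trim_len)
  by_prefix <- split(seq_along(uniq), prefix)
  rep_seq <- motus$motus$seed_sequence
  for (i in seq_len(nrow(motus$motus))) {
    cand <- by_prefix[[motus$motus$seed_sequence[i]]]
    if (is.null(cand)) next
    len <- nchar(uniq[cand])
    cand <- cand[len == max(len)]
    if (max(nchar(uniq[cand])) <= trim_len) next
    cand <- cand[order(-ab[cand], uniq[cand])]
    rep_seq[i] <- uniq[cand[1]]
  }
  motus$motus$representative <- rep_seq
  motus
}
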