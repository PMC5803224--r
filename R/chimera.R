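# Dereplication and de-novo two-parent chimera screening.

#' Dereplicate equal-length reads into abundance-sorted amplicons
#'
#' Collapses identical sequences into amplicons with total and per-sample
#' counts, ordered by decreasing total abundance and lexicographically by
#' sequence on ties.  This stable order drives both the chimera scan (parents
#' must be more abundant than the query) and clustering seed selection.
#'
#' @param reads data.frame with `id`, `sample_id`, `sequence`, all sequences
#'   of equal length.
#' @return list of class `amplicon_set`: `amplicons` (data.frame
#'   `amplicon_id`, `sequence`, `abundance`), `counts` (amplicon x sample
#'   integer matrix) and `read_map` (data.frame `id`, `amplicon_id`).
#' @export
dereplicate <- function(reads) {
  stopifnot(all(c("id", "sample_id", "sequence") %in% names(reads)))
  if (length(unique(nchar(reads$sequence))) > 1)
    stop("dereplicate expects equal-length reads (trim first)")
  seqs <- unique(reads$sequence)
  samples <- sort(unique(reads$sample_id))
  counts <- table(factor(reads$sequence, levels = seqs),
                  factor(reads$sample_id, levels = samples))
  counts <- matrix(as.integer(counts), nrow = length(seqs),
                   dimnames = list(NULL, samples))
  abundance <- rowSums(counts)
  ord <- order(-abundance, seqs)
  seqs <- seqs[ord]
  counts <- counts[ord, , drop = FALSE]
  abundance <- abundance[ord]
  ids <- sprintf("amp%06d", seq_along(seqs))
  rownames(counts) <- ids
  structure(list(
    amplicons = data.frame(amplicon_id = ids, sequence = seqs,
                           abundance = as.integer(abundance),
                           stringsAsFactors = FALSE),
    counts = counts,
    read_map = data.frame(id = reads$id,
                          amplicon_id = ids[match(reads$sequence, seqs)],
                          stringsAsFactors = FALSE)),
    class = "amplicon_set")
}

#' De-novo two-parent chimera detection
#'
#' For every amplicon the best chimeric model (two parents among the
#' amplicons at least `abskew` times more abundant, one breakpoint) is
#' compared with the best single parent.  The query is flagged when the
#' chimeric model's global identity exceeds the best single-parent identity
#' by at least `min_div` percentage points and a vote score reaches
#' `min_score`.  Votes are cast per column where the two parents disagree
#' (query matches the model: yes; matches the other parent: no; matches
#' neither: abstain); each side of the breakpoint scores
#' `Y / (Y + xn * N + dn * A)` and the final score is the smaller side, so
#' both parents must contribute signal.
#'
#' @param amplicons an `amplicon_set` from [dereplicate()].
#' @param min_div minimum identity gain of the chimeric model, percentage
#'   points (default 0.8).
#' @param min_score minimum vote score (default 0.28).
#' @param abskew parents must be at least this times more abundant than the
#'   query (default 2).
#' @param xn,dn vote weights for "no" and "abstain" columns (defaults 8 and
#'   1.4).
#' @param top_k with many amplicons, restrict candidate parents to the
#'   `top_k` best k-mer matches, collected per query chunk (8 chunks) so
#'   that both sides of a chimera contribute candidates (default 64).
#' @param exhaustive_below below this number of amplicons all more-abundant
#'   amplicons are candidate parents (default 200).
#' @return data.frame of verdicts: `amplicon_id`, `is_chimera`, `parent_a`,
#'   `parent_b`, `breakpoint`, `score`, `id_single`, `id_chimera`.
#' @export
detect_chimeras <- function(amplicons, min_div = 0.8, min_score = 0.28,
                            abskew = 2, xn = 8, dn = 1.4, top_k = 64,
                            exhaustive_below = 200) {
  stopifnot(inherits(amplicons, "amplicon_set"))
  amp <- amplicons$amplicons
  if (nrow(amp) < 3) {
    return(data.frame(amplicon_id = amp$amplicon_id,
                      is_chimera = FALSE, parent_a = NA_character_,
                      parent_b = NA_character_, breakpoint = NA_integer_,
                      score = 0, id_single = NA_real_, id_chimera = NA_real_,
                      stringsAsFactors = FALSE))
  }
  res <- chimera_scan_cpp(amp$sequence, as.numeric(amp$abundance),
                          abskew, min_div, min_score, xn, dn,
                          as.integer(top_k), as.integer(exhaustive_below))
  data.frame(amplicon_id = amp$amplicon_id,
             is_chimera = res$is_chimera,
             parent_a = amp$amplicon_id[res$parent_a],
             parent_b = amp$amplicon_id[res$parent_b],
             breakpoint = res$breakpoint,
             score = res$score,
             id_single = res$id_single,
             id_chimera = res$id_chimera,
             stringsAsFactors = FALSE)
}

#' Remove flagged chimeras from an amplicon set
#'
#' @param amplicons an `amplicon_set`.
#' @param verdicts verdict table from [detect_chimeras()].
#' @return the filtered `amplicon_set`.
#' @export
remove_chimeras <- function(amplicons, verdicts) {
  bad <- verdicts$amplicon_id[verdicts$is_chimera]
  keep <- !(amplicons$amplicons$amplicon_id %in% bad)
  structure(list(
    amplicons = amplicons$amplicons[keep, , drop = FALSE],
    counts = amplicons$counts[keep, , drop = FALSE],
    read_map = amplicons$read_map[
      !(amplicons$read_map$amplicon_id %in% bad), , drop = FALSE]),
    class = "amplicon_set")
}
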