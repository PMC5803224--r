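# Demultiplexing, primer filtering and trimming of tagged amplicon reads.

#' Demultiplex tagged reads
#'
#' Assigns each read to a sample by comparing its leading tag to the tag map
#' (Hamming distance up to `tolerance`; default exact).  The tag is stripped
#' from assigned reads.  Reads whose tag matches no sample, or more than one
#' sample within the tolerance, are routed to a reject bin with a reason.
#'
#' @param reads data.frame with columns `id` and `sequence`.
#' @param tag_map data.frame with columns `sample_id` and `tag` (all tags of
#'   equal length, pairwise at distance >= 2).
#' @param tolerance maximum Hamming distance between read prefix and tag.
#' @return list with `assigned` (data.frame `id`, `sample_id`, `sequence`
#'   with the tag removed) and `rejected` (data.frame `id`, `reason`).
#' @export
demultiplex <- function(reads, tag_map, tolerance = 0) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)),
            all(c("sample_id", "tag") %in% names(tag_map)))
  if (anyDuplicated(tag_map$tag)) stop("duplicate tags in tag map")
  tag_len <- unique(nchar(tag_map$tag))
  if (length(tag_len) != 1) stop("all tags must have equal length")

  if (nrow(reads) == 0)
    return(list(assigned = data.frame(id = character(0),
                                      sample_id = character(0),
                                      sequence = character(0)),
                rejected = data.frame(id = character(0),
                                      reason = character(0))))
  prefix <- substr(reads$sequence, 1, tag_len)
  pm <- do.call(rbind, strsplit(prefix, "", fixed = TRUE))
  dist <- sapply(tag_map$tag, function(tg) {
    tc <- strsplit(tg, "", fixed = TRUE)[[1]]
    rowSums(pm != matrix(tc, nrow(pm), tag_len, byrow = TRUE))
  })
  if (is.null(dim(dist))) dist <- matrix(dist, nrow = 1)
  hits <- dist <= tolerance
  n_hits <- rowSums(hits)
  best <- max.col(-dist, ties.method = "first")

  ok <- n_hits == 1
  assigned <- data.frame(
    id = reads$id[ok],
    sample_id = tag_map$sample_id[best[ok]],
    sequence = substring(reads$sequence[ok], tag_len + 1),
    stringsAsFactors = FALSE)
  reason <- ifelse(n_hits == 0, "no_tag_match", "ambiguous_tag")
  rejected <- data.frame(id = reads$id[!ok], reason = reason[!ok],
                         stringsAsFactors = FALSE)
  list(assigned = assigned, rejected = rejected)
}

#' Primer and ambiguity quality filter
#'
#' Retains only reads that contain the exact forward primer and no base
#' outside A, C, G, T.
#'
#' @param reads demultiplexed data.frame (`id`, `sample_id`, `sequence`).
#' @param primers primer set, see [foram_primers()].
#' @return list with `retained` (subset of `reads`) and `rejected`
#'   (data.frame `id`, `reason` in `no_forward_primer` / `ambiguous_base`),
#'   plus a `counts` table of rejection reasons.
#' @export
quality_filter <- function(reads, primers = foram_primers()) {
  has_primer <- grepl(primers$forward, reads$sequence, fixed = TRUE)
  clean <- !grepl("[^ACGT]", reads$sequence)
  keep <- has_primer & clean
  reason <- ifelse(!has_primer, "no_forward_primer", "ambiguous_base")
  rejected <- data.frame(id = reads$id[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  list(retained = reads[keep, , drop = FALSE],
       rejected = rejected,
       counts = c(retained = sum(keep), table(rejected$reason)))
}

#' Trim reads at a fixed length after the forward primer
#'
#' Returns, for each read, the `length` bases immediately 3' of the forward
#' primer; reads with fewer than `length` bases after the primer are dropped
#' and reported.  Already-trimmed input (no primer, sequence exactly
#' `length` bp) passes through unchanged, making the operation idempotent.
#'
#' @param reads data.frame that passed [quality_filter()].
#' @param primers primer set.
#' @param length trim length in bp (default 300).
#' @return list with `trimmed` (data.frame, sequences all `length` bp) and
#'   `dropped` (data.frame `id`, `reason`).
#' @export
trim_after_primer <- function(reads, primers = foram_primers(), length = 300) {
  pos <- regexpr(primers$forward, reads$sequence, fixed = TRUE)
  no_primer <- pos < 0
  already <- no_primer & nchar(reads$sequence) == length
  if (any(no_primer & !already))
    stop("forward primer absent from ", sum(no_primer & !already),
         " read(s); run quality_filter first")
  start <- pos + attr(pos, "match.length")
  insert_len <- nchar(reads$sequence) - start + 1L
  insert_len[already] <- length
  keep <- insert_len >= length
  out <- reads[keep, , drop = FALSE]
  idx <- which(keep)
  out$sequence <- ifelse(already[idx], out$sequence,
                         substr(reads$sequence[idx], start[idx],
                                start[idx] + length - 1L))
  list(trimmed = out,
       dropped = data.frame(id = reads$id[!keep],
                            reason = rep("short_after_primer", sum(!keep)),
                            stringsAsFactors = FALSE))
}

#' Fraction of reads that reach the reverse primer
#'
#' Searches the reverse-complemented reverse primer (IUPAC-aware, up to
#' `max_mismatch` mismatches) in the 3' half of each untrimmed read.
#'
#' @param reads data.frame of untrimmed retained reads.
#' @param primers primer set.
#' @param max_mismatch allowed mismatches (default 1; the reverse primer
#'   carries degenerate bases).
#' @return proportion in `[0, 1]`.
#' @export
reverse_primer_fraction <- function(reads, primers = foram_primers(),
                                    max_mismatch = 1) {
  if (nrow(reads) == 0) return(NaN)
  half <- substring(reads$sequence,
                    floor(nchar(reads$sequence) / 2) + 1)
  subj <- Biostrings::DNAStringSet(half)
  pat <- revcomp(primers$reverse)
  hits <- Biostrings::vcountPattern(pat, subj, max.mismatch = max_mismatch,
                                    fixed = FALSE)
  mean(hits > 0)
}
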