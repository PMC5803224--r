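# Reference-database assignment, meta-reference construction and
# reassignment of the full MOTU set.

#' Read an annotated reference FASTA
#'
#' Headers follow the protist reference-database dialect
#' `>id taxonomy=Rank1;Rank2;...;RankN`.
#'
#' @param path FASTA file.
#' @return data.frame with `id`, `sequence`, `path`.
#' @export
read_ref_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  id <- sub("\\s.*$", "", nm)
  tax <- ifelse(grepl("taxonomy=", nm),
                sub("^.*taxonomy=(\\S+).*$", "\\1", nm), NA_character_)
  data.frame(id = id, sequence = as.character(ss), path = tax,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an annotated reference FASTA
#'
#' @param refdb data.frame with `id`, `sequence`, `path`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ref_fasta <- function(refdb, path) {
  ss <- Biostrings::DNAStringSet(setNames(
    refdb$sequence, sprintf("%s taxonomy=%s", refdb$id, refdb$path)))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

default_align_scoring <- function() {
  list(match = 5, mismatch = -4, gap_open = 12, gap_ext = 4)
}

# Needleman-Wunsch global-global alignments of one query against a set of
# references; identity = matching columns / all alignment columns (end gaps
# included).
identity_vs_refs <- function(query, refs, scoring = default_align_scoring()) {
  if (nchar(query) == 0 || any(nchar(refs) == 0))
    stop("empty sequence in global alignment")
  nw_identity_cpp(rep(query, length(refs)), refs,
                  scoring$match, scoring$mismatch,
                  scoring$gap_open, scoring$gap_ext)
}

#' Global alignment percent identity
#'
#' Global-global (Needleman-Wunsch) alignment of two sequences; identity is
#' the number of matching columns over all alignment columns, end gaps
#' included.  Default scoring: match +5, mismatch -4, gap open -12, gap
#' extend -4.
#'
#' @param a,b DNA strings (same barcode region).
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_ext`.
#' @return percent identity in `[0, 100]`.
#' @export
global_identity <- function(a, b, scoring = default_align_scoring()) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  identity_vs_refs(a, b, scoring)
}

#' Best-hit taxonomic assignment
#'
#' Assigns each query to its closest reference by global-alignment identity.
#' Equal-identity best hits sharing the taxonomy path (at `ambiguity_rank`,
#' or the full path when `NULL`) are not ambiguous; conflicting paths set
#' `ambiguous = TRUE`.  When best hits agree at `ambiguity_rank` but differ
#' below it, the path below the deciding rank is replaced by "unresolved".
#'
#' @param queries named character vector of query sequences.
#' @param refdb data.frame with `id`, `sequence`, `path`.
#' @param ambiguity_rank 1-based rank index at which conflicting paths make
#'   an assignment ambiguous, or `NULL` to compare full paths.
#' @param scoring alignment scoring, see [global_identity()].
#' @return data.frame: `query`, `best_hit`, `identity`, `path`, `ambiguous`,
#'   `n_best`.
#' @export
assign_taxonomy <- function(queries, refdb, ambiguity_rank = NULL,
                            scoring = default_align_scoring()) {
  stopifnot(length(queries) > 0, nrow(refdb) > 0)
  if (is.null(names(queries)))
    names(queries) <- sprintf("query%04d", seq_along(queries))
  out <- vector("list", length(queries))
  maxlen <- max(nchar(refdb$sequence)) + max(nchar(queries))
  for (q in seq_along(queries)) {
    # edit-distance prescreen: only references within a few edits of the
    # closest one can reach the best alignment identity
    d <- edit_distance_to_set_cpp(queries[[q]], refdb$sequence, maxlen)
    short <- which(d <= min(d) + 6)
    ident <- identity_vs_refs(queries[[q]], refdb$sequence[short], scoring)
    best <- max(ident)
    tied <- short[ident >= best - 1e-9]
    paths <- refdb$path[tied]
    if (is.null(ambiguity_rank)) {
      keys <- paths
    } else {
      keys <- vapply(split_path(paths), function(p)
        paste(p[seq_len(min(ambiguity_rank, length(p)))], collapse = ";"),
        character(1))
    }
    ambiguous <- length(unique(keys)) > 1
    path <- paths[1]
    if (!ambiguous && length(unique(paths)) > 1) {
      # agreement at the deciding rank, conflict below: mark unresolved
      depth <- length(split_path(paths[1])[[1]])
      stem <- unique(keys)
      path <- paste(c(strsplit(stem, ";")[[1]],
                      rep("unresolved",
                          max(0, depth - ambiguity_rank))), collapse = ";")
    }
    out[[q]] <- data.frame(
      query = names(queries)[q], best_hit = refdb$id[tied[1]],
      identity = best, path = path, ambiguous = ambiguous,
      n_best = length(tied), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Screen out MOTUs assigned to non-foraminiferal eukaryotes
#'
#' MOTUs whose best-hit taxonomy path does not carry `rank_value` at
#' position `rank_index` (level 3 of a PR2-style path) are discarded.
#'
#' @param motus a `motu_set`.
#' @param assignments assignment table from [assign_taxonomy()] with one row
#'   per MOTU (query = motu_id).
#' @param rank_index path position checked (default 3).
#' @param rank_value taxon expected at that position (default
#'   "Foraminifera").
#' @return list with `foram` and `discarded`, both `motu_set`s, plus the
#'   matching assignment subsets.
#' @export
screen_nonforam <- function(motus, assignments, rank_index = 3,
                            rank_value = "Foraminifera") {
  stopifnot(inherits(motus, "motu_set"))
  m <- match(motus$motus$motu_id, assignments$query)
  if (anyNA(m)) stop("assignments missing for some MOTUs")
  is_foram <- path_rank(assignments$path[m], rank_index) == rank_value
  is_foram[is.na(is_foram)] <- FALSE
  list(foram = subset_motus(motus, is_foram),
       discarded = subset_motus(motus, !is_foram),
       foram_assignments = assignments[m[is_foram], , drop = FALSE],
       discarded_assignments = assignments[m[!is_foram], , drop = FALSE])
}

#' Build the meta-reference database
#'
#' Merges the planktonic reference database, benthic references and the
#' delineated environmental MOTU representatives into one database with
#' harmonised 4-rank paths.  Entries sharing a path but diverging more than
#' 5% in sequence trigger a warning; both are kept.
#'
#' @param pfr2_like data.frame `id`, `sequence`, `path` (4-rank paths).
#' @param pr2_benthics optional data.frame of benthic references, same
#'   columns.
#' @param env_reps data.frame of environmental representatives with their
#'   delineated 4-rank `path`.
#' @return data.frame with `id`, `sequence`, `path`, `source`; attribute
#'   `n_paths` holds the number of unique taxonomic paths.
#' @export
build_meta_reference <- function(pfr2_like, pr2_benthics = NULL, env_reps) {
  pieces <- list(
    cbind(pfr2_like[c("id", "sequence", "path")], source = "reference-db"),
    if (!is.null(pr2_benthics) && nrow(pr2_benthics))
      cbind(pr2_benthics[c("id", "sequence", "path")], source = "reference-db"),
    cbind(env_reps[c("id", "sequence", "path")], source = "environmental"))
  meta <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  rownames(meta) <- NULL
  dup <- unique(meta$path[duplicated(meta$path)])
  for (p in dup) {
    seqs <- meta$sequence[meta$path == p]
    L <- min(nchar(seqs))
    ident <- identity_vs_refs(substr(seqs[1], 1, L),
                              substr(seqs[-1], 1, L))
    if (any(ident < 95))
      warning("path ", p, " carried by sequences below 95% identity; ",
              "both kept")
  }
  attr(meta, "n_paths") <- length(unique(meta$path))
  meta
}

#' Reassign every MOTU against the meta-reference and merge by taxon
#'
#' Each MOTU (abundant and rare) is assigned to its closest meta-reference
#' entry on the shared `region` bp; MOTUs above the identity threshold and
#' without ambiguous attribution inherit the hit's 4-rank path, and MOTUs
#' sharing a path are merged by summing their per-sample abundance vectors.
#'
#' @param motus a `motu_set` covering the full foraminiferal MOTU set.
#' @param meta meta-reference from [build_meta_reference()].
#' @param threshold identity threshold in percent (default 95; retained
#'   strictly above unless `inclusive`).
#' @param inclusive if `TRUE`, retain at `>= threshold` instead of
#'   `> threshold`.
#' @param region length in bp of the shared comparison region (default 300).
#' @param ambiguity_rank deciding rank for ambiguity (default 3,
#'   morphospecies of the 4-rank path).
#' @return list: `table` (data.frame `path` + per-sample read counts),
#'   `assignments`, `excluded` (with reasons), `retained_reads`,
#'   `total_reads`.
#' @export
reassign_all <- function(motus, meta, threshold = 95, inclusive = FALSE,
                         region = 300, ambiguity_rank = 3) {
  stopifnot(inherits(motus, "motu_set"))
  queries <- setNames(substr(motus$motus$seed_sequence, 1, region),
                      motus$motus$motu_id)
  refdb <- meta
  refdb$sequence <- substr(refdb$sequence, 1, region)
  asg <- assign_taxonomy(queries, refdb, ambiguity_rank = ambiguity_rank)
  pass_id <- if (inclusive) asg$identity >= threshold else
    asg$identity > threshold
  keep <- pass_id & !asg$ambiguous
  reason <- ifelse(!pass_id, "below_threshold", "ambiguous")
  excluded <- cbind(asg[!keep, , drop = FALSE],
                    reason = reason[!keep])[, c("query", "identity",
                                                "ambiguous", "reason")]
  counts <- motus$counts[keep, , drop = FALSE]
  paths <- asg$path[keep]
  if (nrow(counts)) {
    merged <- rowsum(counts, group = paths)
    table <- data.frame(path = rownames(merged), merged,
                        row.names = NULL, check.names = FALSE,
                        stringsAsFactors = FALSE)
  } else {
    table <- data.frame(path = character(0))
  }
  list(table = table, assignments = asg, excluded = excluded,
       retained_reads = sum(counts),
       total_reads = sum(motus$counts))
}
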