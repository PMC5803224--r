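# End-to-end orchestration of the inference chain on a (simulated or real)
# multiplexed dataset.

#' Run the complete metabarcoding inference chain
#'
#' Demultiplexes and filters the reads, trims at `trim_length` after the
#' forward primer, dereplicates, screens chimeras, clusters amplicons into
#' MOTUs at local threshold `d`, discards MOTUs assigned to non-target
#' eukaryotes, filters by occurrence and abundance, selects representative
#' sequences, delineates genetic types and morphospecies per clade anchored
#' to the reference labels, builds the meta-reference, reassigns the full
#' MOTU set above the identity threshold, and assembles the ecological
#' table.
#'
#' @param reads data.frame `id`, `sequence` (multiplexed, tagged).
#' @param tag_map data.frame `sample_id`, `tag`, `station`, `depth`,
#'   `size_fraction`.
#' @param refdb_pr2 data.frame `id`, `sequence`, `path` with full
#'   (PR2-style) paths; used for the non-target screen and clade placement.
#' @param anchors data.frame of reference sequences anchoring the
#'   delimitation: `id`, `sequence`, `morphogroup`, `morphospecies`,
#'   `genetic_type`, `path` (4-rank).
#' @param primers primer set.
#' @param trim_length trim length after the forward primer (default 300).
#' @param d clustering threshold in differences (default 2).
#' @param min_samples,min_reads MOTU retention thresholds (defaults 3, 10).
#' @param identity_threshold meta-reference retention threshold in percent
#'   (default 95, strict).
#' @param clade_policies passed to [apply_clade_policy()] (named vector,
#'   e.g. `c(Basal = "collapse_genetic_types")`).
#' @param abgd_args list of overrides for [abgd_sweep()].
#' @param exclusion_list optional character vector of MOTU ids excluded
#'   before delineation (manual curation analogue).
#' @return list of class `foram_pipeline` carrying every intermediate stage
#'   and a `summary` of headline counts.
#' @export
run_pipeline <- function(reads, tag_map, refdb_pr2, anchors,
                         primers = foram_primers(), trim_length = 300,
                         d = 2, min_samples = 3, min_reads = 10,
                         identity_threshold = 95, clade_policies = NULL,
                         abgd_args = list(), exclusion_list = NULL) {
  dmx <- demultiplex(reads, tag_map)
  qf <- quality_filter(dmx$assigned, primers)
  rp_frac <- reverse_primer_fraction(qf$retained, primers)
  tr <- trim_after_primer(qf$retained, primers, length = trim_length)
  amp <- dereplicate(tr$trimmed)
  verdicts <- detect_chimeras(amp)
  amp_clean <- remove_chimeras(amp, verdicts)
  motus <- swarm_cluster(amp_clean, d = d)

  asg <- assign_taxonomy(
    setNames(motus$motus$seed_sequence, motus$motus$motu_id),
    data.frame(id = refdb_pr2$id,
               sequence = substr(refdb_pr2$sequence, 1, trim_length),
               path = refdb_pr2$path, stringsAsFactors = FALSE))
  scr <- screen_nonforam(motus, asg)
  filt <- abundance_occurrence_filter(scr$foram, min_samples, min_reads)
  retained <- filt$retained
  if (!is.null(exclusion_list)) {
    keep <- !(retained$motus$motu_id %in% exclusion_list)
    retained <- subset_motus(retained, keep)
  }
  retained <- select_representative(retained, qf$retained, primers)

  # clade of each retained MOTU = morphogroup of its best PR2-style hit
  hit_path <- asg$path[match(retained$motus$motu_id, asg$query)]
  clade <- path_rank(hit_path, 4)
  delins <- list()
  for (cl in unique(clade)) {
    rows <- which(clade == cl)
    anch <- anchors[anchors$morphogroup == cl, , drop = FALSE]
    env_seqs <- setNames(retained$motus$seed_sequence[rows],
                         retained$motus$motu_id[rows])
    ref_seqs <- setNames(substr(anch$sequence, 1, trim_length), anch$id)
    ref_labels <- data.frame(id = anch$id,
                             morphospecies = anch$morphospecies,
                             genetic_type = anch$genetic_type,
                             stringsAsFactors = FALSE)
    delins[[cl]] <- do.call(delineate_clade,
                            c(list(env_seqs = env_seqs, ref_seqs = ref_seqs,
                                   ref_labels = ref_labels,
                                   clade_label = cl), abgd_args))
  }
  assignment <- do.call(rbind, delins)
  rownames(assignment) <- NULL
  class(assignment) <- c("rank_assignment", "data.frame")
  assignment <- apply_clade_policy(assignment, clade_policies)

  # 4-rank paths for the environmental representatives
  env_rows <- !assignment$is_reference
  env_ids <- assignment$id[env_rows]
  genus_of <- function(cl, ms) {
    g <- anchors$genus[anchors$morphogroup == cl &
                         anchors$morphospecies == ms]
    if (length(g)) g[1] else paste0(gsub("[^A-Za-z]", "", cl), "_incertae")
  }
  env_paths <- vapply(which(env_rows), function(i) {
    paste(assignment$clade[i],
          genus_of(assignment$clade[i], assignment$morphospecies[i]),
          assignment$morphospecies[i], assignment$genetic_type[i], sep = ";")
  }, character(1))
  rep_seq <- retained$motus$representative[
    match(env_ids, retained$motus$motu_id)]
  env_reps <- data.frame(id = env_ids, sequence = rep_seq, path = env_paths,
                         stringsAsFactors = FALSE)

  meta <- build_meta_reference(
    pfr2_like = data.frame(id = anchors$id, sequence = anchors$sequence,
                           path = anchors$path, stringsAsFactors = FALSE),
    env_reps = env_reps)
  final <- reassign_all(scr$foram, meta, threshold = identity_threshold,
                        region = trim_length)
  table <- build_table(final, tag_map)

  summary <- list(
    n_raw_reads = nrow(reads),
    n_demultiplexed = nrow(dmx$assigned),
    n_quality_retained = nrow(qf$retained),
    reverse_primer_fraction = rp_frac,
    n_trimmed = nrow(tr$trimmed),
    n_amplicons = nrow(amp$amplicons),
    n_chimeric_amplicons = sum(verdicts$is_chimera),
    n_motus = nrow(motus$motus),
    n_nonforam_motus = nrow(scr$discarded$motus),
    n_foram_motus = nrow(scr$foram$motus),
    n_retained_motus = nrow(retained$motus),
    n_meta_reference = nrow(meta),
    n_meta_paths = attr(meta, "n_paths"),
    n_final_taxa = nrow(table$counts),
    n_genetic_types = length(unique(path_rank(rownames(table$counts), 4))),
    n_morphospecies = length(unique(path_rank(rownames(table$counts), 3))),
    retained_read_fraction = final$retained_reads / final$total_reads)

  structure(list(
    demultiplexed = dmx, quality = qf, trimmed = tr,
    reverse_primer_fraction = rp_frac, amplicons = amp,
    chimera_verdicts = verdicts, amplicons_clean = amp_clean,
    motus = motus, pr2_assignments = asg, screened = scr,
    filtered = filt, retained = retained, delineation = assignment,
    env_reps = env_reps, meta_reference = meta, final = final,
    ecology = table, summary = summary),
    class = "foram_pipeline")
}

#' @export
print.foram_pipeline <- function(x, ...) {
  s <- x$summary
  cat("Metabarcoding inference chain\n")
  cat(sprintf("  raw reads          %8d\n", s$n_raw_reads))
  cat(sprintf("  quality retained   %8d (%.1f%%)\n", s$n_quality_retained,
              100 * s$n_quality_retained / s$n_raw_reads))
  cat(sprintf("  reach rev. primer  %8.2f%%\n",
              100 * s$reverse_primer_fraction))
  cat(sprintf("  MOTUs              %8d (non-target discarded: %d)\n",
              s$n_motus, s$n_nonforam_motus))
  cat(sprintf("  retained MOTUs     %8d\n", s$n_retained_motus))
  cat(sprintf("  final taxa         %8d genetic types in %d morphospecies\n",
              s$n_genetic_types, s$n_morphospecies))
  cat(sprintf("  reads in ecological dataset %.1f%%\n",
              100 * s$retained_read_fraction))
  invisible(x)
}
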