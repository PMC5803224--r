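# Synthetic amplicon-community generator with known ground truth.
#
# Emulates a tagged 454-style survey of planktonic foraminifera: a 4-rank
# taxonomy (Morphogroup|Genus|Morphospecies|GeneticType), reference sequences
# evolved under K80 with tiered divergences and per-morphogroup rate
# multipliers ("long branch" clades), multiplexed primer-flanked reads with
# pyrosequencing-style errors, PCR chimeras, and partial reverse-primer
# coverage.

#' Generate a ground-truth 4-rank taxonomy
#'
#' Builds a hierarchical nomenclature Morphogroup > Genus > Morphospecies >
#' Genetic type with one row per genetic type.  Morphogroups may carry a
#' rate multiplier >= 1 modelling lineages with strongly elevated rDNA
#' substitution rates.
#'
#' @param morphogroups character vector of morphogroup names.
#' @param n_genera number of genera per morphogroup (recycled).
#' @param n_morphospecies number of morphospecies per genus (recycled over
#'   morphogroups).
#' @param n_types number of genetic types per morphospecies (recycled over
#'   morphospecies in order).
#' @param rate_multiplier per-morphogroup rate multiplier (>= 1); by default
#'   morphogroups whose name contains "Long" get 3, others 1.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return A data.frame of class `truth_taxonomy` with columns `morphogroup`,
#'   `genus`, `morphospecies`, `genetic_type`, `path` (semicolon-delimited
#'   4-rank path) and `rate_multiplier`.
#' @export
#' @examples
#' tx <- generate_taxonomy(c("Spinose", "Microperforate"),
#'                         n_genera = 1, n_morphospecies = 2, n_types = 2)
#' nrow(tx)  # 2 x 1 x 2 x 2 = 8 genetic types
generate_taxonomy <- function(morphogroups = c("Spinose", "Non-Spinose",
                                               "Microperforate", "Basal",
                                               "Long-Branch"),
                              n_genera = 1,
                              n_morphospecies = 2,
                              n_types = 2,
                              rate_multiplier = NULL,
                              seed = 1) {
  stopifnot(length(morphogroups) >= 1)
  n_mg <- length(morphogroups)
  n_genera <- rep_len(as.integer(n_genera), n_mg)
  n_morphospecies <- rep_len(as.integer(n_morphospecies), n_mg)
  if (any(n_genera < 1) || any(n_morphospecies < 1) || any(n_types < 1))
    stop("all rank counts must be >= 1")
  if (is.null(rate_multiplier))
    rate_multiplier <- ifelse(grepl("Long", morphogroups), 3, 1)
  rate_multiplier <- rep_len(rate_multiplier, n_mg)
  if (any(rate_multiplier < 1)) stop("rate_multiplier must be >= 1")

  rows <- list()
  n_species_total <- sum(n_genera * n_morphospecies)
  types_per_species <- rep_len(as.integer(n_types), n_species_total)
  sp_i <- 0L
  with_seed(seed, {
    for (m in seq_len(n_mg)) {
      mg <- morphogroups[m]
      for (g in seq_len(n_genera[m])) {
        genus <- sprintf("%s_gen%d", gsub("[^A-Za-z]", "", mg), g)
        for (s in seq_len(n_morphospecies[m])) {
          sp_i <- sp_i + 1L
          species <- sprintf("%s_sp%d", genus, s)
          for (t in seq_len(types_per_species[sp_i])) {
            rows[[length(rows) + 1L]] <- data.frame(
              morphogroup = mg, genus = genus, morphospecies = species,
              genetic_type = sprintf("%s Type %s", species, utils::as.roman(t)),
              rate_multiplier = rate_multiplier[m],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  out$path <- paste(out$morphogroup, out$genus, out$morphospecies,
                    out$genetic_type, sep = ";")
  if (anyDuplicated(out$path)) stop("internal error: duplicated rank paths")
  class(out) <- c("truth_taxonomy", "data.frame")
  out
}

# one K80 substitution step applied to integer-coded sites
k80_evolve_codes <- function(codes, t, kappa = 2) {
  if (t < 0) stop("branch length must be >= 0")
  if (t == 0) return(codes)
  n_events <- rpois(length(codes), t)
  p_ts <- kappa / (kappa + 2)
  rounds <- max(n_events)
  k <- 0L
  while (k < rounds) {
    k <- k + 1L
    active <- which(n_events >= k)
    if (!length(active)) break
    is_ts <- runif(length(active)) < p_ts
    x <- codes[active]
    new <- integer(length(active))
    new[is_ts] <- (x[is_ts] + 2L) %% 4L
    off <- sample(c(1L, 3L), sum(!is_ts), replace = TRUE)
    new[!is_ts] <- (x[!is_ts] + off) %% 4L
    codes[active] <- new
  }
  codes
}

#' Evolve a DNA sequence under the K80 substitution model
#'
#' Applies a Poisson number of substitution events per site (mean =
#' `distance`, in expected substitutions/site); each event is a transition
#' with probability kappa/(kappa + 2), otherwise a transversion to one of the
#' two possible bases.
#'
#' @param sequence DNA string (ACGT).
#' @param distance branch length in expected substitutions per site.
#' @param kappa transition/transversion rate ratio (default 2).
#' @return The evolved DNA string.
#' @export
evolve_sequence <- function(sequence, distance, kappa = 2) {
  codes <- encode_dna(sequence)
  if (anyNA(codes)) stop("sequence must contain only A, C, G, T")
  decode_dna(k80_evolve_codes(codes, distance, kappa))
}

#' Simulate one reference sequence per genetic type
#'
#' Sequences evolve along a star-like hierarchy: morphogroup ancestors
#' diverge from a common root, morphospecies ancestors from their
#' morphogroup ancestor, and genetic types from their morphospecies ancestor,
#' with branch lengths chosen so that the expected pairwise K80 distance is
#' about `divergence_between_types` within a morphospecies and
#' `divergence_between_species` between morphospecies of the same
#' morphogroup.  All branches of a morphogroup are scaled by its rate
#' multiplier.  The genus rank is nomenclatural and adds no divergence.
#'
#' @param taxonomy a `truth_taxonomy` from [generate_taxonomy()].
#' @param root_length reference (amplicon insert) length in bp, >= 350.
#' @param divergence_between_types expected K80 distance between genetic
#'   types of one morphospecies.
#' @param divergence_between_species expected K80 distance between
#'   morphospecies of one morphogroup; must exceed `divergence_between_types`.
#' @param kappa transition/transversion rate ratio.
#' @param seed integer seed.
#' @return A data.frame of class `reference_set`: one row per genetic type
#'   with the taxonomy columns plus `id` and `sequence`.
#' @export
evolve_references <- function(taxonomy, root_length = 500,
                              divergence_between_types = 0.05,
                              divergence_between_species = 0.15,
                              kappa = 2, seed = 1) {
  stopifnot(inherits(taxonomy, "truth_taxonomy"))
  if (root_length < 350) stop("root_length must be >= 350 bp")
  if (!(divergence_between_types < divergence_between_species))
    stop("divergence ordering violated: between-types must be < between-species")
  d_bt <- divergence_between_types
  d_bs <- divergence_between_species
  with_seed(seed, {
    root <- sample(0:3, root_length, replace = TRUE)
    seqs <- character(nrow(taxonomy))
    for (mg in unique(taxonomy$morphogroup)) {
      rows_mg <- which(taxonomy$morphogroup == mg)
      m <- taxonomy$rate_multiplier[rows_mg[1]]
      anc_mg <- k80_evolve_codes(root, d_bs / 2 * m, kappa)
      for (sp in unique(taxonomy$morphospecies[rows_mg])) {
        rows_sp <- rows_mg[taxonomy$morphospecies[rows_mg] == sp]
        anc_sp <- k80_evolve_codes(anc_mg, d_bs / 2 * m, kappa)
        for (i in rows_sp)
          seqs[i] <- decode_dna(k80_evolve_codes(anc_sp, d_bt / 2 * m, kappa))
      }
    }
    out <- as.data.frame(taxonomy)
    out$id <- sprintf("ref%03d", seq_len(nrow(out)))
    out$sequence <- seqs
    class(out) <- c("reference_set", "data.frame")
    out
  })
}

#' Simulate unrelated non-foraminiferal reference sequences
#'
#' Random sequences standing in for other eukaryote lineages co-amplified by
#' the foraminifera-specific primers; used to exercise the non-target
#' screening stage.
#'
#' @param n number of outgroup taxa.
#' @param length sequence length in bp.
#' @param seed integer seed.
#' @return data.frame with `id`, `sequence` and a non-foraminiferal PR2-style
#'   `pr2_path`.
#' @export
outgroup_references <- function(n = 3, length = 500, seed = 1) {
  groups <- c("Alveolata;Dinophyceae", "Stramenopiles;Bacillariophyta",
              "Opisthokonta;Metazoa", "Archaeplastida;Chlorophyta")
  with_seed(seed, {
    data.frame(
      id = sprintf("out%02d", seq_len(n)),
      sequence = vapply(seq_len(n), function(i) random_dna(length), character(1)),
      pr2_path = sprintf("Eukaryota;%s;Outgroup_sp%d;unknown",
                         rep_len(groups, n), seq_len(n)),
      stringsAsFactors = FALSE)
  })
}

#' Design per-sample tags by rejection sampling
#'
#' Tags are drawn uniformly and accepted only if they contain no more than
#' `max_run` consecutive identical nucleotides and differ from every accepted
#' tag at `min_diff` or more positions.
#'
#' @param n number of tags.
#' @param length tag length (default 8 nt).
#' @param min_diff minimum pairwise Hamming distance (default 2).
#' @param max_run maximum homopolymer run allowed inside a tag (default 2).
#' @param seed integer seed.
#' @return character vector of `n` tags.
#' @export
make_tags <- function(n, length = 8, min_diff = 2, max_run = 2, seed = 1) {
  with_seed(seed, {
    tags <- character(0)
    mat <- NULL
    tries <- 0
    while (length(tags) < n) {
      tries <- tries + 1
      if (tries > 100000) stop("tag rejection sampling failed; relax constraints")
      cand <- sample(BASES, length, replace = TRUE)
      r <- rle(cand)
      if (max(r$lengths) > max_run) next
      if (!is.null(mat)) {
        dmin <- min(colSums(t(mat) != cand))
        if (dmin < min_diff) next
      }
      tags <- c(tags, paste(cand, collapse = ""))
      mat <- rbind(mat, cand)
    }
    tags
  })
}

#' Simulation configuration
#'
#' Collects every tunable of the read simulator.  Defaults emulate the
#' structure of a size-fractionated photic-zone survey: 8 stations, surface
#' and deep-chlorophyll-maximum depths, three plankton size fractions,
#' 454-style error rates, 5% PCR chimeras and about a third of reads long
#' enough to reach the reverse primer.
#'
#' @param n_stations number of stations.
#' @param depths depth stratum labels.
#' @param size_fractions size fraction labels.
#' @param reads_per_sample reads generated per sample.
#' @param error_rate_sub per-base substitution error probability.
#' @param homopolymer_indel_rate per-base indel probability inside
#'   homopolymer runs of length >= 3 (pyrosequencing artifact).
#' @param chimera_fraction proportion of reads that are two-parent chimeras.
#' @param divergence_within_type expected pairwise K80 distance among reads
#'   of one genetic type (intra-genomic/population variation).
#' @param divergence_between_types expected distance between genetic types of
#'   a morphospecies.
#' @param divergence_between_species expected distance between morphospecies.
#' @param fraction_full_length proportion of reads that terminate with the
#'   reverse primer.
#' @param outgroup_fraction proportion of reads drawn from non-target taxa.
#' @param kappa transition/transversion rate ratio of the error-free
#'   evolutionary steps.
#' @param clade_weights optional morphogroup x size-fraction weight matrix
#'   biasing community composition per fraction; `NULL` gives the built-in
#'   bias (small fractions dominated by Microperforate/Basal/Long-Branch,
#'   the large fraction by Spinose/Non-Spinose).
#' @param seed integer seed governing every random choice.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_stations = 8,
                       depths = c("SUR", "DCM"),
                       size_fractions = c("20-180", "180-2000", ">0.8"),
                       reads_per_sample = 1000,
                       error_rate_sub = 0.001,
                       homopolymer_indel_rate = 0.002,
                       chimera_fraction = 0.05,
                       divergence_within_type = 0.002,
                       divergence_between_types = 0.05,
                       divergence_between_species = 0.15,
                       fraction_full_length = 0.3222,
                       outgroup_fraction = 0.10,
                       kappa = 2,
                       clade_weights = NULL,
                       seed = 1) {
  rates <- c(error_rate_sub, homopolymer_indel_rate, chimera_fraction,
             fraction_full_length, outgroup_fraction)
  if (any(rates < 0) || any(rates > 1)) stop("all rates must lie in [0, 1]")
  if (!(divergence_within_type < divergence_between_types &&
        divergence_between_types < divergence_between_species))
    stop("divergence tiers must satisfy within < between-types < between-species")
  structure(list(
    n_stations = as.integer(n_stations), depths = depths,
    size_fractions = size_fractions,
    reads_per_sample = as.integer(reads_per_sample),
    error_rate_sub = error_rate_sub,
    homopolymer_indel_rate = homopolymer_indel_rate,
    chimera_fraction = chimera_fraction,
    divergence_within_type = divergence_within_type,
    divergence_between_types = divergence_between_types,
    divergence_between_species = divergence_between_species,
    fraction_full_length = fraction_full_length,
    outgroup_fraction = outgroup_fraction,
    kappa = kappa, clade_weights = clade_weights,
    seed = as.integer(seed)), class = "sim_config")
}

default_clade_weights <- function(morphogroups, size_fractions) {
  w <- matrix(1, length(morphogroups), length(size_fractions),
              dimnames = list(morphogroups, size_fractions))
  small <- !grepl("^180", size_fractions)   # small + bulk fractions
  for (mg in morphogroups) {
    if (grepl("Micro|Basal|Long", mg)) {
      w[mg, small] <- 4; w[mg, !small] <- 0.5
    } else {
      w[mg, small] <- 0.5; w[mg, !small] <- 4
    }
  }
  w
}

# pyrosequencing-style indels: one insertion/deletion per affected
# homopolymer run of length >= 3, probability rate * run_length per run
apply_homopolymer_indels <- function(codes, rate) {
  if (rate <= 0) return(codes)
  r <- rle(codes)
  runs <- which(r$lengths >= 3)
  if (!length(runs)) return(codes)
  hit <- runs[runif(length(runs)) < rate * r$lengths[runs]]
  if (!length(hit)) return(codes)
  r$lengths[hit] <- r$lengths[hit] +
    ifelse(runif(length(hit)) < 0.5, 1L, -1L)
  inverse.rle(r)
}

apply_substitution_errors <- function(codes, rate) {
  if (rate <= 0) return(codes)
  hit <- which(runif(length(codes)) < rate)
  if (!length(hit)) return(codes)
  codes[hit] <- (codes[hit] + sample(1:3, length(hit), replace = TRUE)) %% 4L
  codes
}

#' Simulate a multiplexed tagged amplicon dataset with ground truth
#'
#' Generates reads of the form `tag + forward primer + insert
#' [+ reverse-complemented reverse primer]`.  Inserts derive from the
#' per-genetic-type references with within-type K80 variation, homopolymer
#' indels and uniform substitution errors; a fixed proportion of reads per
#' sample are two-parent chimeras with a single breakpoint placed in the
#' middle 60% of the 300-bp region analysed downstream, parents drawn
#' abundance-weighted from two distinct genetic types; an exact per-sample
#' count of reads (`round(fraction_full_length * n)`) reaches the reverse
#' primer, the rest are truncated.
#'
#' @param references a `reference_set` from [evolve_references()].
#' @param config a [sim_config()].
#' @param outgroups optional data.frame from [outgroup_references()].
#' @param primers primer set, see [foram_primers()].
#' @return list of class `foram_sim` with elements `reads` (data.frame `id`,
#'   `sequence`), `tag_map` (sample_id, tag, station, depth, size_fraction),
#'   `truth` (read_id, sample_id, path, is_chimera, parent_a, parent_b,
#'   breakpoint), `references`, `outgroups`, `config`.
#' @export
simulate_reads <- function(references, config, outgroups = NULL,
                           primers = foram_primers()) {
  stopifnot(inherits(references, "reference_set"),
            inherits(config, "sim_config"))
  if (config$chimera_fraction > 0 && nrow(references) < 2)
    stop("chimeric reads require at least 2 references")

  stations <- sprintf("S%02d", seq_len(config$n_stations))
  grid <- expand.grid(size_fraction = config$size_fractions,
                      depth = config$depths, station = stations,
                      stringsAsFactors = FALSE)[, 3:1]
  grid$sample_id <- sprintf("%s_%s_%s", grid$station, grid$depth,
                            gsub("[^A-Za-z0-9.]", "", grid$size_fraction))
  n_samples <- nrow(grid)

  fwd <- encode_dna(primers$forward)
  # reverse primer may hold IUPAC codes: realise one concrete variant per read
  rev_variants <- iupac_variants(revcomp(primers$reverse))

  mgs <- unique(references$morphogroup)
  cw <- config$clade_weights %||%
    default_clade_weights(mgs, config$size_fractions)

  with_seed(config$seed, {
    tags <- make_tags(n_samples, length = primers$tag_length,
                      seed = sample.int(2^31 - 1, 1))
    tag_map <- data.frame(sample_id = grid$sample_id, tag = tags,
                          station = grid$station, depth = grid$depth,
                          size_fraction = grid$size_fraction,
                          stringsAsFactors = FALSE)

    ref_codes <- lapply(references$sequence, encode_dna)
    out_codes <- if (!is.null(outgroups)) lapply(outgroups$sequence, encode_dna)
    base_abund <- stats::rlnorm(nrow(references), 0, 1)

    reads <- vector("list", n_samples)
    truths <- vector("list", n_samples)
    counter <- 0L
    n <- config$reads_per_sample
    m_rate <- references$rate_multiplier
    half_wt <- config$divergence_within_type / 2

    for (s in seq_len(n_samples)) {
      frac <- grid$size_fraction[s]
      w <- base_abund * cw[references$morphogroup, frac]
      p_type <- w / sum(w)
      n_out <- if (!is.null(outgroups)) round(config$outgroup_fraction * n) else 0L
      n_chim <- round(config$chimera_fraction * (n - n_out))
      n_norm <- n - n_out - n_chim
      kind <- sample(c(rep("norm", n_norm), rep("chim", n_chim),
                       rep("out", n_out)))
      full <- logical(n)
      full[sample.int(n, round(config$fraction_full_length * n))] <- TRUE

      seqs <- character(n)
      tr <- data.frame(read_id = sprintf("r%07d", counter + seq_len(n)),
                       sample_id = grid$sample_id[s],
                       path = NA_character_, is_chimera = FALSE,
                       parent_a = NA_character_, parent_b = NA_character_,
                       breakpoint = NA_integer_, stringsAsFactors = FALSE)
      tag_codes <- encode_dna(tags[s])
      for (i in seq_len(n)) {
        if (kind[i] == "norm") {
          ty <- sample.int(nrow(references), 1, prob = p_type)
          ins <- k80_evolve_codes(ref_codes[[ty]], half_wt * m_rate[ty],
                                  config$kappa)
          tr$path[i] <- references$path[ty]
        } else if (kind[i] == "chim") {
          ab <- sample.int(nrow(references), 2, prob = p_type)
          ta <- k80_evolve_codes(ref_codes[[ab[1]]], half_wt * m_rate[ab[1]],
                                 config$kappa)
          tb <- k80_evolve_codes(ref_codes[[ab[2]]], half_wt * m_rate[ab[2]],
                                 config$kappa)
          bp <- sample(61:240, 1)   # middle 60% of the 300-bp analysis window
          ins <- c(ta[seq_len(bp)], tb[(bp + 1):length(tb)])
          tr$path[i] <- references$path[ab[1]]
          tr$is_chimera[i] <- TRUE
          tr$parent_a[i] <- references$id[ab[1]]
          tr$parent_b[i] <- references$id[ab[2]]
          tr$breakpoint[i] <- bp
        } else {
          og <- sample.int(nrow(outgroups), 1)
          ins <- k80_evolve_codes(out_codes[[og]], half_wt, config$kappa)
          tr$path[i] <- outgroups$pr2_path[og]
        }
        ins <- apply_homopolymer_indels(ins, config$homopolymer_indel_rate)
        if (full[i]) {
          rp <- rev_variants[[sample.int(length(rev_variants), 1)]]
          read <- c(tag_codes, fwd, ins, rp)
        } else {
          keep <- sample(min(250L, length(ins) - 1L):(length(ins) - 1L), 1)
          read <- c(tag_codes, fwd, ins[seq_len(keep)])
        }
        read <- apply_substitution_errors(read, config$error_rate_sub)
        seqs[i] <- decode_dna(read)
      }
      reads[[s]] <- data.frame(id = tr$read_id, sequence = seqs,
                               stringsAsFactors = FALSE)
      truths[[s]] <- tr
      counter <- counter + n
    }
    structure(list(reads = do.call(rbind, reads),
                   tag_map = tag_map,
                   truth = do.call(rbind, truths),
                   references = references,
                   outgroups = outgroups,
                   config = config),
              class = "foram_sim")
  })
}

# enumerate the concrete ACGT variants of a short IUPAC string (few codes)
iupac_variants <- function(x) {
  amb <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  combos <- expand.grid(lapply(chars, function(c) amb[[c]]),
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(combos)),
         function(i) match(unlist(combos[i, ]), BASES) - 1L)
}

#' Write a simulated dataset to disk
#'
#' Emits the multiplexed reads as FASTA, the tag map and the ground truth as
#' TSV, and the reference databases as annotated FASTA
#' (`>id taxonomy=...` headers).
#'
#' @param sim a `foram_sim` from [simulate_reads()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "foram_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ss <- Biostrings::DNAStringSet(setNames(sim$reads$sequence, sim$reads$id))
  Biostrings::writeXStringSet(ss, file.path(dir, "reads.fasta"))
  utils::write.table(sim$tag_map, file.path(dir, "tags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  refs <- sim$references
  write_ref_fasta(data.frame(id = refs$id, sequence = refs$sequence,
                             path = pr2_paths(refs)),
                  file.path(dir, "refdb_pr2like.fasta"))
  invisible(dir)
}

#' PR2-style full taxonomic paths for foraminiferal references
#'
#' Prefixes the 4-rank path with the higher ranks so that Foraminifera sits
#' at level 3, as in protist ribosomal reference databases.
#'
#' @param references a `reference_set`.
#' @return character vector of paths.
#' @export
pr2_paths <- function(references) {
  paste("Eukaryota", "Rhizaria", "Foraminifera", references$path, sep = ";")
}
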