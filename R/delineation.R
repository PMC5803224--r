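# K80 distances, barcode-gap prior sweep, plateau detection and the
# reference-anchored two-rank selection that produces the 4-rank
# nomenclature.

k80_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K80 saturation: substitution proportions too large (P=",
         signif(P, 4), ", Q=", signif(Q, 4), ")")
  -0.5 * log(w1 * sqrt(w2))
}

#' Kimura (1980) two-parameter distance
#'
#' `d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]` with P and Q the proportions of
#' transition and transversion differences over the compared sites.  Sites
#' with a gap or ambiguity in either sequence are excluded (pairwise
#' deletion); fewer than `min_sites` comparable sites triggers a warning.
#'
#' @param a,b equal-length strings over the same region (gaps `-` allowed).
#' @param min_sites minimum ungapped sites for a reliable distance
#'   (default 100).
#' @return distance in substitutions/site.
#' @export
k80_distance <- function(a, b, min_sites = 100) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb))
    stop("sequences must cover the same region (equal length)")
  ok <- ca %in% BASES & cb %in% BASES
  n <- sum(ok)
  if (n == 0) stop("no comparable sites")
  if (n < min_sites)
    warning("only ", n, " comparable sites; distance unreliable")
  ia <- match(ca[ok], BASES) - 1L
  ib <- match(cb[ok], BASES) - 1L
  diff <- ia != ib
  transition <- diff & (ia %% 2L == ib %% 2L)  # purine<->purine, pyr<->pyr
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  k80_from_pq(P, Q)
}

#' Pairwise K80 distance matrix
#'
#' @param seqs named character vector of equal-length sequences.
#' @param min_sites see [k80_distance()].
#' @return symmetric matrix of distances; saturated pairs become `NA` with a
#'   warning.
#' @export
k80_matrix <- function(seqs, min_sites = 100) {
  n <- length(seqs)
  stopifnot(n >= 2)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%04d", seq_len(n))
  enc <- lapply(seqs, function(s) {
    m <- match(strsplit(s, "", fixed = TRUE)[[1]], BASES) - 1L
    m
  })
  L <- unique(lengths(enc))
  if (length(L) != 1) stop("sequences must cover the same region")
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  saturated <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ia <- enc[[i]]; ib <- enc[[j]]
      ok <- !is.na(ia) & !is.na(ib)
      m <- sum(ok)
      d <- if (m == 0) NA_real_ else {
        da <- ia[ok]; db <- ib[ok]
        diff <- da != db
        ts <- sum(diff & (da %% 2L == db %% 2L))
        tv <- sum(diff) - ts
        w1 <- 1 - 2 * ts / m - tv / m
        w2 <- 1 - 2 * tv / m
        if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1 * sqrt(w2))
      }
      if (is.na(d)) saturated <- saturated + 1L
      D[i, j] <- d; D[j, i] <- d
    }
  }
  if (saturated > 0)
    warning(saturated, " pair(s) saturated or incomparable (NA)")
  D
}

# Recursive barcode-gap partitioning of one group at prior P: find the first
# interval in the sorted distance list whose upper end exceeds P and whose
# width exceeds X times the running mean of the distances below it, cut
# there, and recurse into the resulting subgroups.
gap_split <- function(D, idx, P, X, depth, max_depth = 10) {
  if (length(idx) < 3 || depth > max_depth) return(list(idx))
  d <- D[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
  d <- sort(d)
  dd <- unique(d)
  if (length(dd) < 2) return(list(idx))
  thr <- NA_real_
  for (i in seq_len(length(dd) - 1)) {
    lo <- dd[i]; hi <- dd[i + 1]
    if (hi <= P) next
    below_mean <- mean(d[d <= lo])
    if ((hi - lo) > X * below_mean) { thr <- lo; break }
  }
  if (is.na(thr)) return(list(idx))
  sub <- D[idx, idx, drop = FALSE]
  comp <- components_from_adjacency(sub <= thr & upper_or_lower(sub))
  if (max(comp) == 1) return(list(idx))
  out <- list()
  for (k in seq_len(max(comp)))
    out <- c(out, gap_split(D, idx[comp == k], P, X, depth + 1, max_depth))
  out
}

upper_or_lower <- function(m) {
  diag(m) <- NA
  !is.na(m)
}

#' Sweep barcode-gap partitions over a grid of prior divergences
#'
#' For each prior P on a log-spaced grid the distance list is scanned for
#' the first gap above P whose width exceeds `relative_gap` times the
#' running mean of the distances below it; sequences linked below the gap
#' form groups, and the scan is applied recursively within groups.
#'
#' @param D symmetric K80 distance matrix (finite entries).
#' @param Pmin,Pmax prior range (defaults 0.001 and 0.2).
#' @param steps number of priors (default 100).
#' @param relative_gap relative gap width X (default 0.5).
#' @return list of class `partition_series`: `priors` (increasing),
#'   `partitions` (steps x n matrix of canonical group labels), `ids`.
#' @export
abgd_sweep <- function(D, Pmin = 0.001, Pmax = 0.2, steps = 100,
                       relative_gap = 0.5) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (!(Pmin > 0 && Pmin < Pmax)) stop("need 0 < Pmin < Pmax")
  if (any(!is.finite(D))) stop("distance matrix must be finite")
  n <- nrow(D)
  ids <- rownames(D) %||% sprintf("seq%04d", seq_len(n))
  priors <- exp(seq(log(Pmin), log(Pmax), length.out = steps))
  parts <- matrix(NA_integer_, steps, n, dimnames = list(NULL, ids))
  for (s in seq_len(steps)) {
    groups <- gap_split(D, seq_len(n), priors[s], relative_gap, 1)
    lab <- integer(n)
    for (k in seq_along(groups)) lab[groups[[k]]] <- k
    parts[s, ] <- canonical_partition(lab)
  }
  structure(list(priors = priors, partitions = parts, ids = ids),
            class = "partition_series")
}

#' Detect plateaus in a partition series
#'
#' Plateaus are maximal runs of consecutive priors yielding the identical
#' partition.
#'
#' @param series a `partition_series` from [abgd_sweep()].
#' @return data.frame: `plateau`, `prior_lo`, `prior_hi`, `span` (number of
#'   consecutive priors), `n_groups`; attribute `partitions` holds one
#'   canonical label vector per plateau.
#' @export
detect_plateaus <- function(series) {
  stopifnot(inherits(series, "partition_series"))
  keys <- apply(series$partitions, 1, paste, collapse = ",")
  r <- rle(keys)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  parts <- lapply(starts, function(s) series$partitions[s, ])
  out <- data.frame(
    plateau = seq_along(r$lengths),
    prior_lo = series$priors[starts],
    prior_hi = series$priors[ends],
    span = r$lengths,
    n_groups = vapply(parts, function(p) as.integer(max(p)), integer(1)))
  attr(out, "partitions") <- parts
  attr(out, "ids") <- series$ids
  out
}

refines <- function(fine, coarse) {
  all(tapply(coarse, fine, function(x) length(unique(x))) == 1)
}

plateau_admissible <- function(part, ref_idx, key) {
  # no group may contain two references with different values of `key`
  g <- part[ref_idx]
  all(tapply(key, g, function(x) length(unique(x))) == 1)
}

#' Select the genetic-type and morphospecies levels among plateaus
#'
#' Anchored to the reference sequences' known two-rank labels: the
#' morphospecies level is the admissible plateau (never co-clustering
#' references of distinct morphospecies) with the fewest groups; the
#' genetic-type level is the admissible plateau (never co-clustering
#' references of distinct genetic types of the same morphospecies) with the
#' fewest groups among those refining the chosen morphospecies partition.
#' Environmental sequences inherit labels from co-clustered references and
#' otherwise receive new labels in the style "<clade> A" / "<species> Type
#' N".
#'
#' @param plateaus plateau table from [detect_plateaus()].
#' @param ref_labels data.frame with `id`, `morphospecies`, `genetic_type`
#'   for the reference sequences present in the series.
#' @param plateau_rule `"coarsest_admissible"` (fewest groups, default) or
#'   `"longest_span_admissible"`.
#' @param clade_label clade name used to label novel morphospecies.
#' @return data.frame of class `rank_assignment`: `id`, `genetic_type`,
#'   `morphospecies`, `is_reference`, `clade`; attributes record the chosen
#'   plateau indices and whether the fallback to the finest partition fired.
#' @export
select_ranks <- function(plateaus, ref_labels,
                         plateau_rule = c("coarsest_admissible",
                                          "longest_span_admissible"),
                         clade_label = "Clade") {
  plateau_rule <- match.arg(plateau_rule)
  parts <- attr(plateaus, "partitions")
  ids <- attr(plateaus, "ids")
  ref_idx <- match(ref_labels$id, ids)
  if (anyNA(ref_idx)) stop("reference ids missing from the series")

  adm_ms <- vapply(parts, plateau_admissible, logical(1),
                   ref_idx = ref_idx, key = ref_labels$morphospecies)
  # genetic-type rule: within one morphospecies, types must stay separate
  adm_gt <- vapply(parts, function(p) {
    g <- p[ref_idx]
    key <- paste(ref_labels$morphospecies, ref_labels$genetic_type)
    for (sp in unique(ref_labels$morphospecies)) {
      rows <- ref_labels$morphospecies == sp
      if (any(tapply(key[rows], g[rows],
                     function(x) length(unique(x))) != 1)) return(FALSE)
    }
    TRUE
  }, logical(1))

  pick <- function(adm, must_refine = NULL) {
    cand <- which(adm)
    if (!is.null(must_refine))
      cand <- cand[vapply(parts[cand], refines, logical(1),
                          coarse = must_refine)]
    if (!length(cand)) return(NA_integer_)
    score <- if (plateau_rule == "coarsest_admissible")
      order(plateaus$n_groups[cand], -plateaus$span[cand])
    else order(-plateaus$span[cand], plateaus$n_groups[cand])
    cand[score[1]]
  }

  fallback <- FALSE
  ms_i <- pick(adm_ms)
  if (is.na(ms_i)) {
    warning("no admissible morphospecies plateau; falling back to finest")
    ms_i <- which.max(plateaus$n_groups)
    fallback <- TRUE
  }
  ms_part <- parts[[ms_i]]
  gt_i <- pick(adm_gt, must_refine = ms_part)
  if (is.na(gt_i)) {
    warning("no admissible genetic-type plateau refining the morphospecies",
            " level; falling back to finest")
    gt_i <- which.max(plateaus$n_groups)
    fallback <- TRUE
  }
  gt_part <- parts[[gt_i]]

  # morphospecies labels per MS group
  ms_names <- character(max(ms_part))
  novel <- 0
  for (g in seq_len(max(ms_part))) {
    refs_in <- ref_labels$morphospecies[ms_part[ref_idx] == g]
    if (length(refs_in)) {
      ms_names[g] <- refs_in[1]
    } else {
      novel <- novel + 1
      ms_names[g] <- sprintf("%s %s", clade_label, LETTERS[novel])
    }
  }
  # genetic-type labels per GT group
  gt_names <- character(max(gt_part))
  per_ms_new <- list()
  for (g in seq_len(max(gt_part))) {
    refs_in <- ref_labels$genetic_type[gt_part[ref_idx] == g]
    if (length(refs_in)) {
      gt_names[g] <- refs_in[1]
    } else {
      ms_of_g <- ms_names[ms_part[match(g, gt_part)]]
      k <- (per_ms_new[[ms_of_g]] %||% 0) + 1
      per_ms_new[[ms_of_g]] <- k
      gt_names[g] <- sprintf("%s Type %s", ms_of_g, utils::as.roman(k))
    }
  }
  out <- data.frame(
    id = ids,
    genetic_type = gt_names[gt_part],
    morphospecies = ms_names[ms_part],
    is_reference = ids %in% ref_labels$id,
    clade = clade_label,
    stringsAsFactors = FALSE)
  class(out) <- c("rank_assignment", "data.frame")
  attr(out, "ms_plateau") <- ms_i
  attr(out, "gt_plateau") <- gt_i
  attr(out, "fallback") <- fallback
  out
}

#' Collapse genetic types within designated clades
#'
#' Conservative policy for clades whose reference material carries no
#' molecular taxonomy (high intragenomic variability): genetic types are set
#' equal to the morphospecies label, so no sub-species diversity is claimed.
#'
#' @param assignment a `rank_assignment`.
#' @param clade_policies named character vector, e.g.
#'   `c(Basal = "collapse_genetic_types")`.
#' @return the modified `rank_assignment`.
#' @export
apply_clade_policy <- function(assignment, clade_policies = NULL) {
  if (is.null(clade_policies) || !length(clade_policies)) return(assignment)
  unknown <- setdiff(names(clade_policies), unique(assignment$clade))
  if (length(unknown))
    stop("unknown clade(s) in policy: ", paste(unknown, collapse = ", "))
  for (cl in names(clade_policies)) {
    if (clade_policies[[cl]] != "collapse_genetic_types") next
    rows <- assignment$clade == cl
    assignment$genetic_type[rows] <- assignment$morphospecies[rows]
  }
  assignment
}

#' Validate a two-rank delimitation with patristic distances
#'
#' Pairwise patristic distances (sums of branch lengths on the tree) are
#' partitioned into intra-genetic-type, inter-genetic-type-intra-species and
#' inter-species classes, and consecutive classes are compared with
#' two-sample Kolmogorov-Smirnov and Mann-Whitney tests.
#'
#' @param tree an `ape` phylo object or path to a newick file; tips must
#'   cover the assigned sequences.
#' @param assignment a `rank_assignment`.
#' @return list: `distances` (data.frame `a`, `b`, `class`, `distance`) and
#'   `tests` (data.frame of statistic and p-value per class pair and test).
#' @export
patristic_validation <- function(tree, assignment) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(assignment$id, tree$tip.label)
  if (length(missing))
    stop("tips missing from tree: ", paste(missing, collapse = ", "))
  D <- ape::cophenetic.phylo(tree)[assignment$id, assignment$id]
  n <- nrow(assignment)
  pr <- which(upper.tri(D), arr.ind = TRUE)
  a <- assignment$id[pr[, 1]]; b <- assignment$id[pr[, 2]]
  same_gt <- assignment$genetic_type[pr[, 1]] ==
    assignment$genetic_type[pr[, 2]]
  same_ms <- assignment$morphospecies[pr[, 1]] ==
    assignment$morphospecies[pr[, 2]]
  cls <- ifelse(same_gt, "intra_genetic_type",
                ifelse(same_ms, "inter_genetic_type", "inter_species"))
  distances <- data.frame(a = a, b = b, class = cls,
                          distance = D[pr], stringsAsFactors = FALSE)
  pairs <- list(c("intra_genetic_type", "inter_genetic_type"),
                c("inter_genetic_type", "inter_species"))
  tests <- list()
  for (p in pairs) {
    x <- distances$distance[distances$class == p[1]]
    y <- distances$distance[distances$class == p[2]]
    if (!length(x) || !length(y)) next
    ks <- suppressWarnings(ks.test(x, y))
    mw <- suppressWarnings(wilcox.test(x, y))
    tests[[length(tests) + 1]] <- data.frame(
      lower_class = p[1], upper_class = p[2],
      ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
      mw_statistic = unname(mw$statistic), mw_p = mw$p.value)
  }
  list(distances = distances,
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}

#' Delineate one clade: distances, sweep, plateaus, rank selection
#'
#' Convenience wrapper running [k80_matrix()], [abgd_sweep()],
#' [detect_plateaus()] and [select_ranks()] on the reference and
#' environmental sequences of one crown group.
#'
#' @param env_seqs named character vector of environmental sequences.
#' @param ref_seqs named character vector of reference sequences.
#' @param ref_labels data.frame `id`, `morphospecies`, `genetic_type`.
#' @param clade_label clade name for novel labels.
#' @param ... passed to [abgd_sweep()] / [select_ranks()].
#' @param plateau_rule see [select_ranks()].
#' @return a `rank_assignment` for all sequences of the clade.
#' @export
delineate_clade <- function(env_seqs, ref_seqs, ref_labels,
                            clade_label = "Clade",
                            plateau_rule = "coarsest_admissible", ...) {
  seqs <- c(ref_seqs, env_seqs)
  if (length(seqs) < 3) {
    # too few sequences to scan for a gap: everything inherits from the
    # nearest reference at both ranks, or forms one novel group
    lab <- if (nrow(ref_labels)) ref_labels[1, ] else
      data.frame(morphospecies = paste(clade_label, "A"),
                 genetic_type = paste(clade_label, "A Type I"))
    out <- data.frame(id = names(seqs),
                      genetic_type = lab$genetic_type[1],
                      morphospecies = lab$morphospecies[1],
                      is_reference = names(seqs) %in% ref_labels$id,
                      clade = clade_label, stringsAsFactors = FALSE)
    class(out) <- c("rank_assignment", "data.frame")
    return(out)
  }
  D <- k80_matrix(seqs)
  series <- abgd_sweep(D, ...)
  plateaus <- detect_plateaus(series)
  select_ranks(plateaus, ref_labels, plateau_rule = plateau_rule,
               clade_label = clade_label)
}
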