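# Final taxon x sample table, rarefaction, occurrence and clade
# composition summaries.

#' Build the ecological taxon-by-sample table
#'
#' @param final output of [reassign_all()] (merged taxon table).
#' @param tag_map sample metadata (`sample_id`, `station`, `depth`,
#'   `size_fraction`).
#' @return list of class `ecology_table`: `counts` (taxa x samples integer
#'   matrix, rownames = 4-rank paths) and `samples` (metadata data.frame in
#'   column order).
#' @export
build_table <- function(final, tag_map) {
  tab <- final$table
  if (nrow(tab) == 0) stop("no retained taxa")
  counts <- as.matrix(tab[, setdiff(names(tab), "path"), drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- tab$path
  meta <- tag_map[match(colnames(counts), tag_map$sample_id), ,
                  drop = FALSE]
  if (anyNA(meta$sample_id)) stop("samples missing from tag map")
  structure(list(counts = counts, samples = meta), class = "ecology_table")
}

#' Expected richness in a random subsample (analytic rarefaction)
#'
#' `E[S_n] = sum_i [1 - C(N - N_i, n) / C(N, n)]`, the individual-based
#' (hypergeometric) rarefaction expectation; deterministic, no resampling.
#'
#' @param counts integer vector of per-taxon read counts.
#' @param n subsample depth(s); must not exceed `sum(counts)`.
#' @return expected richness, one value per depth.
#' @export
rarefy_expected <- function(counts, n) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(n > N)) stop("subsample depth exceeds total reads (", N, ")")
  if (any(n < 0)) stop("subsample depth must be >= 0")
  vapply(n, function(k) {
    if (k == 0) return(0)
    # vegan warns about singleton-free counts; irrelevant for an expectation
    suppressWarnings(unname(vegan::rarefy(matrix(counts, nrow = 1),
                                          sample = k)))
  }, numeric(1))
}

#' Rarefaction curves per stratum
#'
#' Pools samples by stratum (station, depth, size fraction, individual
#' sample, or the total dataset) and evaluates the analytic rarefaction
#' expectation on a grid of depths.
#'
#' @param table an `ecology_table`.
#' @param stratum one of `"station"`, `"depth"`, `"size_fraction"`,
#'   `"sample"`, `"total"`.
#' @param step depth grid spacing in reads (default 100); each curve is also
#'   evaluated at its stratum's full depth.
#' @return data.frame: `stratum`, `depth`, `expected_richness`.
#' @export
rarefaction_curve <- function(table, stratum = c("total", "station", "depth",
                                                 "size_fraction", "sample"),
                              step = 100) {
  stopifnot(inherits(table, "ecology_table"))
  stratum <- match.arg(stratum)
  groups <- switch(stratum,
    total = rep("total", ncol(table$counts)),
    sample = table$samples$sample_id,
    table$samples[[stratum]])
  pooled <- rowsum(t(table$counts), group = groups)  # stratum x taxa
  out <- list()
  for (g in rownames(pooled)) {
    cnt <- pooled[g, ]
    N <- sum(cnt)
    depths <- unique(c(seq(step, N, by = step), N))
    depths <- depths[depths >= 1]
    out[[g]] <- data.frame(stratum = g, depth = depths,
                           expected_richness = rarefy_expected(cnt, depths),
                           stringsAsFactors = FALSE)
  }
  rn <- do.call(rbind, out)
  rownames(rn) <- NULL
  rn
}

#' Relative clade composition per size fraction
#'
#' Computes, per sample, the relative read proportion of each clade, grouped
#' by size fraction; an optional table of surface-sediment census
#' proportions is appended as an extra pseudo-fraction for side-by-side
#' comparison.
#'
#' @param table an `ecology_table`.
#' @param clade_map named character vector mapping each taxon path to a
#'   clade; by default the first rank of the path (the morphogroup).
#' @param sediment_counts optional data.frame with columns `clade` and
#'   `count` (or `proportion`).
#' @return data.frame: `sample_id`, `station`, `depth`, `size_fraction`,
#'   `clade`, `proportion`; proportions sum to 1 per sample.
#' @export
composition_by_fraction <- function(table, clade_map = NULL,
                                    sediment_counts = NULL) {
  stopifnot(inherits(table, "ecology_table"))
  paths <- rownames(table$counts)
  if (is.null(clade_map)) {
    clade_map <- setNames(path_rank(paths, 1), paths)
  } else {
    unmapped <- setdiff(paths, names(clade_map))
    if (length(unmapped))
      stop("taxa missing from clade map: ", paste(unmapped, collapse = ", "))
  }
  clades <- clade_map[paths]
  by_clade <- rowsum(table$counts, group = clades)  # clade x sample
  out <- list()
  for (s in seq_len(ncol(by_clade))) {
    tot <- sum(by_clade[, s])
    if (tot == 0) next
    out[[length(out) + 1]] <- data.frame(
      sample_id = colnames(by_clade)[s],
      station = table$samples$station[s],
      depth = table$samples$depth[s],
      size_fraction = table$samples$size_fraction[s],
      clade = rownames(by_clade),
      proportion = by_clade[, s] / tot,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (!is.null(sediment_counts)) {
    val <- sediment_counts$count %||% sediment_counts$proportion
    res <- rbind(res, data.frame(
      sample_id = "sediment", station = NA, depth = NA,
      size_fraction = "sediment", clade = sediment_counts$clade,
      proportion = val / sum(val), stringsAsFactors = FALSE))
  }
  rownames(res) <- NULL
  res
}

#' Per-taxon occurrence and stratified abundance shares
#'
#' For every taxon: the number of samples where it occurs and the share of
#' its reads falling in each depth and size-fraction stratum.  Taxa absent
#' from every sample are dropped with a warning.
#'
#' @param table an `ecology_table`.
#' @return data.frame with one row per taxon: `path`, `n_samples`,
#'   `total_reads`, one `share_depth_*` column per depth and one
#'   `share_fraction_*` column per size fraction.
#' @export
occurrence_profiles <- function(table) {
  stopifnot(inherits(table, "ecology_table"))
  cnt <- table$counts
  tot <- rowSums(cnt)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " taxa absent from every sample dropped")
    cnt <- cnt[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  out <- data.frame(path = rownames(cnt),
                    n_samples = rowSums(cnt > 0),
                    total_reads = tot,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (d in unique(table$samples$depth)) {
    cols <- table$samples$depth == d
    out[[paste0("share_depth_", d)]] <-
      rowSums(cnt[, cols, drop = FALSE]) / tot
  }
  for (f in unique(table$samples$size_fraction)) {
    cols <- table$samples$size_fraction == f
    out[[paste0("share_fraction_", gsub("[^A-Za-z0-9.]", "", f))]] <-
      rowSums(cnt[, cols, drop = FALSE]) / tot
  }
  out
}

#' Plot rarefaction curves
#'
#' Minimal base-graphics display of [rarefaction_curve()] output, one line
#' per stratum.
#'
#' @param curves data.frame from [rarefaction_curve()].
#' @param ... passed to [plot()].
#' @return invisibly, `NULL`.
#' @export
plot_rarefaction <- function(curves, ...) {
  strata <- unique(curves$stratum)
  graphics::plot(NA, xlim = range(curves$depth),
                 ylim = range(curves$expected_richness),
                 xlab = "reads", ylab = "expected richness", ...)
  for (i in seq_along(strata)) {
    d <- curves[curves$stratum == strata[i], ]
    graphics::lines(d$depth, d$expected_richness, col = i)
  }
  graphics::legend("bottomright", legend = strata, col = seq_along(strata),
                   lty = 1, cex = 0.7)
  invisible(NULL)
}
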