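test_that("taxonomy generation multiplies rank counts, is deterministic, rejects zeros", {
  tx <- generate_taxonomy(c("Alpha", "Beta"), n_genera = 1,
                          n_morphospecies = 2, n_types = 2,
                          rate_multiplier = 1)
  expect_equal(nrow(tx), 8)
  expect_equal(anyDuplicated(tx$path), 0L)
  expect_true(all(tapply(tx$morphospecies, tx$genetic_type,
                         function(x) length(unique(x))) == 1))

  expect_identical(generate_taxonomy(seed = 99), generate_taxonomy(seed = 99))
  expect_equal(nrow(generate_taxonomy("X", 1, 1, 1, 1)), 1)
  expect_error(generate_taxonomy("X", 0, 1, 1), "counts")
  expect_error(generate_taxonomy("X", 1, 1, 1, rate_multiplier = 0.5),
               "rate_multiplier")
})

test_that("reference evolution reproduces its generative divergences", {
  tx <- generate_taxonomy("X", 1, 1, 2, rate_multiplier = 1)
  refs0 <- evolve_references(tx, root_length = 400,
                             divergence_between_types = 0,
                             divergence_between_species = 0.1, seed = 3)
  expect_identical(refs0$sequence[1], refs0$sequence[2])

  expect_error(evolve_references(tx, divergence_between_types = 0.2,
                                 divergence_between_species = 0.1),
               "ordering")

  # Monte-Carlo: two lineages at 0.05 expected substitutions/site
  set.seed(11)
  d <- replicate(100, {
    root <- rand_seq(500)
    k80_distance(evolve_sequence(root, 0.025), evolve_sequence(root, 0.025))
  })
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.05), 3 * se)
})

test_that("rate multiplier scales distances by about that factor", {
  tx <- generate_taxonomy(c("Slow", "Fast"), n_genera = 1,
                          n_morphospecies = 3, n_types = 1,
                          rate_multiplier = c(1, 3))
  ratios <- vapply(1:8, function(s) {
    refs <- evolve_references(tx, root_length = 1000,
                              divergence_between_species = 0.1, seed = s)
    dist_in <- function(mg) {
      rows <- which(refs$morphogroup == mg)
      mean(utils::combn(rows, 2, function(p)
        k80_distance(refs$sequence[p[1]], refs$sequence[p[2]])))
    }
    dist_in("Fast") / dist_in("Slow")
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 3), 0.6)
})

test_that("read simulation bookkeeping, determinism, exact full-length count", {
  tx <- generate_taxonomy(c("P", "Q"), 1, 2, 2, rate_multiplier = 1)
  refs <- evolve_references(tx, seed = 5)
  cfg <- sim_config(n_stations = 1, depths = "SUR",
                    size_fractions = c("20-180", "180-2000"),
                    reads_per_sample = 400, chimera_fraction = 0,
                    outgroup_fraction = 0, seed = 21)
  sim <- simulate_reads(refs, cfg)
  expect_equal(nrow(sim$truth), 2 * 400)
  expect_identical(sim$truth$read_id, sim$reads$id)
  expect_false(any(sim$truth$is_chimera))
  expect_identical(simulate_reads(refs, cfg), sim)

  expect_error(simulate_reads(refs[1, ], sim_config(chimera_fraction = 0.5)),
               "at least 2 references")

  # the configured fraction of reads reaches the reverse primer
  cfg2 <- sim_config(n_stations = 2, depths = "SUR",
                     size_fractions = c("a", "b"), reads_per_sample = 2500,
                     error_rate_sub = 0, homopolymer_indel_rate = 0,
                     chimera_fraction = 0, outgroup_fraction = 0,
                     fraction_full_length = 0.32, seed = 9)
  sim2 <- simulate_reads(refs, cfg2)
  obs <- reverse_primer_fraction(sim2$reads)
  ci <- 2.576 * sqrt(0.32 * 0.68 / 10000)
  expect_lt(abs(obs - 0.32), ci + 1e-4)
})

test_that("tag design honours pairwise distance and homopolymer constraints", {
  tags <- make_tags(32, seed = 4)
  expect_equal(length(unique(tags)), 32)
  mat <- do.call(rbind, strsplit(tags, ""))
  for (i in 1:31) for (j in (i + 1):32)
    expect_gte(sum(mat[i, ] != mat[j, ]), 2)
  runs <- vapply(strsplit(tags, ""), function(x) max(rle(x)$lengths),
                 integer(1))
  expect_true(all(runs <= 2))
})

test_that("tiered divergences produce a clean barcode gap", {
  within <- c(); btype <- c(); bspec <- c()
  for (s in 1:10) {
    tx <- generate_taxonomy("G", 1, 4, 3, rate_multiplier = 1)
    refs <- evolve_references(tx, root_length = 500, seed = s)
    set.seed(s)
    for (i in seq_len(nrow(refs))) {
      a <- evolve_sequence(refs$sequence[i], 0.001)
      b <- evolve_sequence(refs$sequence[i], 0.001)
      within <- c(within, k80_distance(a, b))
    }
    for (sp in unique(refs$morphospecies)) {
      rows <- which(refs$morphospecies == sp)
      btype <- c(btype, utils::combn(rows, 2, function(p)
        k80_distance(refs$sequence[p[1]], refs$sequence[p[2]])))
    }
    sp1 <- which(refs$morphospecies == refs$morphospecies[1])
    other <- which(refs$morphospecies != refs$morphospecies[1])
    for (i in sp1) bspec <- c(bspec, vapply(other, function(j)
      k80_distance(refs$sequence[i], refs$sequence[j]), numeric(1)))
  }
  expect_gte(length(within), 100)
  expect_gte(length(btype), 100)
  expect_gte(length(bspec), 100)
  expect_lt(stats::quantile(within, 0.99), stats::quantile(btype, 0.01))
  expect_lt(stats::quantile(btype, 0.99), stats::quantile(bspec, 0.01))
})
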