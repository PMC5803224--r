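test_that("K80 distance matches the closed form and handles edge cases", {
  set.seed(24)
  s <- rand_seq(200)
  expect_equal(k80_distance(s, s), 0)

  # P = 0.1, Q = 0.05 on 1000 sites -> -0.5 ln[(0.75) sqrt(0.9)] = 0.1702
  L <- 1000
  a <- paste(rep("A", L), collapse = "")
  b <- paste(c(rep("G", 100), rep("C", 50), rep("A", 850)), collapse = "")
  expect_equal(k80_distance(a, b), 0.1702, tolerance = 1e-3)
  expect_equal(k80_distance(a, b),
               -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)))

  # saturation: P = 0.5, Q = 0
  b2 <- paste(c(rep("G", 500), rep("A", 500)), collapse = "")
  expect_error(k80_distance(a, b2), "saturation")

  # pairwise deletion: gaps and ambiguities excluded
  a3 <- paste0("----NNNNN", strrep("A", 191))
  b3 <- paste0("GGGGGGGGG", strrep("A", 181), strrep("G", 10))
  expect_equal(k80_distance(a3, b3),
               k80_distance(strrep("A", 191),
                            paste0(strrep("A", 181), strrep("G", 10))))
  expect_warning(k80_distance(paste0(strrep("-", 150), strrep("A", 50)),
                              strrep("A", 200)), "unreliable")
})

test_that("K80 matrix agrees with the ape implementation", {
  set.seed(25)
  root <- rand_seq(400)
  seqs <- setNames(c(root,
                     vapply(c(5, 15, 30, 45), function(n) sub_mutate(root, n),
                            character(1))),
                   paste0("s", 1:5))
  D <- k80_matrix(seqs)
  bin <- ape::as.DNAbin(t(sapply(seqs, function(s) strsplit(s, "")[[1]])))
  Dape <- as.matrix(ape::dist.dna(bin, model = "K80",
                                  pairwise.deletion = TRUE))
  expect_equal(unname(D), unname(Dape[names(seqs), names(seqs)]),
               tolerance = 1e-9)
})

test_that("the prior sweep finds the two-group partition across the gap", {
  ids <- paste0("x", 1:6)
  D <- matrix(0.20, 6, 6, dimnames = list(ids, ids))
  D[1:3, 1:3] <- 0.01
  D[4:6, 4:6] <- 0.01
  diag(D) <- 0
  series <- abgd_sweep(D, Pmin = 0.001, Pmax = 0.2, steps = 100)
  in_range <- series$priors >= 0.02 & series$priors <= 0.15
  n_groups <- apply(series$partitions, 1, max)
  expect_true(all(n_groups[in_range] == 2))
  expect_true(all(series$partitions[in_range, 1:3] !=
                    series$partitions[in_range, 4:6]))

  # all sequences identical -> one group at every prior
  D0 <- matrix(0, 4, 4)
  s0 <- abgd_sweep(D0, steps = 20)
  expect_true(all(apply(s0$partitions, 1, max) == 1))

  # group count never increases with the prior
  expect_true(all(diff(n_groups) <= 0))
})

test_that("plateau detection returns maximal runs of identical partitions", {
  series <- structure(list(
    priors = c(0.01, 0.02, 0.04, 0.08, 0.16),
    partitions = rbind(c(1, 1, 2), c(1, 1, 2),
                       c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)),
    ids = c("a", "b", "c")), class = "partition_series")
  pl <- detect_plateaus(series)
  expect_equal(pl$span, c(2, 3))
  expect_equal(pl$n_groups, c(2, 1))
  expect_equal(pl$prior_lo, c(0.01, 0.04))
  expect_equal(pl$prior_hi, c(0.02, 0.16))

  # all partitions distinct -> spans of 1
  series2 <- structure(list(
    priors = 1:3 / 10,
    partitions = rbind(c(1, 2, 3), c(1, 1, 2), c(1, 1, 1)),
    ids = c("a", "b", "c")), class = "partition_series")
  expect_true(all(detect_plateaus(series2)$span == 1))
})

test_that("rank selection anchors both levels to the references", {
  # T1a, T1b: two genetic types of S1; T2: another species; e1 near T1a
  ids <- c("T1a", "T1b", "T2", "e1")
  D <- matrix(0.25, 4, 4, dimnames = list(ids, ids))
  D["T1a", "e1"] <- D["e1", "T1a"] <- 0.01
  D["T1a", "T1b"] <- D["T1b", "T1a"] <- 0.05
  D["T1b", "e1"] <- D["e1", "T1b"] <- 0.05
  diag(D) <- 0
  series <- abgd_sweep(D)
  pl <- detect_plateaus(series)
  refs <- data.frame(id = c("T1a", "T1b", "T2"),
                     morphospecies = c("S1", "S1", "S2"),
                     genetic_type = c("t1a", "t1b", "t2"))
  out <- select_ranks(pl, refs, clade_label = "CladeX")
  get <- function(id, col) out[[col]][out$id == id]
  # genetic-type level keeps T1a and T1b separate
  expect_false(get("T1a", "genetic_type") == get("T1b", "genetic_type"))
  # morphospecies level merges them but not with T2
  expect_equal(get("T1a", "morphospecies"), get("T1b", "morphospecies"))
  expect_false(get("T1a", "morphospecies") == get("T2", "morphospecies"))
  # the environmental sequence inherits by co-clustering
  expect_equal(get("e1", "genetic_type"), "t1a")
  expect_equal(get("e1", "morphospecies"), "S1")
  # nesting: genetic types refine morphospecies
  expect_true(all(tapply(out$morphospecies, out$genetic_type,
                         function(x) length(unique(x))) == 1))
})

test_that("with single-type references the constraint is vacuous and the coarsest plateau wins", {
  ids <- c("R", "e1", "e2")
  D <- matrix(0.1, 3, 3, dimnames = list(ids, ids))
  D["R", "e1"] <- D["e1", "R"] <- 0.01
  diag(D) <- 0
  series <- abgd_sweep(D)
  pl <- detect_plateaus(series)
  refs <- data.frame(id = "R", morphospecies = "S1", genetic_type = "t1")
  out <- select_ranks(pl, refs)
  # every plateau admissible; the fewest-groups (single group) plateau selected
  expect_true(all(out$genetic_type == "t1"))
  expect_true(all(out$morphospecies == "S1"))
})

test_that("clade policy collapses genetic types only where requested", {
  asg <- data.frame(id = paste0("m", 1:4),
                    genetic_type = c("S1 I", "S1 II", "S2 I", "S2 II"),
                    morphospecies = c("S1", "S1", "S2", "S2"),
                    is_reference = FALSE,
                    clade = c("Basal", "Basal", "Spinose", "Spinose"),
                    stringsAsFactors = FALSE)
  class(asg) <- c("rank_assignment", "data.frame")
  out <- apply_clade_policy(asg, c(Basal = "collapse_genetic_types"))
  expect_equal(out$genetic_type[1:2], c("S1", "S1"))
  expect_equal(out$genetic_type[3:4], c("S2 I", "S2 II"))
  expect_identical(apply_clade_policy(asg, NULL), asg)
  expect_error(apply_clade_policy(asg, c(Nope = "collapse_genetic_types")),
               "unknown clade")
})

test_that("patristic validation computes hand-checked path sums and tests", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  asg <- data.frame(id = c("a", "b", "c", "d"),
                    genetic_type = c("t1", "t1", "t2", "t3"),
                    morphospecies = c("S1", "S1", "S1", "S2"),
                    is_reference = FALSE, clade = "X",
                    stringsAsFactors = FALSE)
  out <- patristic_validation(tree, asg)
  d <- out$distances
  expect_equal(d$distance[d$class == "intra_genetic_type"], 2)     # a-b
  expect_true(all(d$distance[d$class == "inter_genetic_type"] == 4))
  expect_equal(sort(d$distance[d$class == "inter_species"]), c(2, 4, 4))

  # identical class distributions give a KS statistic of zero
  star <- ape::read.tree(text = "((a:1,b:1):0,(c:1,d:1):0);")
  out2 <- patristic_validation(star, asg)
  expect_lt(max(out2$tests$ks_statistic), 1e-12)

  expect_error(patristic_validation(tree, transform(asg, id = c("a", "b", "c", "zz"))),
               "zz")
})
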