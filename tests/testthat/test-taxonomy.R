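test_that("global identity: exact values, symmetry, agreement with reference aligner", {
  set.seed(17)
  s <- rand_seq(300)
  expect_equal(global_identity(s, s), 100)
  s15 <- sub_mutate(s, 15)
  expect_equal(global_identity(s, s15), 95)     # 285/300, no gaps
  expect_error(global_identity("ACGT", ""), "empty")

  for (i in 1:5) {
    a <- rand_seq(90)
    bx <- strsplit(sub_mutate(a, 7), "")[[1]]
    b <- paste(bx[-sample(90, 1)], collapse = "")   # one deletion
    expect_equal(global_identity(a, b), global_identity(b, a))
    # independent aligner oracle (same scoring scheme)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                    baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = 12, gapExtension = 4)
    pc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sc <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    expect_equal(global_identity(a, b),
                 100 * sum(pc == sc & pc != "-") / length(pc),
                 tolerance = 1e-9)
  }
})

test_that("best-hit assignment resolves ties by taxonomy path", {
  set.seed(18)
  base <- rand_seq(300)
  refdb <- data.frame(
    id = c("r1", "r2", "r3"),
    sequence = c(base, sub_mutate(base, 40), rand_seq(300)),
    path = c("Eukaryota;Rhizaria;Foraminifera;Spinose",
             "Eukaryota;Stramenopiles;Bacillariophyta;Diatom",
             "Eukaryota;Opisthokonta;Metazoa;Copepod"),
    stringsAsFactors = FALSE)
  a <- assign_taxonomy(c(q = base), refdb)
  expect_equal(a$best_hit, "r1")
  expect_equal(a$identity, 100)
  expect_false(a$ambiguous)

  # equidistant to a foraminifer and a diatom -> ambiguous
  x <- strsplit(base, "")[[1]]
  y <- strsplit(refdb$sequence[2], "")[[1]]
  diffpos <- which(x != y)
  half <- diffpos[seq_len(floor(length(diffpos) / 2))]
  mid <- x; mid[half] <- y[half]
  a2 <- assign_taxonomy(c(q = paste(mid, collapse = "")), refdb)
  expect_true(a2$ambiguous)
  expect_equal(a2$n_best, 2)
})

test_that("assignment equals the all-vs-all identity oracle on a query fixture", {
  set.seed(19)
  refs <- replicate(6, rand_seq(120))
  refdb <- data.frame(id = sprintf("r%d", 1:6), sequence = refs,
                      path = sprintf("Eukaryota;Rhizaria;Foraminifera;T%d", 1:6),
                      stringsAsFactors = FALSE)
  queries <- setNames(
    vapply(1:20, function(i) sub_mutate(refs[sample(6, 1)], sample(0:20, 1)),
           character(1)),
    sprintf("q%02d", 1:20))
  got <- assign_taxonomy(queries, refdb)
  for (i in seq_along(queries)) {
    oracle <- vapply(refs, function(r) global_identity(queries[[i]], r),
                     numeric(1))
    expect_equal(got$identity[i], max(oracle))
    expect_equal(got$path[i], refdb$path[which.max(oracle)])
  }
})

test_that("equal hits agreeing at morphospecies assign with unresolved genetic type", {
  set.seed(20)
  base <- rand_seq(200)
  refdb <- data.frame(
    id = c("a", "b"),
    sequence = c(sub_mutate(base, 1), sub_mutate(base, 1)),
    path = c("MG;Gen;SpeciesX;Type I", "MG;Gen;SpeciesX;Type II"),
    stringsAsFactors = FALSE)
  stopifnot(refdb$sequence[1] != refdb$sequence[2])
  a <- assign_taxonomy(c(q = base), refdb, ambiguity_rank = 3)
  expect_false(a$ambiguous)
  expect_equal(a$path, "MG;Gen;SpeciesX;unresolved")
})

test_that("non-foraminiferal MOTUs are screened out by path level 3", {
  set.seed(21)
  seqs <- replicate(10, rand_seq(60))
  rd <- reads_df(seqs, counts = sample(2:5, 10, TRUE))
  rd$id <- sprintf("r%04d", seq_len(nrow(rd)))
  mo <- swarm_cluster(dereplicate(rd), d = 2)
  n <- nrow(mo$motus)
  is_foram <- rep(c(TRUE, FALSE), length.out = n)
  asg <- data.frame(
    query = mo$motus$motu_id,
    best_hit = "r", identity = 99,
    path = ifelse(is_foram, "Eukaryota;Rhizaria;Foraminifera;X;Y;Z",
                  "Eukaryota;Alveolata;Dinophyceae;W"),
    ambiguous = FALSE, n_best = 1, stringsAsFactors = FALSE)
  out <- screen_nonforam(mo, asg)
  expect_equal(nrow(out$foram$motus), sum(is_foram))
  expect_equal(nrow(out$discarded$motus), sum(!is_foram))
  expect_equal(sum(out$foram$counts) + sum(out$discarded$counts),
               sum(mo$counts))
})

test_that("meta-reference merges sources and counts unique paths", {
  set.seed(22)
  pfr2 <- data.frame(id = c("p1", "p2", "p3"),
                     sequence = replicate(3, rand_seq(120)),
                     path = c("M;G;S1;T1", "M;G;S1;T2", "M;G;S2;T1"))
  env <- data.frame(id = c("e1", "e2"),
                    sequence = replicate(2, rand_seq(120)),
                    path = c("M;G;S3;T1", "M;G;S4;T1"))
  meta <- build_meta_reference(pfr2, env_reps = env)
  expect_equal(nrow(meta), 5)
  expect_equal(attr(meta, "n_paths"), 5)

  # an environmental rep sharing a path with a close reference: count unchanged
  env2 <- env
  env2$path[1] <- "M;G;S1;T1"
  env2$sequence[1] <- sub_mutate(pfr2$sequence[1], 2)
  meta2 <- build_meta_reference(pfr2, env_reps = env2)
  expect_equal(attr(meta2, "n_paths"), 4)

  # same path carried by divergent sequences -> warning, both kept
  env3 <- env
  env3$path[1] <- "M;G;S1;T1"
  expect_warning(m3 <- build_meta_reference(pfr2, env_reps = env3),
                 "below 95")
  expect_equal(nrow(m3), 5)
})

test_that("reassignment applies a strict >95% rule, merges taxa and conserves reads", {
  set.seed(23)
  R1 <- rand_seq(300)
  R2 <- rand_seq(300)
  m1 <- R1                      # 100%
  m2 <- sub_mutate(R1, 15)      # exactly 95.0% -> excluded under strict rule
  m3 <- sub_mutate(R1, 12)      # 96% -> retained, same taxon as m1
  m4 <- sub_mutate(R2, 6)       # 98% -> retained, other taxon
  rd <- rbind(reads_df(m1, "s1", 7), reads_df(m2, "s1", 5),
              reads_df(m3, "s2", 4), reads_df(m4, "s2", 2))
  rd$id <- sprintf("r%04d", seq_len(nrow(rd)))
  mo <- swarm_cluster(dereplicate(rd), d = 2)
  expect_equal(nrow(mo$motus), 4)
  meta <- data.frame(id = c("R1", "R2"), sequence = c(R1, R2),
                     path = c("M;G;S1;T1", "M;G;S2;T1"),
                     source = "reference-db", stringsAsFactors = FALSE)
  out <- reassign_all(mo, meta, threshold = 95)
  expect_equal(sort(out$table$path), c("M;G;S1;T1", "M;G;S2;T1"))
  expect_equal(sum(out$table[out$table$path == "M;G;S1;T1",
                             c("s1", "s2")]), 11)  # m1 + m3 merged
  expect_equal(out$excluded$reason, "below_threshold")
  expect_equal(out$retained_reads + sum(rowSums(mo$counts)[
    mo$motus$motu_id %in% out$excluded$query]), out$total_reads)

  # inclusive rule admits the boundary MOTU
  out2 <- reassign_all(mo, meta, threshold = 95, inclusive = TRUE)
  expect_equal(nrow(out2$excluded), 0)

  # self-assignment: an environmental rep in the meta-reference hits itself
  meta3 <- rbind(meta, data.frame(id = "e1", sequence = m4,
                                  path = "M;G;S9;T1", source = "environmental"))
  a <- assign_taxonomy(c(e1 = m4), meta3)
  expect_equal(a$identity, 100)
  expect_equal(a$best_hit, "e1")
})
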