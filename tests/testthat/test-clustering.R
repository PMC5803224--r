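test_that("seq_distance is the Levenshtein edit distance", {
  expect_equal(seq_distance("ACGT", "ACGT"), 0)
  expect_equal(seq_distance("ACGT", "ACGA"), 1)
  expect_equal(seq_distance("ACGT", "AGT"), 1)
  # dynamic-programming oracle on random pairs, including indels
  set.seed(10)
  for (i in 1:200) {
    a <- rand_seq(sample(10:60, 1))
    b <- if (i %% 2) rand_seq(sample(10:60, 1)) else {
      x <- strsplit(a, "")[[1]]
      drop <- sample(length(x), sample(0:3, 1))
      if (length(drop)) x <- x[-drop]
      paste(x, collapse = "")
    }
    expect_equal(seq_distance(a, b), utils::adist(a, b)[1, 1])
  }
  # symmetry
  expect_equal(seq_distance("ACGTT", "TACG"), seq_distance("TACG", "ACGTT"))
})

test_that("single-linkage chaining joins A-B-C even when A and C are far", {
  set.seed(11)
  A <- rand_seq(60)
  B <- sub_mutate(A, 2)
  C0 <- sub_mutate(B, 2)
  stopifnot(utils::adist(A, C0)[1, 1] > 2)
  amp <- dereplicate(reads_df(c(A, B, C0), counts = c(5, 3, 2)))
  mo <- swarm_cluster(amp, d = 2)
  expect_equal(nrow(mo$motus), 1)
  expect_equal(mo$motus$total_reads, 10L)
  expect_equal(mo$motus$seed_sequence, A)
})

test_that("amplicons all beyond d form singleton MOTUs", {
  set.seed(12)
  seqs <- replicate(6, rand_seq(50))
  amp <- dereplicate(reads_df(seqs))
  mo <- swarm_cluster(amp, d = 2)
  expect_equal(nrow(mo$motus), 6)
  expect_error(swarm_cluster(amp, d = -1), "d must be")
})

test_that("clustering equals connected components over the full distance matrix", {
  set.seed(13)
  centers <- replicate(8, rand_seq(80))
  seqs <- unique(unlist(lapply(centers, function(cc)
    c(cc, replicate(5, sub_mutate(cc, sample(1:4, 1)))))))
  amp <- dereplicate(reads_df(seqs, counts = sample(1:9, length(seqs), TRUE)))
  mo <- swarm_cluster(amp, d = 2)
  imp <- mo$membership$motu_id[match(amp$amplicons$amplicon_id,
                                     mo$membership$amplicon_id)]
  oracle <- component_oracle(amp$amplicons$sequence, 2)
  expect_equal(ari(imp, oracle), 1)
})

test_that("the MOTU partition is invariant under read shuffling and conserves reads", {
  set.seed(14)
  centers <- replicate(4, rand_seq(70))
  seqs <- unlist(lapply(centers, function(cc)
    c(cc, replicate(3, sub_mutate(cc, 2)))))
  rd <- reads_df(seqs, counts = sample(1:5, length(seqs), TRUE))
  rd$id <- sprintf("r%04d", seq_len(nrow(rd)))
  mo1 <- swarm_cluster(dereplicate(rd), d = 2)
  rd2 <- rd[sample(nrow(rd)), ]
  mo2 <- swarm_cluster(dereplicate(rd2), d = 2)
  expect_identical(mo1$motus, mo2$motus)
  # partition property: every amplicon in exactly one MOTU, reads conserved
  expect_equal(sort(mo1$membership$amplicon_id),
               sort(dereplicate(rd)$amplicons$amplicon_id))
  expect_equal(sum(mo1$counts), nrow(rd))
  expect_equal(mo1$motus$total_reads, unname(rowSums(mo1$counts)))
  expect_equal(mo1$motus$n_samples_present,
               unname(rowSums(mo1$counts > 0)))
})

test_that("abundance/occurrence filter applies both thresholds at their boundaries", {
  set.seed(15)
  seqs <- replicate(3, rand_seq(50))
  rd <- rbind(reads_df(seqs[1], "s1", 4), reads_df(seqs[1], "s2", 3),
              reads_df(seqs[1], "s3", 3),          # 3 samples, 10 reads
              reads_df(seqs[2], "s1", 500), reads_df(seqs[2], "s2", 500),
              reads_df(seqs[3], "s1", 3), reads_df(seqs[3], "s2", 3),
              reads_df(seqs[3], "s3", 3))          # 3 samples, 9 reads
  rd$id <- sprintf("r%05d", seq_len(nrow(rd)))
  mo <- swarm_cluster(dereplicate(rd), d = 2)
  out <- abundance_occurrence_filter(mo, min_samples = 3, min_reads = 10)
  expect_equal(out$retained$motus$seed_sequence, seqs[2 - 1])
  expect_setequal(out$rare$motus$seed_sequence, seqs[2:3])
})

test_that("representative selection takes the most abundant of the longest prefix matches", {
  p <- foram_primers()
  set.seed(16)
  seed300 <- rand_seq(300)
  long650 <- paste0(seed300, rand_seq(350))
  long500 <- paste0(seed300, rand_seq(200))
  untrimmed <- rbind(
    reads_df(paste0(p$forward, seed300), counts = 6),
    reads_df(paste0(p$forward, long650), counts = 2),
    reads_df(paste0(p$forward, long500), counts = 5))
  untrimmed$id <- sprintf("u%03d", seq_len(nrow(untrimmed)))
  mo <- swarm_cluster(dereplicate(reads_df(seed300, counts = 13)), d = 2)
  out <- select_representative(mo, untrimmed, p)
  # unique longest candidate wins regardless of abundance
  expect_equal(out$motus$representative, long650)

  # two maximal-length candidates: abundance decides
  long650b <- paste0(seed300, rand_seq(350))
  untrimmed2 <- rbind(untrimmed,
                      reads_df(paste0(p$forward, long650b), counts = 5))
  untrimmed2$id <- sprintf("u%03d", seq_len(nrow(untrimmed2)))
  out2 <- select_representative(mo, untrimmed2, p)
  expect_equal(out2$motus$representative, long650b)

  # no longer read -> fall back to the seed
  mo3 <- swarm_cluster(dereplicate(reads_df(rand_seq(300), counts = 4)), d = 2)
  out3 <- select_representative(mo3, untrimmed, p)
  expect_equal(out3$motus$representative, mo3$motus$seed_sequence)
})
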