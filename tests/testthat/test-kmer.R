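test_that("k-mer tables of the worked 2-mer example match entry for entry", {
  t1 <- as_kmer_vector(kmer_counts("AACTACTCT", 2))
  t2 <- as_kmer_vector(kmer_counts("AGCTACTT", 2))
  expected1 <- c(AA = 1, AC = 2, CT = 3, TA = 1, TC = 1)
  expected2 <- c(AC = 1, AG = 1, CT = 2, GC = 1, TA = 1, TT = 1)
  expect_equal(t1[names(expected1)], expected1)
  expect_equal(sum(t1), 8)  # L - k + 1 and nothing else
  expect_equal(t2[names(expected2)], expected2)
  expect_equal(sum(t2), 7)
  expect_length(t1, 16)
})

test_that("k-mer distance reproduces the 7/15 worked value and its bounds", {
  t1 <- kmer_counts("AACTACTCT", 2)
  t2 <- kmer_counts("AGCTACTT", 2)
  expect_equal(kmer_distance(t1, t2), 7 / 15)
  expect_equal(kmer_distance(t2, t1), 7 / 15)
  expect_equal(kmer_distance(t1, t1), 0)
  ## disjoint support
  a <- kmer_counts("AAAA", 2)
  b <- kmer_counts("CCCC", 2)
  expect_equal(kmer_distance(a, b), 1)
})

test_that("a sequence of length k yields a single unit count", {
  v <- as_kmer_vector(kmer_counts("ACGT", 4))
  expect_equal(sum(v), 1)
  expect_equal(unname(v["ACGT"]), 1)
})

test_that("input validation: short sequences and illegal symbols", {
  expect_error(kmer_counts("ACG", 4), "shorter than k")
  expect_error(kmer_counts("ACGNACGT", 2), "illegal symbol")
  expect_error(kmer_distance(kmer_counts("ACGT", 2), kmer_counts("ACGT", 3)),
               "mismatched k")
  ## lenient mode drops only the windows touching the bad symbol
  v <- as_kmer_vector(kmer_counts("ACGNACGT", 2, lenient = TRUE))
  expect_equal(sum(v), 5)  # 7 windows minus the 2 containing N
  expect_equal(unname(v[c("AC", "CG", "GT")]), c(2, 2, 1))
})

test_that("k-mer distance is symmetric and bounded on random pairs", {
  set.seed(42)
  for (i in 1:1000) {
    s1 <- random_dna(sample(8:60, 1))
    s2 <- random_dna(sample(8:60, 1))
    a <- kmer_counts(s1, 4); b <- kmer_counts(s2, 4)
    d <- kmer_distance(a, b)
    expect_identical(d, kmer_distance(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("a single substitution away from the ends alters at most 2k k-mers", {
  set.seed(7)
  k <- 8
  for (i in 1:50) {
    s <- random_dna(100)
    p <- sample(20:80, 1)
    ch <- strsplit(s, "")[[1]]
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    s2 <- paste(ch, collapse = "")
    t1 <- kmer_counts(s, k); t2 <- kmer_counts(s2, k)
    num <- kmer_distance(t1, t2) * (t1$total + t2$total)
    expect_lte(num, 2 * k)
  }
})

test_that("a single-base insertion moves the distance only slightly", {
  set.seed(11)
  s <- random_dna(200)
  s_ins <- paste0(substr(s, 1, 100), "A", substr(s, 101, 200))
  d <- kmer_distance(kmer_counts(s, 8), kmer_counts(s_ins, 8))
  expect_lt(d, 0.1)
  expect_gt(d, 0)
})

test_that("sample pair distance averages haplotype pairs and targets", {
  ## hand example: one shared target, s1 homozygous {X}, s2 het {X, Y}
  X <- "ACGTACGTACGTACGTACGTACGTACGTACGT"
  set.seed(3)
  repeat {   # find Y with d(X, Y) about 0.5 for a clean hand enumeration
    Y <- random_dna(32)
    dXY <- kmer_distance(kmer_counts(X, 8), kmer_counts(Y, 8))
    if (dXY > 0.2) break
  }
  s1 <- sample_genotypes("s1", list(t1 = X))
  s2 <- sample_genotypes("s2", list(t1 = c(X, Y)))
  expect_equal(sample_pair_distance(s1, s2, k = 8), (0 + dXY) / 2)
  ## identical homozygous samples -> 0
  expect_equal(sample_pair_distance(s1, sample_genotypes("s3", list(t1 = X))), 0)
  ## two shared targets -> arithmetic mean of the per-target means
  s4 <- sample_genotypes("s4", list(t1 = X, t2 = X))
  s5 <- sample_genotypes("s5", list(t1 = X, t2 = Y))
  expect_equal(sample_pair_distance(s4, s5, k = 8), mean(c(0, dXY)))
  ## no shared target errors at the point level
  s6 <- sample_genotypes("s6", list(t9 = X))
  expect_error(sample_pair_distance(s1, s6), "share no amplified target")
})

test_that("sample pair distance matches the brute-force oracle", {
  set.seed(9)
  for (i in 1:10) {
    mk <- function(id) {
      nt <- sample(1:3, 1)
      targets <- lapply(seq_len(nt), function(j) {
        nh <- sample(1:3, 1)
        unique(replicate(nh, random_dna(sample(20:40, 1))))
      })
      names(targets) <- paste0("t", 1:nt)
      sample_genotypes(id, targets)
    }
    g1 <- mk("g1"); g2 <- mk("g2")
    expect_equal(sample_pair_distance(g1, g2, k = 4),
                 oracle_sample_distance(g1, g2, k = 4))
  }
})

test_that("pairwise distance matrix is symmetric, zero-diagonal and entrywise correct", {
  set.seed(5)
  gts <- lapply(1:3, function(i)
    sample_genotypes(paste0("s", i),
                     list(t1 = random_dna(30), t2 = random_dna(30))))
  D <- pairwise_distance_matrix(gts, k = 4)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(D[i, j], sample_pair_distance(gts[[i]], gts[[j]], k = 4))
  ## single sample
  expect_equal(dim(pairwise_distance_matrix(gts[1], k = 4)), c(1, 1))
  ## non-overlapping pair: sentinel 1.0 with a warning
  g4 <- sample_genotypes("s4", list(t9 = random_dna(30)))
  expect_warning(D2 <- pairwise_distance_matrix(c(gts[1], list(g4)), k = 4),
                 "no shared targets")
  expect_equal(D2["s1", "s4"], 1.0)
  expect_error(pairwise_distance_matrix(list()), "empty")
})

test_that("FASTA round trip preserves haplotype records", {
  recs <- data.frame(sample = c("s1", "s1", "s2"),
                     target = c("t1", "t1", "t1"),
                     sequence = c("ACGTACGT", "ACGTTCGT", "GGGGCCCC"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_haplotype_fasta(recs, path)
  back <- read_haplotype_fasta(path)
  expect_equal(back[order(back$sample, back$sequence), ],
               recs[order(recs$sample, recs$sequence), ],
               ignore_attr = TRUE)
})

test_that("distance matrix TSV round trip", {
  D <- matrix(c(0, .2, .2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(D, path, long = TRUE)
  expect_equal(read_distance_matrix(path), D)
  long <- read.delim(paste0(path, ".long.tsv"))
  expect_equal(long$distance, 0.2)
})

test_that("birthday-model k-mer uniqueness probabilities", {
  ## 160 bp target, 8-mers: about 84%
  expect_equal(round(100 * prob_all_kmers_distinct(160, 8)), 84)
  ## 149 bp, 4-mers: vanishingly small
  expect_lt(prob_all_kmers_distinct(149, 4), 1e-22)
  ## exact product cross-check at small scale
  expect_equal(prob_all_kmers_distinct(5, 2), prod(1 - (0:3) / 16))
})
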