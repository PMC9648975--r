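test_that("nearest-neighbour sets include all distance ties", {
  fx <- worked_example_db()
  idx <- kmerassign:::db_index(fx$db, k = 4)
  q <- kmer_counts(fx$near, 4)
  nn <- nearest_neighbour_set(q, "t1", idx)
  expect_equal(nn$distance, 0)
  ## the identical allele occurs in 3 samples: all returned
  expect_setequal(nn$hits$sample, c("A01", "A02", "B01"))
  ## absent target: empty set
  expect_equal(nrow(nearest_neighbour_set(q, "t99", idx)$hits), 0)
  ## equidistant distinct sequences are both returned
  set.seed(2)
  a <- "AACCGGTTAACCGGTT"
  g1 <- sample_genotypes("r1", list(t1 = "AACCGGTTAACCGGTA"))
  g2 <- sample_genotypes("r2", list(t1 = "TACCGGTTAACCGGTT"))
  db2 <- reference_db(list(g1, g2), c(r1 = "x", r2 = "y"), min_targets = 1)
  nn2 <- nearest_neighbour_set(kmer_counts(a, 4), "t1",
                               kmerassign:::db_index(db2, 4))
  expect_setequal(nn2$hits$sample, c("r1", "r2"))
})

test_that("frequency-normalised proportions reproduce the 0.29/0.71 example", {
  fx <- worked_example_db()
  idx <- kmerassign:::db_index(fx$db, k = 4)
  nn <- nearest_neighbour_set(kmer_counts(fx$near, 4), "t1", idx)
  freqs <- group_frequencies(nn, "t1", idx, fx$partition)
  ## allele in 2 of 10 homozygous samples of A and 1 of 2 of B
  expect_equal(unname(freqs["A"]), 2 / 10)
  expect_equal(unname(freqs["B"]), 1 / 2)
  props <- per_target_proportions(freqs)
  expect_equal(round(unname(props["A"]), 2), 0.29)
  expect_equal(round(unname(props["B"]), 2), 0.71)
  expect_equal(sum(props), 1)
  ## the count-based alternative would misattribute by group size:
  ## a documented counter-example, not an implemented code path
  counts <- c(A = 2, B = 1)
  count_props <- counts / sum(counts)
  expect_equal(round(unname(count_props), 2), c(0.67, 0.33))
})

test_that("zygosity-aware allele-copy accounting", {
  ## one heterozygote carrying the NN haplotype once among a 1-sample group
  het <- sample_genotypes("h1", list(t1 = c("ACGTACGTACGT", "GGGTACGTACGT")))
  other <- sample_genotypes("o1", list(t1 = "TTTTTTAAAAAA"))
  db <- reference_db(list(het, other), c(h1 = "spH", o1 = "spO"),
                     min_targets = 1)
  part <- structure(list(level_name = "fine", threshold = 0.1,
                         membership = c(h1 = "H", o1 = "O"),
                         group_labels = c(H = "H", O = "O")),
                    class = "species_partition")
  idx <- kmerassign:::db_index(db, 4)
  nn <- nearest_neighbour_set(kmer_counts("ACGTACGTACGT", 4), "t1", idx)
  expect_equal(nrow(nn$hits), 1)
  freqs <- group_frequencies(nn, "t1", idx, part)
  expect_equal(unname(freqs["H"]), 1 / 2)   # one allele copy of two
  ## a sample with 3 alleles keeps total weight 2 (2/3 per haplotype)
  tri <- sample_genotypes("m1", list(t1 = c("ACGTACGTACGT", "GGGTACGTACGT",
                                            "CCGTACGTACGT")))
  db3 <- reference_db(list(tri, other), c(m1 = "spM", o1 = "spO"),
                      min_targets = 1)
  idx3 <- kmerassign:::db_index(db3, 4)
  part3 <- structure(list(level_name = "fine", threshold = 0.1,
                          membership = c(m1 = "M", o1 = "O"),
                          group_labels = c(M = "M", O = "O")),
                     class = "species_partition")
  nn3 <- nearest_neighbour_set(kmer_counts("ACGTACGTACGT", 4), "t1", idx3)
  freqs3 <- group_frequencies(nn3, "t1", idx3, part3)
  expect_equal(unname(freqs3["M"]), (2 / 3) / 2)
  expect_error(per_target_proportions(c(A = 0, B = 0)), "positive")
})

test_that("an exact copy of a reference with private alleles assigns fully", {
  sim <- sim_fixture()
  parts <- sim_partitions()
  q <- sim$db$genotypes[[1]]
  a <- assign_sample(q, sim$db, parts)
  expect_gte(a$levels$fine$proportions[[1]], 0.8)
  expect_true(a$levels$fine$outcome != "unassigned")
  ## proportions sum to one at every level and for every target
  for (lv in names(a$levels))
    expect_equal(sum(a$levels[[lv]]$proportions), 1, tolerance = 1e-9)
  sums <- aggregate(proportion ~ target + level, a$detail, sum)
  expect_true(all(abs(sums$proportion - 1) < 1e-9))
})

test_that("classification threshold 0.8 is inclusive", {
  ## 5 targets: 4 point to group A, 1 to group B -> overall exactly 0.8
  set.seed(31)
  seqs_a <- replicate(5, random_dna(40))
  seqs_b <- replicate(5, random_dna(40))
  ga <- sample_genotypes("refA", setNames(as.list(seqs_a), paste0("t", 1:5)))
  gb <- sample_genotypes("refB", setNames(as.list(seqs_b), paste0("t", 1:5)))
  db <- reference_db(list(ga, gb), c(refA = "spA", refB = "spB"),
                     min_targets = 1)
  part <- structure(list(level_name = "fine", threshold = 0.1,
                         membership = c(refA = "A", refB = "B"),
                         group_labels = c(A = "A", B = "B")),
                    class = "species_partition")
  parts <- structure(list(fine = part), class = "species_partitions")
  q <- sample_genotypes("q", setNames(
    as.list(c(seqs_a[1:4], seqs_b[5])), paste0("t", 1:5)))
  a <- assign_sample(q, db, parts, k = 8, nn_gate = 1)
  expect_equal(unname(a$levels$fine$proportions["A"]), 0.8)
  expect_equal(a$levels$fine$outcome, "A")        # "at least 0.8" classifies
  q2 <- sample_genotypes("q2", setNames(
    as.list(c(seqs_a[1:3], seqs_b[4:5])), paste0("t", 1:5)))
  a2 <- assign_sample(q2, db, parts, k = 8, nn_gate = 1)
  expect_equal(unname(a2$levels$fine$proportions["A"]), 0.6)
  expect_equal(a2$levels$fine$outcome, "unassigned")
})

test_that("missing-target arithmetic caps the achievable proportion (0.58 case)", {
  ## query with 26 amplified targets; its sole same-group reference shares
  ## only 15 of them; a foreign-group reference covers all 26
  set.seed(37)
  all_t <- paste0("t", sprintf("%02d", 1:26))
  shared_seqs <- setNames(lapply(1:26, function(i) random_dna(40)), all_t)
  refA <- sample_genotypes("refA", shared_seqs[1:15])
  refB <- sample_genotypes("refB", setNames(
    lapply(1:26, function(i) random_dna(40)), all_t))
  db <- reference_db(list(refA, refB), c(refA = "spA", refB = "spB"))
  part <- structure(list(level_name = "fine", threshold = 0.1,
                         membership = c(refA = "A", refB = "B"),
                         group_labels = c(A = "A", B = "B")),
                    class = "species_partition")
  parts <- structure(list(fine = part), class = "species_partitions")
  q <- sample_genotypes("q", shared_seqs)   # an exact copy of A's species
  a <- assign_sample(q, db, parts)
  expect_equal(round(unname(a$levels$fine$proportions["A"]), 2), 0.58)
  expect_equal(unname(a$levels$fine$proportions["A"]), 15 / 26)
  expect_equal(a$levels$fine$outcome, "unassigned")
})

test_that("assignment matches the brute-force oracle on a 20-sample database", {
  sim <- sim_fixture()
  parts <- sim_partitions()
  ## restrict to 8 targets to keep the dense oracle cheap
  slim <- lapply(sim$db$genotypes, function(g) {
    sample_genotypes(g$sample_id, g$targets[intersect(paste0("t0", 1:8),
                                                      names(g$targets))])
  })
  db <- reference_db(slim, sim$db$labels, min_targets = 1)
  qs <- simulate_queries(sim, "member", n = 3, seed = 11)$queries
  for (q in qs) {
    qslim <- sample_genotypes(q$sample_id,
                              q$targets[intersect(paste0("t0", 1:8),
                                                  names(q$targets))])
    a <- assign_sample(qslim, db, parts, nn_gate = 1)
    oracle <- oracle_assign(qslim, db, parts)
    for (lv in names(parts)) {
      got <- a$levels[[lv]]$proportions
      expect_equal(got[sort(names(got))], oracle[[lv]][sort(names(oracle[[lv]]))],
                   tolerance = 1e-9)
    }
  }
})

test_that("frequencies make assignment invariant to reference duplication", {
  set.seed(41)
  seqs <- setNames(lapply(1:12, function(i) random_dna(40)), paste0("t", 1:12))
  mut <- function(s) { substr(s, 1, 1) <- "T"; s }
  gA1 <- sample_genotypes("a1", seqs)
  gA2 <- sample_genotypes("a2", lapply(seqs, mut))
  gB <- sample_genotypes("b1", setNames(lapply(1:12, function(i)
    random_dna(40)), paste0("t", 1:12)))
  part <- function(ids, grp) structure(
    list(level_name = "fine", threshold = 0.1,
         membership = setNames(grp, ids),
         group_labels = setNames(unique(grp), unique(grp))),
    class = "species_partition")
  db1 <- reference_db(list(gA1, gA2, gB), c(a1 = "A", a2 = "A", b1 = "B"))
  parts1 <- structure(list(fine = part(c("a1", "a2", "b1"), c("A", "A", "B"))),
                      class = "species_partitions")
  ## duplicate a2 under a new id within the same group
  gA2b <- sample_genotypes("a3", gA2$targets)
  db2 <- reference_db(list(gA1, gA2, gA2b, gB),
                      c(a1 = "A", a2 = "A", a3 = "A", b1 = "B"))
  parts2 <- structure(list(fine = part(c("a1", "a2", "a3", "b1"),
                                       c("A", "A", "A", "B"))),
                      class = "species_partitions")
  q <- sample_genotypes("q", seqs[1:10])
  p1 <- assign_sample(q, db1, parts1)$levels$fine$proportions
  p2 <- assign_sample(q, db2, parts2)$levels$fine$proportions
  expect_equal(p1[sort(names(p1))], p2[sort(names(p2))], tolerance = 1e-12)
})

test_that("the top group's proportion grows towards coarser levels", {
  ## pooling numerators and denominators makes the dominant group's
  ## proportion at least as large at each coarser level for its own samples
  ## (strict all-group monotonicity can fail for minor groups, where pooling
  ## with an empty sibling dilutes a small frequency; that behaviour is
  ## documented rather than asserted)
  sim <- sim_fixture()
  parts <- sim_partitions()
  qs <- simulate_queries(sim, "member", n = 5, seed = 19)$queries
  int_of_fine <- tapply(
    parts$intermediate$membership,
    parts$fine$membership[names(parts$intermediate$membership)],
    function(x) unique(x)[1])
  coarse_of_int <- tapply(
    parts$coarse$membership,
    parts$intermediate$membership[names(parts$coarse$membership)],
    function(x) unique(x)[1])
  for (q in qs) {
    a <- assign_sample(q, sim$db, parts)
    fine <- a$levels$fine$proportions
    int <- a$levels$intermediate$proportions
    coarse <- a$levels$coarse$proportions
    top <- names(fine)[1]
    expect_lte(fine[[top]], int[[int_of_fine[[top]]]] + 1e-9)
    expect_lte(int[[int_of_fine[[top]]]],
               coarse[[coarse_of_int[[int_of_fine[[top]]]]]] + 1e-9)
  }
})

test_that("the nearest-neighbour gate is enforced", {
  sim <- sim_fixture()
  parts <- sim_partitions()
  thin <- sample_genotypes("thin",
                           sim$db$genotypes[[1]]$targets[1:9])
  expect_error(assign_sample(thin, sim$db, parts), "at least 10")
  foreign <- sample_genotypes("foreign", setNames(
    lapply(1:12, function(i) random_dna(30)), paste0("x", 1:12)))
  expect_error(assign_sample(foreign, sim$db, parts), "no amplified target")
})

test_that("drop-one-out validation separates singletons and handles twins", {
  ## two identical samples assign to their shared group with proportion 1
  set.seed(43)
  seqs <- setNames(lapply(1:12, function(i) random_dna(40)), paste0("t", 1:12))
  far <- setNames(lapply(1:12, function(i) random_dna(40)), paste0("t", 1:12))
  twins_db <- reference_db(
    list(sample_genotypes("tw1", seqs), sample_genotypes("tw2", seqs),
         sample_genotypes("lone", far)),
    c(tw1 = "twin", tw2 = "twin", lone = "loner"))
  D <- pairwise_distance_matrix(twins_db$genotypes)
  parts <- build_level_partitions(D, labels = twins_db$labels)
  v <- dropout_validation(twins_db, parts)
  tw <- v$per_sample[v$per_sample$sample %in% c("tw1", "tw2") &
                       v$per_sample$level == "fine", ]
  expect_true(all(tw$correct))
  expect_equal(tw$correct_proportion, c(1, 1))
  ## the singleton cannot be assigned to its own fine group
  lone <- v$per_sample[v$per_sample$sample == "lone" &
                         v$per_sample$level == "fine", ]
  expect_true(lone$singleton)
  expect_equal(lone$correct_proportion, 0)
  sf <- v$summary[v$summary$level == "fine", ]
  expect_equal(sf$n_singleton, 1)
  expect_equal(sf$n_evaluated, 2)
})
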