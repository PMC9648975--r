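## Shared fixtures and independent oracles for the test suite.
## Everything here is deliberately naive (dense vectors, plain loops) so it
## stays independent of the package's own computation paths.

.fx <- new.env()

## one calibrated simulated reference panel, shared across test files
sim_fixture <- function() {
  if (is.null(.fx$sim)) .fx$sim <- simulate_reference_db(seed = 1)
  .fx$sim
}

sim_partitions <- function() {
  if (is.null(.fx$parts)) {
    sim <- sim_fixture()
    .fx$parts <- build_level_partitions(sim$D, labels = sim$db$labels)
  }
  .fx$parts
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## ---- dense k-mer oracle -------------------------------------------------

oracle_kmer_levels <- function(k) {
  key <- paste0("kn", k)
  if (is.null(.fx[[key]])) {
    bases <- c("A", "C", "G", "T")
    out <- bases
    for (i in seq_len(k - 1)) out <- as.vector(t(outer(out, bases, paste0)))
    .fx[[key]] <- out
  }
  .fx[[key]]
}

oracle_dense_kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1
  km <- substring(seq, 1:n, k:(n + k - 1))
  tabulate(match(km, oracle_kmer_levels(k)), nbins = 4^k)
}

oracle_kmer_distance <- function(s1, s2, k) {
  v1 <- oracle_dense_kmers(s1, k)
  v2 <- oracle_dense_kmers(s2, k)
  sum(abs(v1 - v2)) / sum(v1 + v2)
}

oracle_sample_distance <- function(g1, g2, k) {
  shared <- intersect(names(g1$targets), names(g2$targets))
  per_t <- numeric(0)
  for (t in shared) {
    acc <- 0
    for (a in g1$targets[[t]]) for (b in g2$targets[[t]])
      acc <- acc + oracle_kmer_distance(a, b, k)
    per_t <- c(per_t, acc / (length(g1$targets[[t]]) * length(g2$targets[[t]])))
  }
  mean(per_t)
}

## ---- brute-force nearest-neighbour assignment ---------------------------

## exhaustive re-derivation of the per-level assignment proportions for one
## query, with dense tables and plain loops
oracle_assign <- function(query, db, partitions, k = 8) {
  ref <- db$genotypes
  per_level_acc <- lapply(partitions, function(p) list())
  n_used <- 0
  for (t in names(query$targets)) {
    ref_entries <- list()
    for (g in ref) {
      if (!t %in% names(g$targets)) next
      for (h in g$targets[[t]])
        ref_entries[[length(ref_entries) + 1]] <-
          list(sample = g$sample_id, seq = h,
               w = 2 / length(g$targets[[t]]))
    }
    if (length(ref_entries) == 0) next
    n_used <- n_used + 1
    hap_props <- lapply(partitions, function(p) list())
    for (q in query$targets[[t]]) {
      d <- vapply(ref_entries,
                  function(e) oracle_kmer_distance(q, e$seq, k), numeric(1))
      nn <- which(d <= min(d) + 1e-12)
      for (lv in names(partitions)) {
        memb <- partitions[[lv]]$membership
        amp <- unique(vapply(ref_entries, `[[`, "", "sample"))
        groups <- sort(unique(memb[amp]))
        freq <- sapply(groups, function(gr) {
          num <- 0
          for (i in nn) if (memb[[ref_entries[[i]]$sample]] == gr)
            num <- num + ref_entries[[i]]$w
          num / (2 * sum(memb[amp] == gr))
        })
        hap_props[[lv]][[length(hap_props[[lv]]) + 1]] <- freq / sum(freq)
      }
    }
    for (lv in names(partitions)) {
      groups <- sort(unique(unlist(lapply(hap_props[[lv]], names))))
      m <- sapply(hap_props[[lv]], function(v) {
        out <- setNames(numeric(length(groups)), groups)
        out[names(v)] <- v
        out
      })
      per_level_acc[[lv]][[t]] <- if (is.matrix(m)) rowMeans(m)
                                  else setNames(mean(m), groups)
    }
  }
  lapply(per_level_acc, function(acc) {
    groups <- sort(unique(unlist(lapply(acc, names))))
    m <- sapply(acc, function(v) {
      out <- setNames(numeric(length(groups)), groups)
      out[names(v)] <- v
      out
    })
    if (is.matrix(m)) rowMeans(m) else setNames(mean(m), groups)
  })
}

## ---- hull oracles -------------------------------------------------------

## dense barycentric sampling of the hull surface (tetrahedra: all 4 facets)
oracle_surface_distance <- function(p, vertices, m = 1200) {
  combs <- utils::combn(nrow(vertices), 3)
  best <- Inf
  grid <- expand.grid(i = 0:m, j = 0:m)
  grid <- grid[grid$i + grid$j <= m, ]
  l1 <- grid$i / m; l2 <- grid$j / m; l3 <- 1 - l1 - l2
  for (c_i in seq_len(ncol(combs))) {
    tri <- vertices[combs[, c_i], , drop = FALSE]
    pts <- cbind(l1, l2, l3) %*% tri
    best <- min(best, sqrt(min(rowSums(sweep(pts, 2, p)^2))))
  }
  best
}

## axis-aligned box hull, for exact known point distances
box_hull <- function(xr, yr = c(0, 1), zr = c(0, 1), label = "box") {
  v <- as.matrix(expand.grid(xr, yr, zr))
  colnames(v) <- NULL
  build_hulls(v, rep(label, 8))[[1]]
}

## a small hand-built database used in worked-example tests: `far` is a
## sequence very distant from everything built on a disjoint alphabet walk
worked_example_db <- function() {
  near <- "ACGTACGTACGTACGTACGT"          # the nearest-neighbour allele
  far1 <- "GGGGGGGGGGCCCCCCCCCC"
  far2 <- "TTTTTTTTTTAAAAAAAAAA"
  gts <- list()
  ## species-group A: 10 homozygous samples, 2 carrying the NN allele
  for (i in 1:10) {
    gts[[sprintf("A%02d", i)]] <- sample_genotypes(
      sprintf("A%02d", i), list(t1 = if (i <= 2) near else far1))
  }
  ## species-group B: 2 homozygous samples, 1 carrying the NN allele
  gts[["B01"]] <- sample_genotypes("B01", list(t1 = near))
  gts[["B02"]] <- sample_genotypes("B02", list(t1 = far2))
  labels <- setNames(c(rep("spA", 10), rep("spB", 2)), names(gts))
  db <- reference_db(gts, labels, version = "worked-example", k = 4,
                     min_targets = 1)
  memb <- setNames(c(rep("A", 10), rep("B", 2)), names(gts))
  partition <- structure(list(level_name = "fine", threshold = 0.1,
                              membership = memb,
                              group_labels = c(A = "spA", B = "spB")),
                         class = "species_partition")
  list(db = db, partition = partition, near = near)
}
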