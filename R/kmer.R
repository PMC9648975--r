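#' k-mer count table of a DNA sequence
#'
#' Translates a DNA sequence into its table of overlapping k-mer counts. The
#' table conceptually has one column per possible k-mer (4^k columns, in
#' lexicographic order over A < C < G < T); since amplicon haplotypes populate
#' only a tiny fraction of the 65,536 columns at k = 8, counts are stored
#' sparsely as (index, count) pairs. Use [as_kmer_vector()] for the dense view.
#'
#' @param seq a DNA string over A, C, G, T (upper case).
#' @param k k-mer length; the sequence must be at least k bases long.
#' @param lenient if `TRUE`, k-mer windows containing a symbol outside
#'   A/C/G/T are dropped instead of raising an error. The default is strict:
#'   consensus amplicon haplotypes should be clean, and silently skipping
#'   windows can hide upstream problems.
#' @return an object of class `kmer_counts`: a list with elements `k`,
#'   `idx` (sorted 1-based indices into the 4^k table) and `counts`
#'   (positive integers), plus `total` (sum of counts).
#' @examples
#' kmer_counts("AACTACTCT", 2)
#' @export
kmer_counts <- function(seq, k, lenient = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  k <- as.integer(k)
  if (k < 1L || k > 15L) stop("k must be in [1, 15]")
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k (length ", L, " < ", k, ")")
  code <- .base4_digits(seq)
  if (anyNA(code) && !lenient) {
    bad <- which(is.na(code))[1L]
    stop("illegal symbol '", substr(seq, bad, bad), "' at position ", bad,
         " (only A/C/G/T allowed; use lenient = TRUE to drop affected k-mers)")
  }
  m <- L - k + 1L
  vals <- numeric(m)
  for (j in seq_len(k)) {
    vals <- vals + code[j:(j + m - 1L)] * 4^(k - j)
  }
  vals <- vals[!is.na(vals)]   # lenient mode: windows touching a bad symbol
  if (length(vals) == 0L) stop("no valid k-mer windows in sequence")
  idx <- sort(unique(vals)) + 1
  cnt <- tabulate(match(vals, idx - 1), nbins = length(idx))
  structure(list(k = k, idx = as.double(idx), counts = as.integer(cnt),
                 total = length(vals)),
            class = "kmer_counts")
}

## per-base codes A=0, C=1, G=2, T=3, NA otherwise
.base4_digits <- function(seq) {
  lut <- rep(NA_real_, 256)
  lut[utf8ToInt("A") + 1L] <- 0
  lut[utf8ToInt("C") + 1L] <- 1
  lut[utf8ToInt("G") + 1L] <- 2
  lut[utf8ToInt("T") + 1L] <- 3
  lut[utf8ToInt(seq) + 1L]
}

#' All k-mers of a given length in canonical (lexicographic) order
#'
#' @param k k-mer length.
#' @return character vector of length 4^k.
#' @export
kmer_names <- function(k) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= 10L)
  bases <- c("A", "C", "G", "T")
  out <- bases
  for (i in seq_len(k - 1L)) out <- as.vector(t(outer(out, bases, paste0)))
  out
}

#' Dense view of a k-mer count table
#'
#' @param x a `kmer_counts` object.
#' @param named if `TRUE` (default for k <= 10), name entries by k-mer.
#' @return integer vector of length 4^k.
#' @export
as_kmer_vector <- function(x, named = x$k <= 10L) {
  stopifnot(inherits(x, "kmer_counts"))
  v <- integer(4^x$k)
  v[x$idx] <- x$counts
  if (named) names(v) <- kmer_names(x$k)
  v
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("k-mer count table (k = ", x$k, "): ", length(x$idx),
      " distinct k-mers, total count ", x$total, "\n", sep = "")
  if (x$k <= 6L) {
    nm <- kmer_names(x$k)[x$idx]
    print(stats::setNames(x$counts, nm))
  }
  invisible(x)
}

#' k-mer distance between two count tables
#'
#' The number of non-matching k-mers divided by the total k-mer count of both
#' tables, `sum(|q1 - q2|) / sum(q1 + q2)`. The denominator normalises for
#' sequence length, which would otherwise bias towards smaller distances for
#' shorter sequences. The distance is symmetric, zero exactly for identical
#' tables, and one exactly when the tables share no k-mer. It uses counts,
#' not mere presence/absence.
#'
#' @param t1,t2 `kmer_counts` objects with the same `k`.
#' @return a number in \[0, 1\].
#' @examples
#' kmer_distance(kmer_counts("AACTACTCT", 2), kmer_counts("AGCTACTT", 2)) # 7/15
#' @export
kmer_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "kmer_counts"), inherits(t2, "kmer_counts"))
  if (t1$k != t2$k) stop("mismatched k: ", t1$k, " vs ", t2$k)
  tot <- t1$total + t2$total
  if (tot == 0) stop("both tables are empty")
  common <- match(t1$idx, t2$idx)
  hit <- !is.na(common)
  ## |a-b| over shared indices; private indices contribute their full counts
  num <- sum(abs(t1$counts[hit] - t2$counts[common[hit]])) +
    sum(t1$counts[!hit]) + (t2$total - sum(t2$counts[common[hit]]))
  num / tot
}

#' Per-sample genotypes over amplicon targets
#'
#' A sample's amplified targets with, per target, its list of unique haplotype
#' sequences. Missing targets are absent from the list (never empty).
#'
#' @param sample_id sample identifier.
#' @param targets named list: target id -> character vector of unique
#'   haplotype sequences.
#' @return an object of class `sample_genotypes`.
#' @export
sample_genotypes <- function(sample_id, targets) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.list(targets))
  if (length(targets) > 0 && is.null(names(targets)))
    stop("targets must be a named list")
  for (t in names(targets)) {
    h <- targets[[t]]
    if (!is.character(h) || length(h) == 0L)
      stop("target ", t, ": haplotype list must be a non-empty character vector")
    if (anyDuplicated(h))
      stop("target ", t, ": duplicate haplotype sequences")
  }
  structure(list(sample_id = sample_id, targets = targets),
            class = "sample_genotypes")
}

#' @export
print.sample_genotypes <- function(x, ...) {
  nh <- lengths(x$targets)
  cat("sample ", x$sample_id, ": ", length(x$targets), " amplified targets (",
      sum(nh == 1L), " hom, ", sum(nh == 2L), " het, ", sum(nh > 2L),
      " multi-allelic)\n", sep = "")
  invisible(x)
}

## cache of kmer_counts for every haplotype of a genotype list:
## list per sample -> list per target -> list of kmer_counts
.kmer_cache <- function(samples, k, lenient = FALSE) {
  lapply(samples, function(s)
    lapply(s$targets, function(haps)
      lapply(haps, kmer_counts, k = k, lenient = lenient)))
}

## mean distance over all haplotype pairs at shared targets, given caches
.pair_distance_cached <- function(c1, c2) {
  shared <- intersect(names(c1), names(c2))
  if (length(shared) == 0L) return(NA_real_)
  per_target <- vapply(shared, function(t) {
    d <- outer(seq_along(c1[[t]]), seq_along(c2[[t]]),
               Vectorize(function(i, j) kmer_distance(c1[[t]][[i]], c2[[t]][[j]])))
    mean(d)
  }, numeric(1))
  mean(per_target)
}

#' k-mer distance between two samples
#'
#' For each target amplified in both samples, the mean k-mer distance over all
#' pairs of haplotypes (one from each sample) is computed; the sample distance
#' is the unweighted mean of these per-target means. A homozygous sample
#' contributes its single haplotype, a heterozygous one both, and samples with
#' more than two alleles contribute all of them (the per-target denominator is
#' the product of the two haplotype-list sizes).
#'
#' @param s1,s2 `sample_genotypes` sharing at least one amplified target.
#' @param k k-mer length (default 8).
#' @return a number in \[0, 1\].
#' @export
sample_pair_distance <- function(s1, s2, k = 8) {
  stopifnot(inherits(s1, "sample_genotypes"), inherits(s2, "sample_genotypes"))
  d <- .pair_distance_cached(.kmer_cache(list(s1), k)[[1]],
                             .kmer_cache(list(s2), k)[[1]])
  if (is.na(d))
    stop("distance undefined: samples ", s1$sample_id, " and ", s2$sample_id,
         " share no amplified target")
  d
}

#' Pairwise sample distance matrix
#'
#' Computes the full symmetric matrix of pairwise sample k-mer distances. A
#' pair of samples with no shared amplified target gets the sentinel distance
#' 1.0 with a warning, so matrix-level operations stay total (the point
#' operation [sample_pair_distance()] still errors in that case).
#'
#' @param samples list of `sample_genotypes`.
#' @param k k-mer length (default 8).
#' @return square numeric matrix with sample ids as dimnames, zero diagonal.
#' @export
pairwise_distance_matrix <- function(samples, k = 8) {
  if (length(samples) == 0L) stop("empty sample list")
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  caches <- .kmer_cache(samples, k)
  n <- length(samples)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  no_overlap <- character(0)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d <- .pair_distance_cached(caches[[i]], caches[[j]])
    if (is.na(d)) {
      no_overlap <- c(no_overlap, paste0(ids[i], "/", ids[j]))
      d <- 1.0
    }
    D[i, j] <- D[j, i] <- d
  }
  if (length(no_overlap) > 0L)
    warning("no shared targets (distance set to sentinel 1.0) for pairs: ",
            paste(no_overlap, collapse = ", "))
  D
}

#' Probability that all k-mers of a sequence are distinct
#'
#' Birthday-model probability that the L - k + 1 overlapping k-mers of a
#' random sequence of length L are all different, treating each k-mer as a
#' uniform draw from the 4^k possibilities. This quantifies the resolution
#' trade-off in the choice of k: for small k repeated k-mers are near-certain
#' within a single amplicon, while k = 8 keeps targets of typical length
#' (~160 bp) mostly repeat-free.
#'
#' @param seq_length sequence length L in bp.
#' @param k k-mer length.
#' @return probability in \[0, 1\] (computed on the log scale).
#' @examples
#' prob_all_kmers_distinct(160, 8)  # about 0.84
#' @export
prob_all_kmers_distinct <- function(seq_length, k) {
  n <- seq_length - k + 1
  stopifnot(n >= 1)
  N <- 4^k
  if (n > N) return(0)
  exp(sum(log1p(-(seq_len(n) - 1) / N)))
}

#' Read haplotypes from FASTA
#'
#' Each record header is `sampleID|targetID|hapIndex`; the sequence is one
#' haplotype of that sample at that target.
#'
#' @param path FASTA file path.
#' @return data.frame with columns sample, target, sequence.
#' @export
read_haplotype_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L)
    stop("malformed FASTA header (expected sampleID|targetID|hapIndex) at record ",
         bad[1L])
  data.frame(sample = vapply(parts, `[`, "", 1L),
             target = vapply(parts, `[`, "", 2L),
             sequence = as.character(ss),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write haplotypes to FASTA
#'
#' @param records data.frame with columns sample, target, sequence.
#' @param path output path.
#' @export
write_haplotype_fasta <- function(records, path) {
  idx <- stats::ave(seq_len(nrow(records)),
                    records$sample, records$target, FUN = seq_along)
  ss <- Biostrings::DNAStringSet(records$sequence)
  names(ss) <- paste(records$sample, records$target, idx, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write / read a square distance matrix as TSV
#'
#' @param D square numeric matrix with sample-id dimnames.
#' @param path file path.
#' @param long also write a long-format companion
#'   (`<path>.long.tsv`: sample1, sample2, distance) if `TRUE`.
#' @export
write_distance_matrix <- function(D, path, long = FALSE) {
  utils::write.table(data.frame(sample = rownames(D), D, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (long) {
    iu <- which(upper.tri(D), arr.ind = TRUE)
    utils::write.table(
      data.frame(sample1 = rownames(D)[iu[, 1]], sample2 = colnames(D)[iu[, 2]],
                 distance = D[iu]),
      paste0(path, ".long.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  D <- as.matrix(x[, -1, drop = FALSE])
  rownames(D) <- x[[1]]
  storage.mode(D) <- "double"
  D
}
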