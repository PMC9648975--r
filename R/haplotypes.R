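#' Read a haplotype table
#'
#' Reads the tab-separated haplotype table produced by upstream amplicon
#' processing: one row per (sample, target, unique haplotype) with optional
#' supporting-read count and within-(sample, target) haplotype frequency.
#' In-silico sources (reference genomes, extracted WGS haplotypes) have no
#' read support and leave those columns absent or NA.
#'
#' @param path TSV with required columns `sample`, `target`, `sequence` and
#'   optional `reads_count`, `reads_fraction`.
#' @return data.frame of haplotype records, row order preserved.
#' @export
read_haplotype_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  validate_haplotype_records(parse_haplotype_records(x))
}

parse_haplotype_records <- function(x) {
  required <- c("sample", "target", "sequence")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L)
    stop("haplotype table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("reads_count", "reads_fraction")) {
    if (col %in% names(x)) {
      raw <- x[[col]]
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & raw != "" & raw != "NA" & is.na(val))
      if (length(bad) > 0L)
        stop("malformed ", col, " '", raw[bad[1L]], "' at row ", bad[1L])
      val[raw == "" | raw == "NA"] <- NA_real_
      x[[col]] <- val
    }
  }
  if ("reads_count" %in% names(x)) {
    bad <- which(!is.na(x$reads_count) &
                   (x$reads_count < 0 | x$reads_count != round(x$reads_count)))
    if (length(bad) > 0L)
      stop("reads_count must be a non-negative integer; offending row ", bad[1L])
  }
  if ("reads_fraction" %in% names(x)) {
    bad <- which(!is.na(x$reads_fraction) &
                   (x$reads_fraction < 0 | x$reads_fraction > 1))
    if (length(bad) > 0L)
      stop("reads_fraction must lie in [0, 1]; offending row ", bad[1L])
  }
  x
}

validate_haplotype_records <- function(x) {
  if (any(!nzchar(x$sequence)))
    stop("empty sequence at row ", which(!nzchar(x$sequence))[1L])
  key <- paste(x$sample, x$target, x$sequence, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    first <- match(key[dup[1L]], key)
    stop("duplicate (sample, target, sequence) rows: ", first, " and ", dup[1L])
  }
  x
}

#' Write a haplotype table
#'
#' @param records haplotype data.frame (as from [read_haplotype_table()]).
#' @param path output TSV path.
#' @export
write_haplotype_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Filter haplotypes on read support
#'
#' Keeps a haplotype record iff it is supported by at least `min_reads` read
#' pairs AND has within-(sample, target) frequency at least `min_fraction`
#' (both inclusive). Records without read support (in-silico sources) pass
#' unconditionally. The two conditions are applied jointly; as an AND they
#' are order-independent, and the filter is idempotent. Frequencies are not
#' recomputed after filtering: the upstream pipeline's values are
#' authoritative.
#'
#' @param records haplotype data.frame.
#' @param min_reads minimum supporting read pairs (default 10).
#' @param min_fraction minimum haplotype frequency (default 0.1).
#' @return the filtered data.frame.
#' @export
filter_haplotypes <- function(records, min_reads = 10, min_fraction = 0.1) {
  keep <- rep(TRUE, nrow(records))
  if ("reads_count" %in% names(records)) {
    has <- !is.na(records$reads_count)
    keep[has] <- keep[has] & records$reads_count[has] >= min_reads
  }
  if ("reads_fraction" %in% names(records)) {
    has <- !is.na(records$reads_fraction)
    keep[has] <- keep[has] & records$reads_fraction[has] >= min_fraction
  }
  records[keep, , drop = FALSE]
}

#' Assemble per-sample genotypes from haplotype records
#'
#' @param records filtered haplotype data.frame.
#' @return named list of [sample_genotypes()] objects (by sample id), in
#'   order of first appearance.
#' @export
build_genotypes <- function(records) {
  validate_haplotype_records(records)
  out <- list()
  for (sid in unique(records$sample)) {
    rs <- records[records$sample == sid, , drop = FALSE]
    targets <- split(rs$sequence, factor(rs$target, levels = unique(rs$target)))
    out[[sid]] <- sample_genotypes(sid, as.list(targets))
  }
  out
}

#' Per-sample quality control
#'
#' Reports the number of amplified targets, the fraction of targets with more
#' than two unique haplotypes (a contamination / duplication signal), and
#' whether the sample passes the target-count gates for nearest-neighbour
#' assignment (default 10 targets) and VAE classification (default 50),
#' both inclusive.
#'
#' @param genotypes a single `sample_genotypes` or a list of them.
#' @param nn_gate,vae_gate minimum amplified-target counts.
#' @return data.frame with one row per sample: `sample_id`,
#'   `n_targets_amplified`, `multiallelic_fraction`, `passes_nn_gate`,
#'   `passes_vae_gate`.
#' @export
qc_sample <- function(genotypes, nn_gate = 10, vae_gate = 50) {
  if (inherits(genotypes, "sample_genotypes")) genotypes <- list(genotypes)
  rows <- lapply(genotypes, function(g) {
    n <- length(g$targets)
    data.frame(sample_id = g$sample_id,
               n_targets_amplified = n,
               multiallelic_fraction =
                 if (n == 0L) 0 else mean(lengths(g$targets) > 2L),
               passes_nn_gate = n >= nn_gate,
               passes_vae_gate = n >= vae_gate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Build a labelled reference database
#'
#' Bundles labelled sample genotypes into a versioned reference database.
#' Samples need at least `min_targets` amplified targets (default 10, the
#' nearest-neighbour gate) to be included; rejected samples are reported in
#' the `rejected` element.
#'
#' @param genotypes list of `sample_genotypes`.
#' @param labels named character vector: sample id -> species label.
#' @param version database version string.
#' @param k k-mer length the database is meant to be used with (default 8).
#' @param min_targets inclusion gate on amplified targets.
#' @return object of class `reference_db` with elements `genotypes`
#'   (named list), `labels`, `version`, `k`, `rejected` (data.frame).
#' @export
reference_db <- function(genotypes, labels, version = "v1", k = 8,
                         min_targets = 10) {
  ids <- vapply(genotypes, function(g) g$sample_id, character(1))
  names(genotypes) <- ids
  missing_lab <- setdiff(ids, names(labels))
  if (length(missing_lab) > 0L)
    stop("no species label for sample(s): ", paste(missing_lab, collapse = ", "))
  nt <- vapply(genotypes, function(g) length(g$targets), integer(1))
  rejected <- data.frame(sample_id = ids[nt < min_targets],
                         n_targets = nt[nt < min_targets],
                         reason = rep(sprintf("fewer than %d amplified targets",
                                              min_targets), sum(nt < min_targets)),
                         stringsAsFactors = FALSE, row.names = NULL)
  keep <- nt >= min_targets
  structure(list(genotypes = genotypes[keep],
                 labels = labels[ids[keep]],
                 version = version, k = as.integer(k),
                 rejected = rejected),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("reference database ", x$version, ": ", length(x$genotypes),
      " samples, ", length(unique(x$labels)), " species labels (k = ", x$k,
      ")\n", sep = "")
  if (nrow(x$rejected) > 0L)
    cat("  rejected at build: ", nrow(x$rejected), " sample(s)\n", sep = "")
  invisible(x)
}

#' Save / load a reference database bundle
#'
#' A bundle is a directory holding `haplotypes.tsv`, `labels.tsv`,
#' `manifest.json` (version, k) and, when partitions have been attached via
#' [build_level_partitions()], `partitions.tsv`.
#'
#' @param db a `reference_db`.
#' @param dir bundle directory (created if needed).
#' @param partitions optional `species_partitions` object to store alongside.
#' @export
save_reference_db <- function(db, dir, partitions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(db$genotypes, function(g) {
    do.call(rbind, lapply(names(g$targets), function(t)
      data.frame(sample = g$sample_id, target = t,
                 sequence = g$targets[[t]], stringsAsFactors = FALSE)))
  }))
  write_haplotype_table(rows, file.path(dir, "haplotypes.tsv"))
  utils::write.table(
    data.frame(sample = names(db$labels), species = unname(db$labels)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(version = db$version, k = db$k),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  if (!is.null(partitions))
    write_partitions(partitions, file.path(dir, "partitions.tsv"))
  invisible(dir)
}

#' @rdname save_reference_db
#' @export
load_reference_db <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  records <- read_haplotype_table(file.path(dir, "haplotypes.tsv"))
  lab <- utils::read.delim(file.path(dir, "labels.tsv"),
                           stringsAsFactors = FALSE)
  db <- reference_db(build_genotypes(records),
                     stats::setNames(lab$species, lab$sample),
                     version = manifest$version, k = manifest$k)
  pfile <- file.path(dir, "partitions.tsv")
  if (file.exists(pfile)) attr(db, "partitions") <- read_partitions(pfile)
  db
}
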