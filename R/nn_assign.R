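#' @title Nearest-neighbour species-group assignment
#' @description Per-target nearest-neighbour search against a reference
#'   database, frequency-normalised assignment proportions, hierarchical
#'   classification at the fine / intermediate / coarse species-group levels,
#'   and drop-one-out validation.
#' @name nn_assignment
NULL

## Precomputed per-target index of the reference database: for each target,
## one entry per unique reference haplotype with its sample, its k-mer table,
## and its allele-copy weight (2 / |Q| so every sample carries total weight 2:
## homozygote 2, heterozygote 1 + 1, >2 alleles 2/|Q| each).
db_index <- function(db, k = db$k) {
  entries <- list()
  for (g in db$genotypes) {
    for (t in names(g$targets)) {
      haps <- g$targets[[t]]
      w <- 2 / length(haps)
      e <- entries[[t]]
      if (is.null(e)) e <- list(sample = character(0), table = list(),
                                weight = numeric(0))
      for (h in haps) {
        e$sample <- c(e$sample, g$sample_id)
        e$table[[length(e$table) + 1L]] <- kmer_counts(h, k)
        e$weight <- c(e$weight, w)
      }
      entries[[t]] <- e
    }
  }
  structure(list(targets = entries, k = k,
                 sample_ids = names(db$genotypes)),
            class = "db_index")
}

index_drop_sample <- function(index, sample_id) {
  targets <- lapply(index$targets, function(e) {
    keep <- e$sample != sample_id
    if (!any(keep)) return(NULL)
    list(sample = e$sample[keep], table = e$table[keep],
         weight = e$weight[keep])
  })
  targets <- targets[!vapply(targets, is.null, logical(1))]
  structure(list(targets = targets, k = index$k,
                 sample_ids = setdiff(index$sample_ids, sample_id)),
            class = "db_index")
}

#' Nearest-neighbour haplotypes of a query k-mer table at one target
#'
#' Returns every reference haplotype at the target attaining the minimal
#' k-mer distance to the query. Distinct sequences at exactly the same
#' distance are all included; distances within `tol` (default 1e-12, guarding
#' against floating-point representation of rational distances) count as
#' equal.
#'
#' @param query_table `kmer_counts` of one query haplotype.
#' @param target_id target identifier.
#' @param db a `reference_db`, or a prebuilt index from internal use.
#' @param k k-mer length (ignored when an index is supplied).
#' @param tol distance-tie tolerance.
#' @return list with `hits` (data.frame: `sample`, `hap`), `distance` (the
#'   minimum), or an empty `hits` data.frame when no reference sample
#'   amplified the target.
#' @export
nearest_neighbour_set <- function(query_table, target_id, db, k = 8,
                                  tol = 1e-12) {
  index <- if (inherits(db, "db_index")) db else db_index(db, k)
  e <- index$targets[[target_id]]
  if (is.null(e))
    return(list(hits = data.frame(sample = character(0), hap = integer(0)),
                distance = NA_real_))
  d <- vapply(e$table, kmer_distance, numeric(1), t2 = query_table)
  dmin <- min(d)
  sel <- which(d <= dmin + tol)
  list(hits = data.frame(sample = e$sample[sel], hap = sel,
                         stringsAsFactors = FALSE),
       distance = dmin)
}

#' Nearest-neighbour allele frequencies per species-group
#'
#' For each species-group, the frequency of nearest-neighbour sequences among
#' the group's allele copies at the target: the weighted count of NN
#' haplotypes carried by the group's samples divided by the total allele
#' copies (2 per amplified sample) of the group at that target. Weighting by
#' allele copies makes the frequency zygosity-aware, and using frequencies
#' rather than raw counts corrects for unequal species-group sizes.
#'
#' @param nn_set result of [nearest_neighbour_set()].
#' @param target_id target identifier.
#' @param db `reference_db` or prebuilt index.
#' @param partition a `species_partition` over the reference samples.
#' @param k k-mer length (ignored when an index is supplied).
#' @return named numeric vector of frequencies over the groups amplified at
#'   the target.
#' @export
group_frequencies <- function(nn_set, target_id, db, partition, k = 8) {
  index <- if (inherits(db, "db_index")) db else db_index(db, k)
  e <- index$targets[[target_id]]
  if (is.null(e)) return(stats::setNames(numeric(0), character(0)))
  memb <- partition$membership
  amp_samples <- unique(e$sample)
  groups <- sort(unique(memb[amp_samples]))
  denom <- vapply(groups, function(g)
    2 * sum(memb[amp_samples] == g), numeric(1))
  num <- stats::setNames(numeric(length(groups)), groups)
  if (nrow(nn_set$hits) > 0L) {
    hit_groups <- memb[nn_set$hits$sample]
    w <- e$weight[nn_set$hits$hap]
    for (i in seq_along(w)) num[hit_groups[i]] <- num[hit_groups[i]] + w[i]
  }
  stats::setNames(num / denom, groups)
}

#' Normalise group frequencies to per-target assignment proportions
#'
#' Frequencies are normalised to sum to one over all species-groups, so each
#' target carries equal weight regardless of how common its nearest-neighbour
#' sequences are overall.
#'
#' @param freqs named numeric of per-group frequencies.
#' @return named numeric summing to 1.
#' @export
per_target_proportions <- function(freqs) {
  s <- sum(freqs)
  if (length(freqs) == 0L || s <= 0)
    stop("cannot normalise: no positive nearest-neighbour frequency")
  freqs / s
}

## per-target proportions for one query haplotype, at all three levels
.hap_level_proportions <- function(qtab, target_id, index, partitions, tol) {
  nn <- nearest_neighbour_set(qtab, target_id, index, tol = tol)
  if (nrow(nn$hits) == 0L) return(NULL)
  lapply(partitions, function(p)
    per_target_proportions(group_frequencies(nn, target_id, index, p)))
}

#' Assign a query sample to species-groups
#'
#' Implements hierarchical nearest-neighbour assignment: per amplified target
#' shared with the database, per-target assignment proportions are computed
#' for each of the query's haplotypes separately (so heterozygous and
#' multi-allelic targets contribute the average over their unique sequences)
#' and averaged; the overall proportions at each level are the unweighted
#' mean over targets. Targets missing from the query or from the database are
#' simply ignored. At each level the query is classified to the top group if
#' its proportion reaches `threshold` (inclusive), else left "unassigned".
#' All three levels reuse the same per-target nearest-neighbour sets.
#'
#' @param query a `sample_genotypes` with at least `nn_gate` amplified
#'   targets.
#' @param db a `reference_db` (or prebuilt index).
#' @param partitions a `species_partitions` (fine / intermediate / coarse).
#' @param k k-mer length (default 8).
#' @param threshold classification threshold on the assignment proportion
#'   (default 0.8, inclusive).
#' @param nn_gate minimum amplified targets required (default 10, inclusive).
#' @param tol nearest-neighbour distance-tie tolerance.
#' @return object of class `nn_assignment`: `sample_id`, `n_targets_used`,
#'   `levels` (per level: `proportions`, `outcome`), and `detail`
#'   (per-target per-level proportion table).
#' @export
assign_sample <- function(query, db, partitions, k = 8, threshold = 0.8,
                          nn_gate = 10, tol = 1e-12) {
  stopifnot(inherits(query, "sample_genotypes"))
  if (length(query$targets) < nn_gate)
    stop("sample ", query$sample_id, " has ", length(query$targets),
         " amplified targets; the nearest-neighbour gate requires at least ",
         nn_gate)
  index <- if (inherits(db, "db_index")) db else db_index(db, k)
  shared <- intersect(names(query$targets), names(index$targets))
  if (length(shared) == 0L)
    stop("sample ", query$sample_id,
         " shares no amplified target with the reference database")
  level_names <- names(partitions)
  acc <- stats::setNames(vector("list", length(level_names)), level_names)
  detail <- list()
  n_used <- 0L
  for (t in shared) {
    per_hap <- lapply(query$targets[[t]],
                      function(h) .hap_level_proportions(kmer_counts(h, index$k),
                                                         t, index, partitions, tol))
    per_hap <- per_hap[!vapply(per_hap, is.null, logical(1))]
    if (length(per_hap) == 0L) next
    n_used <- n_used + 1L
    for (lv in level_names) {
      groups <- sort(unique(unlist(lapply(per_hap, function(x) names(x[[lv]])))))
      m <- vapply(per_hap, function(x) {
        v <- stats::setNames(numeric(length(groups)), groups)
        v[names(x[[lv]])] <- x[[lv]]
        v
      }, numeric(length(groups)))
      tp <- if (is.matrix(m)) rowMeans(m) else stats::setNames(mean(m), groups)
      acc[[lv]][[t]] <- tp
      detail[[length(detail) + 1L]] <-
        data.frame(target = t, level = lv, group = names(tp),
                   proportion = unname(tp), stringsAsFactors = FALSE)
    }
  }
  if (n_used == 0L)
    stop("sample ", query$sample_id,
         " shares no amplified target with the reference database")
  levels <- lapply(level_names, function(lv) {
    groups <- sort(unique(unlist(lapply(acc[[lv]], names))))
    m <- vapply(acc[[lv]], function(v) {
      out <- stats::setNames(numeric(length(groups)), groups)
      out[names(v)] <- v
      out
    }, numeric(length(groups)))
    props <- if (is.matrix(m)) rowMeans(m) else stats::setNames(mean(m), groups)
    props <- sort(props, decreasing = TRUE)
    top <- names(props)[1L]
    outcome <- if (props[[1L]] >= threshold) top else "unassigned"
    list(proportions = props, outcome = outcome)
  })
  names(levels) <- level_names
  structure(list(sample_id = query$sample_id, n_targets_used = n_used,
                 threshold = threshold, levels = levels,
                 detail = do.call(rbind, c(detail, list(make.row.names = FALSE)))),
            class = "nn_assignment")
}

#' @export
print.nn_assignment <- function(x, ...) {
  cat("nearest-neighbour assignment of ", x$sample_id, " (",
      x$n_targets_used, " targets used, threshold ", x$threshold, ")\n",
      sep = "")
  for (lv in names(x$levels)) {
    l <- x$levels[[lv]]
    top <- utils::head(l$proportions, 3)
    cat(sprintf("  %-13s %-12s top: %s\n", lv, l$outcome,
                paste(sprintf("%s=%.3f", names(top), top), collapse = " ")))
  }
  invisible(x)
}

#' Assign many query samples
#'
#' @inheritParams assign_sample
#' @param queries list of `sample_genotypes`.
#' @param on_error "skip" records gate/overlap failures in the table with
#'   outcome "failed_qc"; "stop" propagates them.
#' @return list with `assignments` (list of `nn_assignment`) and `table`
#'   (long data.frame: sample, level, group, proportion, outcome).
#' @export
assign_samples <- function(queries, db, partitions, k = 8, threshold = 0.8,
                           nn_gate = 10, on_error = c("skip", "stop")) {
  on_error <- match.arg(on_error)
  index <- if (inherits(db, "db_index")) db else db_index(db, k)
  assignments <- list()
  rows <- list()
  for (q in queries) {
    a <- tryCatch(assign_sample(q, index, partitions, k = k,
                                threshold = threshold, nn_gate = nn_gate),
                  error = function(e) if (on_error == "stop") stop(e) else e)
    if (inherits(a, "error")) {
      rows[[length(rows) + 1L]] <-
        data.frame(sample = q$sample_id, level = NA_character_,
                   group = NA_character_, proportion = NA_real_,
                   outcome = "failed_qc", stringsAsFactors = FALSE)
      next
    }
    assignments[[q$sample_id]] <- a
    for (lv in names(a$levels)) {
      l <- a$levels[[lv]]
      rows[[length(rows) + 1L]] <-
        data.frame(sample = q$sample_id, level = lv,
                   group = names(l$proportions),
                   proportion = unname(l$proportions),
                   outcome = l$outcome, stringsAsFactors = FALSE)
    }
  }
  list(assignments = assignments,
       table = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Drop-one-out validation of a reference database
#'
#' Each database sample in turn is removed and assigned against the
#' remainder. Samples that form a singleton group at a level cannot be
#' assigned correctly there (no same-group neighbour exists) and are excluded
#' from that level's accuracy, reported separately.
#'
#' @inheritParams assign_sample
#' @return object of class `dropout_validation`: `per_sample` (sample,
#'   level, true group, singleton flag, correct-group proportion, outcome,
#'   correctness) and `summary` (per level: evaluated / singleton counts,
#'   accuracy, mean correct proportion).
#' @export
dropout_validation <- function(db, partitions, k = 8, threshold = 0.8,
                               nn_gate = 10) {
  stopifnot(length(db$genotypes) >= 2L)
  index <- db_index(db, k)
  rows <- list()
  for (sid in names(db$genotypes)) {
    reduced <- index_drop_sample(index, sid)
    a <- tryCatch(assign_sample(db$genotypes[[sid]], reduced, partitions,
                                k = k, threshold = threshold,
                                nn_gate = nn_gate),
                  error = function(e) NULL)
    for (lv in names(partitions)) {
      true_group <- partitions[[lv]]$membership[[sid]]
      singleton <- sum(partitions[[lv]]$membership == true_group) == 1L
      if (is.null(a)) {
        prop <- NA_real_; outc <- "failed_qc"
      } else {
        prop <- a$levels[[lv]]$proportions[true_group]
        prop <- if (is.na(prop)) 0 else unname(prop)
        outc <- a$levels[[lv]]$outcome
      }
      rows[[length(rows) + 1L]] <-
        data.frame(sample = sid, level = lv, true_group = true_group,
                   singleton = singleton, correct_proportion = prop,
                   outcome = outc,
                   correct = identical(outc, unname(true_group)),
                   stringsAsFactors = FALSE)
    }
  }
  per_sample <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  summ <- do.call(rbind, lapply(unique(per_sample$level), function(lv) {
    x <- per_sample[per_sample$level == lv, ]
    ev <- x[!x$singleton & x$outcome != "failed_qc", ]
    data.frame(level = lv, n_evaluated = nrow(ev),
               n_singleton = sum(x$singleton),
               accuracy = if (nrow(ev) > 0) mean(ev$correct) else NA_real_,
               mean_correct_proportion =
                 if (nrow(ev) > 0) mean(ev$correct_proportion) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_sample = per_sample, summary = summ),
            class = "dropout_validation")
}

#' @export
print.dropout_validation <- function(x, ...) {
  cat("drop-one-out validation\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write an assignment table as TSV
#'
#' @param result value of [assign_samples()] (or its `table` element).
#' @param path output path.
#' @export
write_assignments <- function(result, path) {
  tab <- if (is.data.frame(result)) result else result$table
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
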