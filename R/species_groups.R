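#' Partition samples into species-groups at a distance threshold
#'
#' Groups are the connected components of the graph with an edge between any
#' two samples whose k-mer distance is strictly below the threshold
#' (single-linkage at level t). This reproduces the ideal partition whenever
#' the partitioning condition holds -- all within-group distances below t and
#' all between-group distances above -- and degrades gracefully otherwise,
#' with violations surfaced by [partition_condition_report()]. Distances
#' exactly equal to t do not connect. Group numbering is deterministic:
#' groups are ordered by their lexicographically smallest member.
#'
#' @param D square symmetric distance matrix with sample-id dimnames.
#' @param t threshold in (0, 1).
#' @param level_name optional name ("fine", "intermediate", "coarse", ...).
#' @param labels optional named character vector sample -> species label used
#'   to derive human-readable group labels (majority label, with ties broken
#'   alphabetically, made unique per group).
#' @return object of class `species_partition`: list with `level_name`,
#'   `threshold`, `membership` (named character: sample -> group id) and
#'   `group_labels` (named character: group id -> label).
#' @export
partition_at_threshold <- function(D, t, level_name = NULL, labels = NULL) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), t > 0, t < 1)
  ids <- rownames(D)
  if (is.null(ids)) stop("distance matrix must carry sample ids as dimnames")
  adj <- D < t
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  ## renumber deterministically by smallest member sample id
  smallest <- vapply(split(ids, comp), min, character(1))
  ord <- order(smallest)
  renum <- match(comp, as.integer(names(smallest))[ord])
  gid <- sprintf("G%03d", renum)
  membership <- stats::setNames(gid, ids)
  group_labels <- stats::setNames(sort(unique(gid)), sort(unique(gid)))
  if (!is.null(labels)) {
    for (gg in names(group_labels)) {
      lab <- labels[ids[gid == gg]]
      tab <- sort(table(lab), decreasing = TRUE)
      group_labels[gg] <- names(tab)[1L]
    }
    group_labels <- stats::setNames(make.unique(unname(group_labels), sep = "_"),
                                    names(group_labels))
  }
  structure(list(level_name = level_name %||% sprintf("t%.3g", t),
                 threshold = t, membership = membership,
                 group_labels = group_labels),
            class = "species_partition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.species_partition <- function(x, ...) {
  cat("species-group partition '", x$level_name, "' at threshold ",
      x$threshold, ": ", length(unique(x$membership)), " group(s), ",
      length(x$membership), " samples\n", sep = "")
  invisible(x)
}

#' Check a partition against the partitioning condition
#'
#' The ideal partitioning condition requires every within-group pair to be
#' closer than the threshold and every between-group pair to be farther.
#' Real databases violate it to some degree; this report lists every
#' violating pair of both kinds.
#'
#' @param D distance matrix.
#' @param partition a `species_partition` covering all samples of `D`.
#' @param t threshold (defaults to the partition's own).
#' @return list with data.frames `within_violations` (same group, distance
#'   > t) and `between_violations` (different groups, distance < t); both
#'   empty iff the condition holds exactly.
#' @export
partition_condition_report <- function(D, partition, t = partition$threshold) {
  ids <- rownames(D)
  stopifnot(all(ids %in% names(partition$membership)))
  memb <- partition$membership[ids]
  iu <- which(upper.tri(D), arr.ind = TRUE)
  same <- memb[iu[, 1]] == memb[iu[, 2]]
  d <- D[iu]
  mk <- function(sel) data.frame(sample1 = ids[iu[sel, 1]],
                                 sample2 = ids[iu[sel, 2]],
                                 distance = d[sel],
                                 stringsAsFactors = FALSE, row.names = NULL)
  list(within_violations = mk(same & d > t),
       between_violations = mk(!same & d < t))
}

#' Build the nested fine / intermediate / coarse partitions
#'
#' Single-linkage partitions at strictly increasing thresholds are nested by
#' construction (an edge at a smaller threshold is an edge at every larger
#' one), so each fine group sits inside one intermediate group and each
#' intermediate group inside one coarse group.
#'
#' @param D distance matrix.
#' @param thresholds strictly increasing length-3 numeric (defaults
#'   0.1, 0.3, 0.51).
#' @param labels optional sample -> species labels, passed through to
#'   [partition_at_threshold()].
#' @return object of class `species_partitions`: named list `fine`,
#'   `intermediate`, `coarse` of `species_partition`s, with the matching
#'   [partition_condition_report()]s in attribute `reports`.
#' @export
build_level_partitions <- function(D, thresholds = c(0.1, 0.3, 0.51),
                                   labels = NULL) {
  stopifnot(length(thresholds) == 3L)
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  level_names <- c("fine", "intermediate", "coarse")
  parts <- mapply(partition_at_threshold, t = thresholds,
                  level_name = level_names,
                  MoreArgs = list(D = D, labels = labels), SIMPLIFY = FALSE)
  names(parts) <- level_names
  reports <- lapply(parts, function(p) partition_condition_report(D, p))
  structure(parts, reports = reports, class = "species_partitions")
}

#' @export
print.species_partitions <- function(x, ...) {
  for (p in x) print(p)
  invisible(x)
}

#' Flag samples whose distances contradict their species label
#'
#' A sample is flagged when its minimum distance to a sample carrying a
#' different label is smaller than its minimum distance to any sample with
#' its own label -- the signature of a mislabelled reference sample.
#' Samples whose label occurs only once are excluded (no same-label distance
#' exists).
#'
#' @param D distance matrix.
#' @param labels named character vector sample -> species label.
#' @return data.frame: `sample_id`, `label`, `min_same_label_distance`,
#'   `min_other_label_distance`, `nearest_foreign_label`; zero rows when all
#'   labels are distance-consistent.
#' @export
flag_label_inconsistencies <- function(D, labels) {
  ids <- rownames(D)
  stopifnot(all(ids %in% names(labels)))
  lab <- labels[ids]
  rows <- lapply(seq_along(ids), function(i) {
    same <- which(lab == lab[i]); same <- setdiff(same, i)
    if (length(same) == 0L) return(NULL)        # singleton label
    other <- which(lab != lab[i])
    if (length(other) == 0L) return(NULL)
    d_same <- min(D[i, same])
    j <- other[which.min(D[i, other])]
    if (D[i, j] < d_same)
      data.frame(sample_id = ids[i], label = lab[i],
                 min_same_label_distance = d_same,
                 min_other_label_distance = D[i, j],
                 nearest_foreign_label = lab[j],
                 stringsAsFactors = FALSE)
    else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(sample_id = character(0), label = character(0),
                      min_same_label_distance = numeric(0),
                      min_other_label_distance = numeric(0),
                      nearest_foreign_label = character(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write / read nested partitions as TSV
#'
#' One row per sample with its group id and group label at each level.
#'
#' @param partitions a `species_partitions`.
#' @param path file path.
#' @export
write_partitions <- function(partitions, path) {
  ids <- names(partitions[[1]]$membership)
  out <- data.frame(sample = ids, stringsAsFactors = FALSE)
  for (lv in names(partitions)) {
    p <- partitions[[lv]]
    out[[paste0(lv, "_group")]] <- unname(p$membership[ids])
    out[[paste0(lv, "_label")]] <- unname(p$group_labels[p$membership[ids]])
    out[[paste0(lv, "_threshold")]] <- p$threshold
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partitions
#' @export
read_partitions <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  levels <- sub("_group$", "", grep("_group$", names(x), value = TRUE))
  parts <- lapply(levels, function(lv) {
    memb <- stats::setNames(x[[paste0(lv, "_group")]], x$sample)
    gl <- unique(data.frame(g = x[[paste0(lv, "_group")]],
                            l = x[[paste0(lv, "_label")]]))
    structure(list(level_name = lv,
                   threshold = x[[paste0(lv, "_threshold")]][1L],
                   membership = memb,
                   group_labels = stats::setNames(gl$l, gl$g)),
              class = "species_partition")
  })
  names(parts) <- levels
  structure(parts, class = "species_partitions")
}
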