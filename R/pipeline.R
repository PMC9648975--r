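#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run with its documented default:
#' k-mer length 8; species-group thresholds 0.1 / 0.3 / 0.51; assignment
#' proportion threshold 0.8; target-count gates of 10 (nearest neighbour)
#' and 50 (VAE classification), with 45 required of reference samples used
#' to train the VAE; hull fuzzy-boundary ratio 7; special-pair distance 14.
#'
#' @param db_dir reference database bundle directory.
#' @param query_path query haplotype TSV.
#' @param out_dir output directory.
#' @param k k-mer length.
#' @param thresholds fine / intermediate / coarse distance thresholds.
#' @param nn_threshold classification threshold on assignment proportions.
#' @param nn_gate,vae_gate,train_gate target-count gates.
#' @param hull_ratio fuzzy-boundary ratio.
#' @param special_pair labels subject to the distance rule (NULL to disable).
#' @param special_dist distance threshold of the special rule.
#' @param vae a [vae_config()] for the within-complex stage.
#' @param min_hull_points minimum latent points required per fine group to
#'   build its hull.
#' @param seed master seed.
#' @return object of class `run_config` (a validated list).
#' @export
run_config <- function(db_dir, query_path, out_dir,
                       k = 8, thresholds = c(0.1, 0.3, 0.51),
                       nn_threshold = 0.8, nn_gate = 10, vae_gate = 50,
                       train_gate = 45, hull_ratio = 7,
                       special_pair = NULL, special_dist = 14,
                       vae = vae_config(), min_hull_points = 4, seed = 1) {
  stopifnot(k >= 2, k <= 12, length(thresholds) == 3,
            all(diff(thresholds) > 0), nn_threshold > 0, nn_threshold <= 1,
            hull_ratio > 0, special_dist > 0)
  structure(list(db_dir = db_dir, query_path = query_path, out_dir = out_dir,
                 k = k, thresholds = thresholds, nn_threshold = nn_threshold,
                 nn_gate = nn_gate, vae_gate = vae_gate,
                 train_gate = train_gate, hull_ratio = hull_ratio,
                 special_pair = special_pair, special_dist = special_dist,
                 vae = vae, min_hull_points = min_hull_points, seed = seed),
            class = "run_config")
}

#' Run the full assignment pipeline
#'
#' QC -> species-group partitions -> nearest-neighbour assignment ->
#' within-complex VAE projection and convex-hull classification, writing
#' every stage output plus a run summary and the resolved configuration to
#' `config$out_dir`. The VAE stage runs per intermediate-level group that
#' splits into several fine-level groups (a species complex): it trains on
#' the reference members with at least `train_gate` targets and classifies
#' the queries assigned to that group at the intermediate level that were
#' not classified at the fine level and have at least `vae_gate` targets.
#' Deterministic under a fixed seed.
#'
#' @param config a [run_config()].
#' @return object of class `pipeline_report`: per-stage tables and the
#'   per-sample terminal outcomes (every sample lands in exactly one of:
#'   a species/fine-group label, an `uncertain_*` call, classification at a
#'   coarser level, `unassigned`, or `failed_qc`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[pipeline] ", ...)

  db <- load_reference_db(config$db_dir)
  records <- read_haplotype_table(config$query_path)
  records <- filter_haplotypes(records)
  queries <- build_genotypes(records)
  log_stage("loaded ", length(db$genotypes), " reference and ",
            length(queries), " query samples")

  qc <- qc_sample(queries, nn_gate = config$nn_gate,
                  vae_gate = config$vae_gate)
  utils::write.table(qc, file.path(config$out_dir, "qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  D <- pairwise_distance_matrix(db$genotypes, k = config$k)
  partitions <- build_level_partitions(D, config$thresholds,
                                       labels = db$labels)
  write_partitions(partitions, file.path(config$out_dir, "partitions.tsv"))
  write_distance_matrix(D, file.path(config$out_dir, "reference_distances.tsv"))

  pass <- qc$sample_id[qc$passes_nn_gate]
  log_stage(length(pass), " of ", length(queries), " queries pass the ",
            config$nn_gate, "-target gate")
  nn <- assign_samples(queries[pass], db, partitions, k = config$k,
                       threshold = config$nn_threshold,
                       nn_gate = config$nn_gate)
  write_assignments(nn, file.path(config$out_dir, "nn_assignments.tsv"))

  terminal <- stats::setNames(rep("failed_qc", length(queries)),
                              names(queries))
  for (sid in pass) {
    a <- nn$assignments[[sid]]
    if (is.null(a)) next
    terminal[sid] <-
      if (a$levels$fine$outcome != "unassigned")
        partitions$fine$group_labels[[a$levels$fine$outcome]]
      else if (a$levels$intermediate$outcome != "unassigned")
        paste0("intermediate:",
               partitions$intermediate$group_labels[[a$levels$intermediate$outcome]])
      else if (a$levels$coarse$outcome != "unassigned")
        paste0("coarse:",
               partitions$coarse$group_labels[[a$levels$coarse$outcome]])
      else "unassigned"
  }

  ## within-complex VAE stage
  fine_of <- partitions$fine$membership
  int_of <- partitions$intermediate$membership
  complexes <- names(which(vapply(split(fine_of, int_of[names(fine_of)]),
                                  function(x) length(unique(x)),
                                  integer(1)) > 1L))
  vae_calls <- list()
  for (cx in complexes) {
    cand <- pass[vapply(pass, function(sid) {
      a <- nn$assignments[[sid]]
      !is.null(a) && a$levels$intermediate$outcome == cx &&
        a$levels$fine$outcome == "unassigned" &&
        length(queries[[sid]]$targets) >= config$vae_gate
    }, logical(1))]
    if (length(cand) == 0L) next
    members <- names(int_of)[int_of == cx]
    train_ids <- members[vapply(members, function(sid)
      length(db$genotypes[[sid]]$targets) >= config$train_gate, logical(1))]
    fine_groups <- split(train_ids, fine_of[train_ids])
    fine_groups <- fine_groups[lengths(fine_groups) >= config$min_hull_points]
    if (length(fine_groups) < 2L) {
      log_stage("complex ", cx, ": not enough reference depth for the VAE ",
                "stage; queries stay at their nearest-neighbour outcome")
      next
    }
    log_stage("complex ", cx, ": training VAE on ", length(train_ids),
              " reference samples for ", length(cand), " queries")
    train_ids <- unlist(fine_groups, use.names = FALSE)
    train_tab <- summed_diploid_tables(db$genotypes[train_ids], k = config$k,
                                       seed = config$seed)
    model <- train_vae(train_tab, config$vae)
    ref_latent <- encode_means(model, train_tab)
    lab <- partitions$fine$group_labels[fine_of[train_ids]]
    ## hulls can fail on a latent space that does not separate the fine
    ## groups (degenerate or inseparably overlapping point sets); queries
    ## then keep their nearest-neighbour outcome
    trimmed <- tryCatch(trim_overlaps(build_hulls(
      as.matrix(ref_latent[, paste0("mu", seq_len(config$vae$latent_dim))]),
      lab)), error = function(e) {
        log_stage("complex ", cx, ": hull construction failed (",
                  conditionMessage(e), "); VAE stage skipped")
        NULL
      })
    if (is.null(trimmed)) next
    q_tab <- summed_diploid_tables(queries[cand], k = config$k,
                                   seed = config$seed + 1)
    q_latent <- encode_means(model, q_tab)
    calls <- classify_latents(q_latent, trimmed$hulls,
                              ratio = config$hull_ratio,
                              special_pair = config$special_pair,
                              special_dist = config$special_dist)
    calls$complex <- cx
    vae_calls[[cx]] <- calls
    write_latent_positions(rbind(cbind(ref_latent, set = "reference"),
                                 cbind(q_latent, set = "query")),
                           file.path(config$out_dir,
                                     paste0("latent_", cx, ".tsv")))
    save_hulls(trimmed, file.path(config$out_dir, paste0("hulls_", cx)))
    terminal[calls$sample_id] <- calls$outcome
  }
  vae_calls <- if (length(vae_calls) > 0)
    do.call(rbind, c(lapply(vae_calls, function(x)
      x[, c("sample_id", "outcome", "complex")]),
      list(make.row.names = FALSE)))
  else data.frame(sample_id = character(0), outcome = character(0),
                  complex = character(0))
  utils::write.table(vae_calls, file.path(config$out_dir, "vae_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary_tab <- as.data.frame(table(outcome = terminal),
                               stringsAsFactors = FALSE)
  names(summary_tab) <- c("outcome", "n_samples")
  utils::write.table(summary_tab, file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  resolved <- config
  resolved$db_version <- db$version
  jsonlite::write_json(lapply(unclass(resolved), function(x)
    if (inherits(x, "vae_config")) unclass(x) else x),
    file.path(config$out_dir, "resolved_config.json"),
    auto_unbox = TRUE, null = "null")

  structure(list(qc = qc, partitions = partitions, nn = nn,
                 vae_calls = vae_calls, terminal = terminal,
                 summary = summary_tab, config = resolved),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline run (database ", x$config$db_version, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
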