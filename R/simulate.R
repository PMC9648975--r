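#' Specification for a simulated reference panel
#'
#' Describes a tree-structured panel emulating a multilocus amplicon assay:
#' a fixed set of targets of roughly 160 bp, species nested in complexes
#' nested in series, diploid samples with heterozygosity, per-target dropout
#' and occasional contamination (more than two alleles at a target).
#' Per-branch substitution rates are chosen so that realised pairwise 8-mer
#' sample distances fall into the calibration bands used to define
#' species-groups: within species below 0.1, within a complex between 0.1
#' and 0.3, within a series between 0.3 and 0.51, and across series above
#' 0.51.
#'
#' @param tree nested list: series -> complex -> character vector of species
#'   names. The default is five species in two complexes, one complex per
#'   series (so the coarse level is informative: a query must choose between
#'   series rather than being handed a single trivial group).
#' @param samples_per_species samples per species (default 4).
#' @param n_targets number of amplicon targets (default 62).
#' @param target_length_mean,target_length_sd target length distribution in
#'   bp (defaults 160 / 30; lengths are floored at 3k).
#' @param rate_within,rate_species,rate_complex,rate_series per-site
#'   substitution rates on the individual, species, complex and series
#'   branches. Defaults (0.003 / 0.012 / 0.018 / 0.045) put expected
#'   pairwise divergences at roughly 0.006 / 0.030 / 0.066 / 0.156, i.e.
#'   expected 8-mer distances of about 0.05 / 0.21 / 0.42 / 0.73.
#' @param indel_rate per-site indel rate on each branch (geometric lengths,
#'   mean 2 bp; default 5e-4).
#' @param heterozygosity probability a target is heterozygous (default 0.3).
#' @param dropout probability a target fails to amplify (default 0.05).
#' @param contamination probability a target gains a third allele from a
#'   random other species (default 0.01).
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(tree = list(
                              seriesA = list(
                                complex1 = c("speciesA", "speciesB", "speciesC")),
                              seriesB = list(
                                complex2 = c("speciesD", "speciesE"))),
                            samples_per_species = 4,
                            n_targets = 62,
                            target_length_mean = 160, target_length_sd = 30,
                            rate_within = 0.003, rate_species = 0.012,
                            rate_complex = 0.018, rate_series = 0.045,
                            indel_rate = 5e-4,
                            heterozygosity = 0.3, dropout = 0.05,
                            contamination = 0.01) {
  rates <- c(rate_within, rate_species, rate_complex, rate_series)
  stopifnot(all(rates >= 0 & rates <= 1), all(diff(rates) > 0),
            heterozygosity >= 0, heterozygosity <= 1,
            dropout >= 0, dropout <= 1, contamination >= 0, contamination <= 1,
            n_targets >= 1, samples_per_species >= 1)
  structure(as.list(environment())[c("tree", "samples_per_species",
    "n_targets", "target_length_mean", "target_length_sd", "rate_within",
    "rate_species", "rate_complex", "rate_series", "indel_rate",
    "heterozygosity", "dropout", "contamination")],
    class = "simulation_spec")
}

.random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                          replace = TRUE), collapse = "")

## substitutions at rate p per site plus geometric indels at indel_rate
.mutate_seq <- function(seq, p, indel_rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < p
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(bases, b), 1L), character(1))
  }
  n_indel <- stats::rbinom(1L, length(ch), indel_rate)
  for (i in seq_len(n_indel)) {
    len <- stats::rgeom(1L, 0.5) + 1L
    pos <- sample(length(ch), 1L)
    if (stats::runif(1) < 0.5) {
      ch <- append(ch, sample(c("A", "C", "G", "T"), len, replace = TRUE), pos)
    } else if (length(ch) > len + 20L) {
      ch <- ch[-(pos:min(pos + len - 1L, length(ch)))]
    }
  }
  paste(ch, collapse = "")
}

## flatten the nested tree into a species table
.species_table <- function(tree) {
  rows <- list()
  for (se in names(tree)) for (co in names(tree[[se]]))
    for (sp in tree[[se]][[co]])
      rows[[length(rows) + 1L]] <- data.frame(species = sp, complex = co,
                                              series = se,
                                              stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Simulate a reference database with calibrated divergence tiers
#'
#' Ancestral target sequences are drawn uniformly at random and mutated down
#' the series / complex / species tree with the spec's tiered substitution
#' and indel rates; individuals then receive per-haplotype mutations,
#' per-target dropout, heterozygosity and occasional contamination.
#' Calibration is empirical-first: after generation, the realised pairwise
#' 8-mer distance tiers are checked against the bands (< 0.1 within species,
#' 0.1--0.3 within complex, 0.3--0.51 within series, > 0.51 across series);
#' on violation the database is redrawn with rates nudged towards the band
#' centres, and after three failed redraws an error with diagnostics is
#' raised. Fully reproducible given `seed`.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed.
#' @param k k-mer length for calibration checks and the database (default 8).
#' @param calibrate verify (and if needed redraw) against the distance bands.
#' @return list of class `simulated_db`: `db` (a [reference_db()]), `truth`
#'   (data.frame sample / species / complex / series), `species_seqs`
#'   (internal per-species target sequences, reused by
#'   [simulate_queries()]), `D` (the realised distance matrix) and
#'   `partitions` (true-tier partitions of the samples).
#' @export
simulate_reference_db <- function(spec = simulation_spec(), seed = 1, k = 8,
                                  calibrate = TRUE) {
  with_preserved_seed(seed, {
    sp_tab <- .species_table(spec$tree)
    for (attempt in 1:4) {
      lens <- pmax(3 * k, round(stats::rnorm(spec$n_targets,
                                             spec$target_length_mean,
                                             spec$target_length_sd)))
      targets <- sprintf("t%02d", seq_len(spec$n_targets))
      root <- lapply(lens, .random_seq)
      names(root) <- targets
      series_seq <- lapply(names(spec$tree), function(se)
        lapply(root, .mutate_seq, p = spec$rate_series,
               indel_rate = spec$indel_rate))
      names(series_seq) <- names(spec$tree)
      species_seqs <- list()
      for (se in names(spec$tree)) for (co in names(spec$tree[[se]])) {
        complex_seq <- lapply(series_seq[[se]], .mutate_seq,
                              p = spec$rate_complex,
                              indel_rate = spec$indel_rate)
        for (sp in spec$tree[[se]][[co]])
          species_seqs[[sp]] <- lapply(complex_seq, .mutate_seq,
                                       p = spec$rate_species,
                                       indel_rate = spec$indel_rate)
      }
      genotypes <- list(); truth <- list()
      for (r in seq_len(nrow(sp_tab))) {
        sp <- sp_tab$species[r]
        for (i in seq_len(spec$samples_per_species)) {
          sid <- sprintf("%s_%02d", sp, i)
          gt <- .simulate_individual(sid, species_seqs[[sp]], spec,
                                     species_seqs, sp)
          genotypes[[sid]] <- gt
          truth[[length(truth) + 1L]] <-
            data.frame(sample = sid, species = sp, complex = sp_tab$complex[r],
                       series = sp_tab$series[r], stringsAsFactors = FALSE)
        }
      }
      truth <- do.call(rbind, truth)
      D <- pairwise_distance_matrix(genotypes, k = k)
      if (!calibrate || .tiers_ok(D, truth)) {
        labels <- stats::setNames(truth$species, truth$sample)
        db <- reference_db(genotypes, labels,
                           version = sprintf("synthetic-seed%d", seed), k = k)
        partitions <- .truth_partitions(truth)
        return(structure(list(db = db, truth = truth,
                              species_seqs = species_seqs, spec = spec,
                              D = D, partitions = partitions),
                         class = "simulated_db"))
      }
      ## nudge rates towards the band centres and redraw
      spec$rate_within <- spec$rate_within * 0.8
      spec$rate_series <- spec$rate_series * 1.1
    }
    stop("distance-tier calibration failed after 3 redraws; realised tiers:\n",
         paste(utils::capture.output(print(.tier_summary(D, truth))),
               collapse = "\n"))
  })
}

.tiers_ok <- function(D, truth) {
  s <- .tier_summary(D, truth)
  all(is.na(s$max_d[s$tier == "within_species"]) |
        s$max_d[s$tier == "within_species"] < 0.1) &&
    all(is.na(c(s$min_d[s$tier == "within_complex"],
                s$max_d[s$tier == "within_complex"])) |
          (s$min_d[s$tier == "within_complex"] > 0.1 &
             s$max_d[s$tier == "within_complex"] < 0.3)) &&
    all(is.na(c(s$min_d[s$tier == "within_series"],
                s$max_d[s$tier == "within_series"])) |
          (s$min_d[s$tier == "within_series"] > 0.3 &
             s$max_d[s$tier == "within_series"] < 0.51)) &&
    all(is.na(s$min_d[s$tier == "across_series"]) |
          s$min_d[s$tier == "across_series"] > 0.51)
}

.tier_summary <- function(D, truth) {
  ids <- rownames(D)
  tr <- truth[match(ids, truth$sample), ]
  iu <- which(upper.tri(D), arr.ind = TRUE)
  tier <- ifelse(tr$species[iu[, 1]] == tr$species[iu[, 2]], "within_species",
          ifelse(tr$complex[iu[, 1]] == tr$complex[iu[, 2]], "within_complex",
          ifelse(tr$series[iu[, 1]] == tr$series[iu[, 2]], "within_series",
                 "across_series")))
  d <- D[iu]
  do.call(rbind, lapply(c("within_species", "within_complex", "within_series",
                          "across_series"), function(tname) {
    sel <- tier == tname
    data.frame(tier = tname, n = sum(sel),
               min_d = if (any(sel)) min(d[sel]) else NA_real_,
               max_d = if (any(sel)) max(d[sel]) else NA_real_)
  }))
}

.truth_partitions <- function(truth) {
  mk <- function(col, lv, t) {
    memb <- stats::setNames(truth[[col]], truth$sample)
    structure(list(level_name = lv, threshold = t, membership = memb,
                   group_labels = stats::setNames(unique(memb), unique(memb))),
              class = "species_partition")
  }
  structure(list(fine = mk("species", "fine", 0.1),
                 intermediate = mk("complex", "intermediate", 0.3),
                 coarse = mk("series", "coarse", 0.51)),
            class = "species_partitions")
}

.simulate_individual <- function(sid, sp_seqs, spec, all_species_seqs,
                                 own_species) {
  targets <- list()
  for (t in names(sp_seqs)) {
    if (stats::runif(1) < spec$dropout) next
    n_hap <- if (stats::runif(1) < spec$heterozygosity) 2L else 1L
    haps <- unique(vapply(seq_len(n_hap), function(i)
      .mutate_seq(sp_seqs[[t]], spec$rate_within, spec$indel_rate),
      character(1)))
    if (stats::runif(1) < spec$contamination &&
        length(all_species_seqs) > 1L) {
      other <- sample(setdiff(names(all_species_seqs), own_species), 1L)
      haps <- unique(c(haps, .mutate_seq(all_species_seqs[[other]][[t]],
                                         spec$rate_within, spec$indel_rate)))
    }
    targets[[t]] <- haps
  }
  sample_genotypes(sid, targets)
}

#' @export
print.simulated_db <- function(x, ...) {
  cat("simulated reference panel (seed-reproducible)\n")
  print(x$db)
  print(.tier_summary(x$D, x$truth), row.names = FALSE)
  invisible(x)
}

#' Simulate query samples under a named scenario
#'
#' Scenarios mirror the situations a deployed assignment method meets:
#' `member` (new individuals of represented species), `novel_in_group` (a
#' fresh species inside a represented complex, expected to be assigned only
#' at a higher level), `diverged` (random sequences; nearest neighbours are
#' effectively random and no level should classify), `hybrid` (per target
#' one haplotype from each of two parent species of the same complex;
#' expected to split proportions and stay unassigned at the fine level) and
#' `contaminated` (members with extra alleles at many targets).
#'
#' @param sim a `simulated_db` from [simulate_reference_db()].
#' @param scenario one of "member", "novel_in_group", "diverged", "hybrid",
#'   "contaminated".
#' @param n number of query samples.
#' @param seed integer seed.
#' @return list: `queries` (list of `sample_genotypes`), `truth`
#'   (data.frame sample / scenario / expected species or parents).
#' @export
simulate_queries <- function(sim, scenario = c("member", "novel_in_group",
                                               "diverged", "hybrid",
                                               "contaminated"),
                             n = 10, seed = 1) {
  scenario <- match.arg(scenario)
  spec <- sim$spec
  with_preserved_seed(seed, {
    queries <- list(); truth <- list()
    species <- names(sim$species_seqs)
    sp_tab <- .species_table(spec$tree)
    for (i in seq_len(n)) {
      sid <- sprintf("query_%s_%02d", scenario, i)
      if (scenario == "member") {
        sp <- sample(species, 1L)
        q <- .simulate_individual(sid, sim$species_seqs[[sp]], spec,
                                  sim$species_seqs, sp)
        tru <- data.frame(sample = sid, scenario = scenario, species = sp)
      } else if (scenario == "novel_in_group") {
        co <- sample(unique(sp_tab$complex), 1L)
        base_sp <- sample(sp_tab$species[sp_tab$complex == co], 1L)
        novel <- lapply(sim$species_seqs[[base_sp]], .mutate_seq,
                        p = spec$rate_species, indel_rate = spec$indel_rate)
        q <- .simulate_individual(sid, novel, spec, sim$species_seqs, base_sp)
        tru <- data.frame(sample = sid, scenario = scenario, species = co)
      } else if (scenario == "diverged") {
        fresh <- lapply(sim$species_seqs[[1L]],
                        function(s) .random_seq(nchar(s)))
        q <- .simulate_individual(sid, fresh, spec, sim$species_seqs,
                                  species[1L])
        tru <- data.frame(sample = sid, scenario = scenario,
                          species = "unassigned")
      } else if (scenario == "hybrid") {
        co <- sample(unique(sp_tab$complex[duplicated(sp_tab$complex) |
                       duplicated(sp_tab$complex, fromLast = TRUE)]), 1L)
        parents <- sample(sp_tab$species[sp_tab$complex == co], 2L)
        targets <- list()
        for (t in names(sim$species_seqs[[parents[1]]])) {
          if (stats::runif(1) < spec$dropout) next
          h <- unique(c(.mutate_seq(sim$species_seqs[[parents[1]]][[t]],
                                    spec$rate_within, spec$indel_rate),
                        .mutate_seq(sim$species_seqs[[parents[2]]][[t]],
                                    spec$rate_within, spec$indel_rate)))
          targets[[t]] <- h
        }
        q <- sample_genotypes(sid, targets)
        tru <- data.frame(sample = sid, scenario = scenario,
                          species = paste(sort(parents), collapse = "x"))
      } else {                                 # contaminated
        sp <- sample(species, 1L)
        contaminant <- sample(setdiff(species, sp), 1L)
        spec2 <- spec; spec2$contamination <- 0.5
        q <- .simulate_individual(sid, sim$species_seqs[[sp]], spec2,
                                  sim$species_seqs[c(sp, contaminant)], sp)
        tru <- data.frame(sample = sid, scenario = scenario, species = sp)
      }
      queries[[sid]] <- q
      truth[[length(truth) + 1L]] <- tru
    }
    list(queries = queries,
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

#' Simulate clustered diploid k-mer tables for the VAE
#'
#' Exercises the VAE and hull classifier without sequence simulation:
#' each species gets a sparse Poisson mean profile over the 4^8 table
#' (a shared backbone plus species-specific k-mers controlled by
#' `effect_size`), scaled so per-sample totals are about 19,000 -- the
#' magnitude of a full 62-target diploid sample. Samples are independent
#' Poisson draws; `effect_size = 0` makes all species exchangeable.
#'
#' @param n_species number of species clusters (>= 2).
#' @param n_per_species samples per species.
#' @param effect_size fraction of each species' profile mass that is
#'   species-specific, in \[0, 1\] (default 0.5).
#' @param seed integer seed.
#' @param total target per-sample total count (default 19000).
#' @param n_active number of non-zero k-mers per profile (default 4000).
#' @return list: `tables` (matrix n x 65536), `labels` (character vector).
#' @export
simulate_vae_clusters <- function(n_species = 3, n_per_species = 50,
                                  effect_size = 0.5, seed = 1,
                                  total = 19000, n_active = 4000) {
  stopifnot(n_species >= 2, effect_size >= 0, effect_size <= 1)
  with_preserved_seed(seed, {
    D <- 4^8
    shared_idx <- sample.int(D, n_active)
    shared_mean <- stats::rgamma(n_active, shape = 2, rate = 1)
    shared_mean <- shared_mean / sum(shared_mean) * total * (1 - effect_size)
    tables <- NULL; labels <- character(0)
    for (s in seq_len(n_species)) {
      own_idx <- sample.int(D, n_active)
      own_mean <- stats::rgamma(n_active, shape = 2, rate = 1)
      own_mean <- own_mean / sum(own_mean) * total * effect_size
      lam <- numeric(D)
      lam[shared_idx] <- lam[shared_idx] + shared_mean
      lam[own_idx] <- lam[own_idx] + own_mean
      draws <- matrix(stats::rpois(n_per_species * D, rep(lam,
                        each = n_per_species)), n_per_species, D)
      tables <- rbind(tables, draws)
      labels <- c(labels, rep(sprintf("species%d", s), n_per_species))
    }
    rownames(tables) <- sprintf("%s_%02d", labels,
                                stats::ave(seq_along(labels), labels,
                                           FUN = seq_along))
    list(tables = tables, labels = labels)
  })
}
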