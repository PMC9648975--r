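#' @title Convex-hull classification in latent space
#' @description Per-species convex hulls over 3-D latent positions, overlap
#'   trimming, point-to-hull distances, and classification with fuzzy
#'   boundaries and ordered uncertain calls.
#' @name hull_classifier
NULL

## Facets of the convex hull of 3-D points, by exhaustive supporting-plane
## enumeration over point triples. Returns unit outward normals N (m x 3) and
## offsets b with the hull = {x : N x <= b}. Robust to >3 coplanar points on
## a facet (duplicate planes are merged); errors when the point set is
## degenerate (fewer than 4 points or all coplanar).
hull_facets <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3L)
  n <- nrow(pts)
  if (n < 4L)
    stop("need at least 4 points to form a 3-D convex hull (got ", n, ")")
  scale <- max(1, max(abs(pts)))
  tol <- tol * scale
  normals <- NULL; offsets <- NULL
  combs <- utils::combn(n, 3L)
  for (c_i in seq_len(ncol(combs))) {
    ijk <- combs[, c_i]
    v1 <- pts[ijk[2], ] - pts[ijk[1], ]
    v2 <- pts[ijk[3], ] - pts[ijk[1], ]
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    len <- sqrt(sum(nrm^2))
    if (len < tol) next                       # collinear triple
    nrm <- nrm / len
    s <- drop(pts %*% nrm) - sum(nrm * pts[ijk[1], ])
    if (all(s <= tol)) {
      normals <- rbind(normals, nrm)
      offsets <- c(offsets, sum(nrm * pts[ijk[1], ]))
    } else if (all(s >= -tol)) {
      normals <- rbind(normals, -nrm)
      offsets <- c(offsets, -sum(nrm * pts[ijk[1], ]))
    }
  }
  if (is.null(normals))
    stop("degenerate point set: points are coplanar, no 3-D hull exists")
  key <- paste(round(normals[, 1] / tol), round(normals[, 2] / tol),
               round(normals[, 3] / tol), round(offsets / tol))
  keep <- !duplicated(key)
  ## a full-dimensional hull has at least 4 facets
  if (sum(keep) < 4L)
    stop("degenerate point set: points are coplanar, no 3-D hull exists")
  list(N = normals[keep, , drop = FALSE], b = offsets[keep])
}

## Minimum-norm point in the convex hull of the rows of V (Wolfe's algorithm).
## Returns list(point, dist). Exact up to numerical tolerance; used for
## point-to-hull and hull-to-hull distances.
min_norm_point <- function(V, tol = 1e-12, max_iter = 1000L) {
  V <- as.matrix(V)
  n <- nrow(V)
  norms2 <- rowSums(V^2)
  j <- which.min(norms2)
  S <- j                      # corral (indices into V)
  a <- 1                      # convex coefficients over S
  x <- V[j, ]
  scale2 <- max(1, max(norms2))
  for (iter in seq_len(max_iter)) {
    ## optimality: min_i <x, v_i> >= <x, x> (up to tolerance)
    ip <- drop(V %*% x)
    jmin <- which.min(ip)
    if (ip[jmin] >= sum(x^2) - tol * scale2) break
    if (!(jmin %in% S)) { S <- c(S, jmin); a <- c(a, 0) }
    repeat {
      ## affine minimiser over the corral
      Vs <- V[S, , drop = FALSE]
      B <- 1 + Vs %*% t(Vs)
      y <- tryCatch(solve(B, rep(1, length(S))), error = function(e) NULL)
      if (is.null(y)) { y <- MASS_ginv_solve(B); }
      y <- y / sum(y)
      if (all(y > tol)) { a <- y; x <- drop(crossprod(Vs, a)); break }
      ## step towards y until a coefficient hits zero; drop those points
      neg <- which(y <= tol)
      th <- min(a[neg] / (a[neg] - y[neg]))
      a <- a + th * (y - a)
      drop_i <- which(a <= tol)
      if (length(drop_i) == length(S)) drop_i <- drop_i[-1]
      S <- S[-drop_i]; a <- a[-drop_i]
      a <- a / sum(a)
      x <- drop(crossprod(V[S, , drop = FALSE], a))
      if (length(S) == 1L) break
    }
  }
  list(point = x, dist = sqrt(max(0, sum(x^2))))
}

## pseudo-inverse fallback for a (near-)singular corral system
MASS_ginv_solve <- function(B) {
  sv <- svd(B)
  pos <- sv$d > max(sv$d) * 1e-12
  drop(sv$v[, pos, drop = FALSE] %*%
         ((t(sv$u[, pos, drop = FALSE]) %*% rep(1, nrow(B))) / sv$d[pos]))
}

#' Build per-species convex hulls from labelled latent points
#'
#' One hull per species label; labels listed together in `merge_groups` are
#' pooled into a single merged hull (for species too close in latent space to
#' separate, such as sister species with non-overlapping geographic ranges).
#' Each (merged) label needs at least 4 points not all coplanar.
#'
#' @param points numeric matrix (n x 3) of latent positions.
#' @param labels character vector of species labels, length n.
#' @param merge_groups list of character vectors of labels to pool; each
#'   merged hull is labelled by the members joined with "+".
#' @return list of `species_hull` objects: `label`, `points` (defining
#'   points), `N`/`b` (facet normals and offsets).
#' @export
build_hulls <- function(points, labels, merge_groups = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) == length(labels))
  labels <- as.character(labels)
  merged_label <- labels
  for (mg in merge_groups) {
    merged_label[labels %in% mg] <- paste(sort(mg), collapse = "+")
  }
  lapply(sort(unique(merged_label)), function(lab) {
    pts <- points[merged_label == lab, , drop = FALSE]
    f <- tryCatch(hull_facets(pts),
                  error = function(e)
                    stop("hull for '", lab, "': ", conditionMessage(e),
                         " -- add more (non-coplanar) reference points",
                         call. = FALSE))
    structure(list(label = lab, points = pts, N = f$N, b = f$b),
              class = "species_hull")
  })
}

#' @export
print.species_hull <- function(x, ...) {
  cat("convex hull '", x$label, "': ", nrow(x$points), " defining points, ",
      nrow(x$N), " facets\n", sep = "")
  invisible(x)
}

#' Euclidean distance from a point to a convex hull
#'
#' Zero if the point lies inside or on the hull (boundary membership counts
#' as inside); otherwise the distance to the nearest point of the hull
#' (attained on a face, edge or vertex), computed exactly as the minimum-norm
#' point of the translated vertex set.
#'
#' @param p length-3 numeric.
#' @param hull a `species_hull`.
#' @return non-negative number.
#' @export
distance_to_hull <- function(p, hull) {
  if (all(hull$N %*% p - hull$b <= 1e-9 * max(1, max(abs(hull$b))))) return(0)
  min_norm_point(sweep(hull$points, 2, p))$dist
}

## penetration depth of p in hull: distance from inside to the boundary,
## 0 if p is outside
penetration_depth <- function(p, hull) {
  s <- hull$b - drop(hull$N %*% p)      # slack of each facet (unit normals)
  if (any(s < 0)) return(0)
  min(s)
}

#' Do two convex hulls share an interior point?
#'
#' Touching exactly on a boundary (a shared vertex, edge or face) is not
#' overlap. Tested as zero distance between the two hulls after shrinking
#' each towards its centroid by a small relative factor, with the exact
#' hull-to-hull distance computed on the Minkowski-difference vertex set;
#' the effective tolerance is `shrink` times the hull diameter.
#'
#' @param h1,h2 `species_hull` objects.
#' @param shrink relative shrink factor (default 1e-6).
#' @return logical.
#' @export
hulls_overlap <- function(h1, h2, shrink = 1e-6) {
  sh <- function(h) {
    ctr <- colMeans(h$points)
    sweep(sweep(h$points, 2, ctr) * (1 - shrink), 2, ctr, "+")
  }
  A <- sh(h1); B <- sh(h2)
  diffs <- A[rep(seq_len(nrow(A)), each = nrow(B)), , drop = FALSE] -
    B[rep(seq_len(nrow(B)), times = nrow(A)), , drop = FALSE]
  scale <- max(1, max(abs(rbind(h1$points, h2$points))))
  min_norm_point(diffs)$dist <= 1e-9 * scale
}

#' Trim overlapping hulls by iterative point removal
#'
#' While any pair of hulls overlaps, the defining point (from either hull of
#' the pair) with the greatest penetration depth into the other hull is
#' removed and both hulls are rebuilt. Ties are broken by label and then by
#' point index, making trimming deterministic. Each iteration removes one
#' point, so the procedure terminates; removals are logged. Minimality of
#' the removal set is not guaranteed.
#'
#' @param hulls list of `species_hull`.
#' @return list with `hulls` (trimmed, pairwise non-overlapping) and
#'   `removed` (data.frame: label, point index into the original defining
#'   set, penetration depth).
#' @export
trim_overlaps <- function(hulls) {
  names(hulls) <- vapply(hulls, function(h) h$label, character(1))
  pts <- lapply(hulls, function(h) h$points)
  keep <- lapply(pts, function(p) rep(TRUE, nrow(p)))
  removed <- list()
  rebuild <- function(lab) {
    p <- pts[[lab]][keep[[lab]], , drop = FALSE]
    if (nrow(p) < 4L)
      stop("trimming reduced hull '", lab, "' below 4 usable points")
    f <- tryCatch(hull_facets(p), error = function(e)
      stop("trimming left hull '", lab, "' degenerate", call. = FALSE))
    structure(list(label = lab, points = p, N = f$N, b = f$b),
              class = "species_hull")
  }
  repeat {
    labs <- names(hulls)
    pair <- NULL
    if (length(labs) > 1L) for (i in 1:(length(labs) - 1L)) {
      for (j in (i + 1L):length(labs)) {
        if (hulls_overlap(hulls[[i]], hulls[[j]])) { pair <- c(i, j); break }
      }
      if (!is.null(pair)) break
    }
    if (is.null(pair)) break
    h1 <- hulls[[pair[1]]]; h2 <- hulls[[pair[2]]]
    cand <- rbind(
      data.frame(label = h1$label,
                 index = which(keep[[h1$label]]),
                 depth = apply(h1$points, 1, penetration_depth, hull = h2)),
      data.frame(label = h2$label,
                 index = which(keep[[h2$label]]),
                 depth = apply(h2$points, 1, penetration_depth, hull = h1)))
    cand <- cand[order(-cand$depth, cand$label, cand$index), ]
    worst <- cand[1L, ]
    keep[[worst$label]][worst$index] <- FALSE
    removed[[length(removed) + 1L]] <- worst
    hulls[[worst$label]] <- rebuild(worst$label)
  }
  removed <- if (length(removed) > 0)
    do.call(rbind, c(removed, list(make.row.names = FALSE)))
  else data.frame(label = character(0), index = integer(0), depth = numeric(0))
  list(hulls = hulls, removed = removed)
}

#' Classify a latent position against species hulls
#'
#' Assignment rules, in order: (i) if the two closest hulls are the special
#' pair (by default the gambiae/coluzzii pair, whose boundary region cannot
#' be resolved reliably) and both distances are below `special_dist`, the
#' call is `uncertain_<closer>_<farther>`; (ii) a point inside (or on) a hull
#' is called as that hull's label; (iii) a point at least `ratio` times
#' closer to one hull than to every other is called as that hull -- the
#' fuzzy boundary proportional to hull separation; (iv) otherwise the call
#' is "uncertain_" followed by all labels whose hulls lie within `ratio`
#' times the closest distance, in order of proximity. Distances to all hulls
#' are always reported. Rules (iii)/(iv) are scale-free; `special_dist` is
#' tied to the latent scale of the trained model and must be re-tuned per
#' model.
#'
#' @param p length-3 numeric latent position.
#' @param hulls list of pairwise non-overlapping `species_hull` (post-trim).
#' @param ratio fuzzy-boundary ratio (default 7).
#' @param special_pair character vector of the two labels subject to the
#'   distance rule; NULL disables it.
#' @param special_dist distance threshold of the special rule (default 14).
#' @param check_overlap verify the hulls are non-overlapping first.
#' @return object of class `hull_classification`: `outcome` (a single label
#'   or `uncertain_...`) and `distances` (named, ascending).
#' @export
classify_latent <- function(p, hulls, ratio = 7,
                            special_pair = c("gambiae", "coluzzii"),
                            special_dist = 14, check_overlap = FALSE) {
  labs <- vapply(hulls, function(h) h$label, character(1))
  if (check_overlap && length(hulls) > 1L) {
    for (i in 1:(length(hulls) - 1L)) for (j in (i + 1L):length(hulls))
      if (hulls_overlap(hulls[[i]], hulls[[j]]))
        stop("hulls '", labs[i], "' and '", labs[j],
             "' overlap; trim before classification")
  }
  d <- vapply(hulls, distance_to_hull, numeric(1), p = p)
  names(d) <- labs
  d <- d[order(d, names(d))]
  outcome <- NULL
  if (!is.null(special_pair) && length(d) >= 2L &&
      setequal(names(d)[1:2], special_pair) &&
      all(d[1:2] < special_dist)) {
    outcome <- paste(c("uncertain", names(d)[1:2]), collapse = "_")
  } else if (d[1L] == 0) {
    outcome <- names(d)[1L]
  } else if (length(d) == 1L || all(d[-1L] >= ratio * d[1L])) {
    outcome <- names(d)[1L]
  } else {
    close <- names(d)[d < ratio * d[1L]]
    outcome <- paste(c("uncertain", close), collapse = "_")
  }
  structure(list(outcome = outcome, distances = d),
            class = "hull_classification")
}

#' @export
print.hull_classification <- function(x, ...) {
  cat("hull classification: ", x$outcome, "\n  distances: ",
      paste(sprintf("%s=%.3g", names(x$distances), x$distances),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify many latent positions
#'
#' @inheritParams classify_latent
#' @param latent data.frame from [encode_means()] (or a matrix of
#'   positions with sample ids as rownames).
#' @return data.frame: sample_id, outcome, and one distance column per hull.
#' @export
classify_latents <- function(latent, hulls, ratio = 7,
                             special_pair = c("gambiae", "coluzzii"),
                             special_dist = 14) {
  if (is.data.frame(latent)) {
    ids <- latent$sample_id
    P <- as.matrix(latent[, grep("^mu", names(latent))])
  } else {
    P <- as.matrix(latent)
    ids <- rownames(P) %||% as.character(seq_len(nrow(P)))
  }
  labs <- vapply(hulls, function(h) h$label, character(1))
  rows <- lapply(seq_len(nrow(P)), function(i) {
    cl <- classify_latent(P[i, ], hulls, ratio, special_pair, special_dist)
    out <- data.frame(sample_id = ids[i], outcome = cl$outcome,
                      stringsAsFactors = FALSE)
    for (l in labs) out[[paste0("dist_", l)]] <- unname(cl$distances[l])
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Save / load species hulls as a text bundle
#'
#' A directory with one `<label>.tsv` vertex file per hull, a removal log
#' and a JSON manifest.
#'
#' @param trimmed value of [trim_overlaps()] (or a bare list of hulls).
#' @param dir bundle directory.
#' @export
save_hulls <- function(trimmed, dir) {
  hulls <- if (!is.null(trimmed$hulls)) trimmed$hulls else trimmed
  removed <- trimmed$removed %||%
    data.frame(label = character(0), index = integer(0), depth = numeric(0))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- vapply(hulls, function(h) h$label, character(1))
  for (h in hulls) {
    fn <- file.path(dir, paste0(gsub("[^A-Za-z0-9_+.-]", "_", h$label), ".tsv"))
    utils::write.table(as.data.frame(h$points), fn, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(removed, file.path(dir, "removed_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(labels = labs,
         files = paste0(gsub("[^A-Za-z0-9_+.-]", "_", labs), ".tsv")),
    file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname save_hulls
#' @export
load_hulls <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  hulls <- mapply(function(lab, fn) {
    pts <- as.matrix(utils::read.delim(file.path(dir, fn)))
    f <- hull_facets(pts)
    structure(list(label = lab, points = pts, N = f$N, b = f$b),
              class = "species_hull")
  }, manifest$labels, manifest$files, SIMPLIFY = FALSE)
  names(hulls) <- manifest$labels
  hulls
}
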