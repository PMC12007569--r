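# Ensemble landscape analysis: quality filtering, k-medoids clustering in
# gating-coordinate space, representative selection and state labels.

#' Filter a gating landscape by model quality score
#'
#' Retains rows whose score is strictly greater than the threshold (0.4 by
#' default, the retention rule for medium-quality interface models), in
#' input order. Every model must have a score unless `drop_missing = TRUE`,
#' in which case unscored models are dropped with a message.
#'
#' @param landscape `data.frame` from [compute_landscape()] (needs
#'   `model_id`).
#' @param scores Named numeric vector (names = model ids) or `data.frame`
#'   with columns `model_id` and `score`.
#' @param threshold Retention threshold; strictly-greater comparison.
#' @param drop_missing Drop models without a score instead of erroring.
#' @return The retained landscape rows, with a `score` column appended and
#'   attribute `n_input` recording the pre-filter count.
#' @export
filter_by_quality <- function(landscape, scores, threshold = 0.4,
                              drop_missing = FALSE) {
  check_that(is_scalar_number(threshold), "threshold must be a finite number")
  if (is.data.frame(scores)) {
    check_that(all(c("model_id", "score") %in% names(scores)),
               "scores data.frame needs columns model_id and score")
    sc <- stats::setNames(scores$score, scores$model_id)
  } else {
    sc <- scores
  }
  s <- sc[landscape$model_id]
  missing <- landscape$model_id[is.na(s)]
  if (length(missing) && !drop_missing) {
    stop(sprintf("no quality score for model(s): %s%s",
                 paste(utils::head(missing, 5L), collapse = ", "),
                 if (length(missing) > 5L) ", ..." else ""), call. = FALSE)
  }
  if (length(missing)) {
    message(sprintf("dropping %d model(s) without a score", length(missing)))
  }
  keep <- !is.na(s) & s > threshold
  out <- landscape[keep, , drop = FALSE]
  out$score <- unname(s[keep])
  rownames(out) <- NULL
  message(sprintf("quality filter (> %g): retained %d of %d models",
                  threshold, nrow(out), nrow(landscape)))
  attr(out, "n_input") <- nrow(landscape)
  out
}

# points: numeric matrix n x d with rownames = model ids (made unique
# upstream); returns scaled copy
scale_points <- function(points, scaling) {
  if (scaling == "zscore") {
    mu <- colMeans(points)
    sd <- apply(points, 2L, stats::sd)
    sd[sd == 0] <- 1
    points <- sweep(sweep(points, 2L, mu), 2L, sd, `/`)
  }
  points
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    ids <- if ("model_id" %in% names(points)) points$model_id else
      rownames(points)
    num <- points[, setdiff(names(points), c("model_id", "score")),
                  drop = FALSE]
    points <- as.matrix(num)
    rownames(points) <- ids
  } else {
    points <- as.matrix(points)
    if (is.null(rownames(points))) {
      rownames(points) <- sprintf("p%05d", seq_len(nrow(points)))
    }
  }
  storage.mode(points) <- "double"
  check_that(all(is.finite(points)), "points must be finite")
  points
}

# classic PAM BUILD initialization: first medoid minimizes total distance,
# each next medoid maximizes the cost reduction. Deterministic.
pam_build <- function(dmat, k) {
  n <- nrow(dmat)
  med <- integer(k)
  med[1L] <- which.min(colSums(dmat))
  if (k > 1L) {
    dmin <- dmat[med[1L], ]
    for (j in 2:k) {
      gain <- colSums(pmax(dmin - dmat, 0))
      gain[med[seq_len(j - 1L)]] <- -Inf
      med[j] <- which.max(gain)
      dmin <- pmin(dmin, dmat[med[j], ])
    }
  }
  med
}

#' Seeded PAM-style k-medoids in gating-coordinate space
#'
#' Partitions models around medoids with Euclidean distance on the (raw or
#' z-scored) metric columns: deterministic PAM BUILD initialization, then
#' alternation of nearest-medoid assignment and per-cluster medoid update
#' until the total cost is stationary. When `n > max_matrix`, medoids are found on a seeded
#' uniform random subsample of `max_matrix` points and all points are then
#' assigned to the nearest medoid, mirroring the capped-distance-matrix
#' strategy of the ensemble study (k = 9, cap 5000). Deterministic given
#' the seed; all ties break lexicographically on model id.
#'
#' @param points Numeric matrix (rows = models) or a landscape `data.frame`
#'   with `model_id` plus metric columns.
#' @param k Number of clusters (default 9).
#' @param max_matrix Largest number of points the medoid search may hold
#'   (default 5000).
#' @param seed Integer seed for seeding/subsampling.
#' @param max_iter Iteration cap for the alternation.
#' @param scaling `"none"` (default: raw coordination numbers) or
#'   `"zscore"`.
#' @return A `clustering_result`: `medoid_ids`, `assignment` (named integer
#'   vector), `representative_ids`, `cost`, `subsample_ids`, `iterations`,
#'   plus the scaled `points` used.
#' @export
kmedoids <- function(points, k = 9, max_matrix = 5000, seed = 1,
                     max_iter = 100, scaling = c("none", "zscore")) {
  scaling <- match.arg(scaling)
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  check_that(k >= 1 && k <= n, "need 1 <= k <= n (k=%d, n=%d)", k, n)
  check_that(max_matrix >= k, "max_matrix must be >= k")
  check_that(nrow(unique(pts)) >= k,
             "need at least k distinct points")
  pts_s <- scale_points(pts, scaling)
  ids <- rownames(pts_s)
  ord <- lex_order(ids)  # lexicographic rank for deterministic tie-breaks

  sub_idx <- seq_len(n)
  if (n > max_matrix) {
    sub_idx <- with_seed(seed, sort(sample.int(n, max_matrix)))
  }
  sub <- pts_s[sub_idx, , drop = FALSE]
  dmat <- as.matrix(stats::dist(sub))

  med <- pam_build(dmat, k)
  cost <- Inf
  cost_trace <- numeric()
  iter <- 0L
  assign_sub <- integer(nrow(sub))
  repeat {
    iter <- iter + 1L
    # nearest-medoid assignment; tie -> lower medoid index (stable since
    # medoids are kept sorted by lexicographic id below)
    dm <- dmat[, med, drop = FALSE]
    assign_sub <- max.col(-dm, ties.method = "first")
    new_cost <- sum(dm[cbind(seq_len(nrow(sub)), assign_sub)])
    cost_trace <- c(cost_trace, new_cost)
    # medoid update: member minimizing total within-cluster distance
    new_med <- med
    for (c_i in seq_len(k)) {
      members <- which(assign_sub == c_i)
      if (!length(members)) next
      within <- colSums(dmat[members, members, drop = FALSE])
      best <- min(within)
      cand <- members[within <= best + 1e-12]
      # ties: lexicographically smallest model id
      new_med[c_i] <- cand[which.min(match(sub_idx[cand], ord))]
    }
    if (new_cost >= cost - 1e-12 && identical(new_med, med)) break
    med <- new_med
    cost <- new_cost
    if (iter >= max_iter) break
  }
  # order clusters by lexicographic medoid id for a stable labelling
  med_ids <- ids[sub_idx[med]]
  reorder <- lex_order(med_ids)
  med <- med[reorder]
  med_ids <- med_ids[reorder]

  # final assignment of every point to its nearest medoid
  med_pts <- sub[med, , drop = FALSE]
  d_all <- outer(rowSums(pts_s^2), rowSums(med_pts^2), `+`) -
    2 * tcrossprod(pts_s, med_pts)
  d_all[d_all < 0] <- 0
  d_all <- sqrt(d_all)
  assignment <- max.col(-d_all, ties.method = "first")
  names(assignment) <- ids
  total_cost <- sum(d_all[cbind(seq_len(n), assignment)])

  res <- structure(list(
    medoid_ids = med_ids,
    assignment = assignment,
    representative_ids = NULL,
    cost = total_cost,
    cost_trace = cost_trace,
    subsample_ids = ids[sub_idx],
    iterations = iter,
    k = k,
    scaling = scaling,
    seed = seed,
    points = pts_s
  ), class = "clustering_result")
  res$representative_ids <- select_representatives(res, pts_s)
  message(sprintf(
    "k-medoids: %d models -> %d clusters (medoid search on %d, %d iteration(s), cost %.4g)",
    n, k, length(sub_idx), iter, total_cost))
  res
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: k = %d, n = %d, cost = %.4g (%s scaling)\n",
              x$k, length(x$assignment), x$cost, x$scaling))
  sizes <- table(x$assignment)
  cat("cluster sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  cat("representatives:", paste(x$representative_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Most centrally located member of each cluster
#'
#' Per cluster, the member minimizing the mean distance to all members of
#' that cluster in metric space (ties: lexicographically smallest model id).
#' Coincides with the medoid when the cluster was fully enumerated during
#' the medoid search.
#'
#' @param result A `clustering_result`.
#' @param points Metric matrix/landscape the clustering was run on (defaults
#'   to the points stored in `result`, already scaled).
#' @return Character vector of k representative ids.
#' @export
select_representatives <- function(result, points = NULL) {
  pts <- if (is.null(points)) result$points else as_point_matrix(points)
  if (!is.null(points) && result$scaling != "none") {
    pts <- scale_points(pts, result$scaling)
  }
  ids <- rownames(pts)
  reps <- character(result$k)
  for (c_i in seq_len(result$k)) {
    members <- which(result$assignment == c_i)
    check_that(length(members) > 0L, "cluster %d is empty", c_i)
    sub <- pts[members, , drop = FALSE]
    dm <- as.matrix(stats::dist(sub))
    mean_d <- rowSums(dm) / length(members)
    best <- min(mean_d)
    cand <- ids[members[mean_d <= best + 1e-12]]
    reps[c_i] <- lex_min(cand)
  }
  reps
}

#' Structural tightness of cluster representatives
#'
#' Mean superposed RMSD (on a residue selection) between each cluster's
#' representative and every other member, the quantity behind "cluster
#' members are within ~1 A of their representative".
#'
#' @param result A `clustering_result` with representatives.
#' @param models List of `StructureModel`s covering all clustered ids.
#' @param selection [group_spec()] (or list of them) giving the atoms to
#'   superpose on; defaults to all atoms.
#' @return `data.frame`: cluster, representative_id, n_members, mean_rmsd.
#' @export
representative_tightness <- function(result, models, selection = NULL) {
  ids <- vapply(models, function(m) m$model_id, character(1L))
  names(models) <- ids
  get_xyz <- function(id) {
    m <- models[[id]]
    check_that(!is.null(m), "model '%s' not supplied", id)
    if (is.null(selection)) coords(m) else coords(select_atoms(m, selection))
  }
  out <- data.frame(cluster = seq_len(result$k),
                    representative_id = result$representative_ids,
                    n_members = NA_integer_, mean_rmsd = NA_real_)
  for (c_i in seq_len(result$k)) {
    rep_id <- result$representative_ids[c_i]
    members <- setdiff(names(result$assignment)[result$assignment == c_i],
                       rep_id)
    out$n_members[c_i] <- length(members) + 1L
    if (!length(members)) {
      out$mean_rmsd[c_i] <- 0
      next
    }
    ref <- get_xyz(rep_id)
    out$mean_rmsd[c_i] <- mean(vapply(members, function(id) {
      superpose(get_xyz(id), ref)$rmsd
    }, numeric(1L)))
  }
  out
}

#' Reference values for state classification
#'
#' Packages the gate coordination numbers of the outward-open and
#' inward-open endpoint models into the reference record used by
#' [classify_state()], together with per-gate margins expressed as a
#' fraction of each gate's reference span.
#'
#' @param outward,inward Named numeric vectors of gate values at the two
#'   endpoints (e.g. `c(C_N = ..., C_C = ...)`).
#' @param n_gate,c_gate Names of the two gate metrics.
#' @param margin_fraction Margin as a fraction of `|closed - open|` per gate
#'   (default 0.1).
#' @return A `state_references` list with `open`, `closed` and `margin` per
#'   gate.
#' @export
state_references <- function(outward, inward, n_gate = "C_N", c_gate = "C_C",
                             margin_fraction = 0.1) {
  check_that(margin_fraction >= 0, "margin_fraction must be >= 0")
  for (g in c(n_gate, c_gate)) {
    check_that(g %in% names(outward) && g %in% names(inward),
               "gate '%s' missing from endpoint values", g)
  }
  # outward endpoint: N-gate open, C-gate closed; inward endpoint: reversed
  refs <- list(
    n_gate = n_gate, c_gate = c_gate,
    open = c(stats::setNames(outward[[n_gate]], n_gate),
             stats::setNames(inward[[c_gate]], c_gate)),
    closed = c(stats::setNames(inward[[n_gate]], n_gate),
               stats::setNames(outward[[c_gate]], c_gate))
  )
  refs$margin <- abs(refs$closed - refs$open) * margin_fraction
  structure(refs, class = "state_references")
}

#' Classify a model's conformational state from its gate values
#'
#' Reference-anchored rule: a gate is "closed" when its coordination number
#' is within the margin of (or beyond) the closed reference, "open" when
#' within the margin of the open reference. N open + C closed is
#' outward-open, N closed + C open is inward-open, both closed is occluded,
#' anything else intermediate. Deterministic and idempotent: the label
#' depends only on the coordinates, references and margins.
#'
#' @param coords Named numeric vector with the two gate values, or a
#'   landscape `data.frame` (then a vector of labels is returned).
#' @param references A [state_references()] object.
#' @param margins Optional named numeric vector overriding the per-gate
#'   margins (absolute units).
#' @return Character label(s):
#'   `outward_open` / `occluded` / `inward_open` / `intermediate`.
#' @export
classify_state <- function(coords, references, margins = NULL) {
  check_that(inherits(references, "state_references"),
             "references must come from state_references()")
  mar <- references$margin
  if (!is.null(margins)) {
    check_that(all(margins >= 0), "margins must be non-negative")
    mar[names(margins)] <- margins
  }
  gates <- c(references$n_gate, references$c_gate)
  classify_one <- function(v) {
    status <- vapply(gates, function(g) {
      x <- v[[g]]
      cl <- references$closed[[g]]
      op <- references$open[[g]]
      hi <- cl >= op  # closed side is the high side for a coordination number
      closed <- if (hi) x >= cl - mar[[g]] else x <= cl + mar[[g]]
      open <- if (hi) x <= op + mar[[g]] else x >= op - mar[[g]]
      if (closed) "closed" else if (open) "open" else "between"
    }, character(1L))
    n_s <- status[[1L]]
    c_s <- status[[2L]]
    if (n_s == "open" && c_s == "closed") "outward_open"
    else if (n_s == "closed" && c_s == "open") "inward_open"
    else if (n_s == "closed" && c_s == "closed") "occluded"
    else "intermediate"
  }
  if (is.data.frame(coords)) {
    vapply(seq_len(nrow(coords)), function(i) {
      classify_one(as.list(coords[i, gates, drop = FALSE]))
    }, character(1L))
  } else {
    classify_one(as.list(coords))
  }
}
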