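# Docking-pose clustering: average-linkage agglomeration on the unfitted
# RMSD over ligand + binding-site heavy atoms, with the cluster number
# chosen at the minimum of the Kelley penalty.

#' Kelley penalty across hierarchical clustering levels
#'
#' For each level k in `2..(n-1)`, the average spread (mean pairwise
#' distance) of the clusters with more than one member is computed, the
#' averages are normalized across levels to the range `[1, n-1]`, and k is
#' added (Kelley, Gardner and Sutcliffe's criterion). The level minimizing
#' the penalty balances tight clusters against their number; ties take the
#' smallest k. If every level has zero spread (all poses identical) the
#' penalty is flat and the choice degenerates to k = 2, flagged in the
#' result.
#'
#' @param hc An [stats::hclust] tree.
#' @param dmat Distance matrix (`matrix` or `dist`) the tree was built on.
#' @return List: `penalty` (named vector over k), `chosen_k`, `degenerate`.
#' @export
kelley_penalty <- function(hc, dmat) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  check_that(n >= 3L, "need at least 3 items for the Kelley criterion")
  ks <- 2:(n - 1L)
  av <- vapply(ks, function(k) {
    cl <- stats::cutree(hc, k = k)
    spreads <- vapply(unique(cl), function(ci) {
      members <- which(cl == ci)
      if (length(members) < 2L) return(NA_real_)
      sub <- dmat[members, members]
      mean(sub[upper.tri(sub)])
    }, numeric(1L))
    spreads <- spreads[!is.na(spreads)]
    if (!length(spreads)) 0 else mean(spreads)
  }, numeric(1L))
  rng <- range(av)
  degenerate <- rng[2L] - rng[1L] <= .Machine$double.eps^0.5
  norm <- if (degenerate) rep(1, length(av)) else
    (n - 2L) * (av - rng[1L]) / (rng[2L] - rng[1L]) + 1
  penalty <- stats::setNames(norm + ks, ks)
  chosen <- ks[which.min(penalty)]  # which.min takes the first = smallest k
  list(penalty = penalty, chosen_k = chosen, degenerate = degenerate)
}

# unfitted-RMSD distance matrix over the selected atoms of each pose
pose_distance_matrix <- function(poses, site = NULL, ligand = NULL) {
  sel_coords <- lapply(poses, function(p) {
    at <- p$atoms
    keep <- rep(FALSE, nrow(at))
    if (!is.null(ligand)) {
      keep <- keep | (at$het & at$res_name == ligand$res_name)
    }
    if (!is.null(site)) {
      site_at <- select_atoms(p, site)
      key <- paste(at$chain_id, at$res_seq, at$atom_name)
      keep <- keep | key %in% paste(site_at$chain_id, site_at$res_seq,
                                    site_at$atom_name)
    }
    if (is.null(ligand) && is.null(site)) keep <- rep(TRUE, nrow(at))
    sub <- at[keep & !at$is_hydrogen, , drop = FALSE]
    sub <- sub[order(sub$chain_id, sub$res_seq, sub$atom_name), , drop = FALSE]
    list(key = paste(sub$chain_id, sub$res_seq, sub$atom_name),
         xyz = coords(sub))
  })
  ref_key <- sel_coords[[1L]]$key
  for (i in seq_along(sel_coords)) {
    check_that(identical(sel_coords[[i]]$key, ref_key),
               "pose %d has a different atom composition", i)
  }
  n <- length(poses)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dmat[i, j] <- dmat[j, i] <-
        rmsd_unaligned(sel_coords[[i]]$xyz, sel_coords[[j]]$xyz)
    }
  }
  dimnames(dmat) <- list(vapply(poses, function(p) p$model_id, character(1L)),
                         vapply(poses, function(p) p$model_id, character(1L)))
  dmat
}

#' Cluster docking poses by average linkage with the Kelley criterion
#'
#' Pairwise distance is the unfitted RMSD ([rmsd_unaligned()]) over the
#' non-hydrogen atoms of the ligand and the binding-site residues;
#' agglomeration is average linkage; the number of clusters is taken at the
#' minimum of the Kelley penalty.
#'
#' @param poses List of `StructureModel` poses with identical atom
#'   composition.
#' @param site Binding-site [group_spec()] (or list), or `NULL` for
#'   ligand-only distances.
#' @param ligand [ligand_spec()] naming the ligand residue, or `NULL` for
#'   site-only distances.
#' @return A `pose_cluster_result`: `linkage` (hclust), `kelley_penalty`,
#'   `chosen_k`, `assignment` (named), `cluster_sizes`, `degenerate`,
#'   `distance_matrix`.
#' @export
cluster_poses <- function(poses, site = NULL, ligand = NULL) {
  check_that(length(poses) >= 3L, "need at least 3 poses")
  dmat <- pose_distance_matrix(poses, site = site, ligand = ligand)
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  kp <- kelley_penalty(hc, dmat)
  assignment <- stats::cutree(hc, k = kp$chosen_k)
  structure(list(
    linkage = hc,
    kelley_penalty = kp$penalty,
    chosen_k = kp$chosen_k,
    assignment = assignment,
    cluster_sizes = as.integer(table(assignment)),
    degenerate = kp$degenerate,
    distance_matrix = dmat
  ), class = "pose_cluster_result")
}

#' @export
print.pose_cluster_result <- function(x, ...) {
  cat(sprintf("pose_cluster_result: %d poses, chosen_k = %d%s\n",
              length(x$assignment), x$chosen_k,
              if (x$degenerate) " (degenerate: flat Kelley penalty)" else ""))
  cat("cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Full docking-pose analysis
#'
#' Convenience wrapper: interaction convergence ([pose_convergence()]) plus
#' geometric clustering ([cluster_poses()]) in one report.
#'
#' @inheritParams pose_convergence
#' @return List combining both results.
#' @export
analyze_poses <- function(poses, ligand, site,
                          criteria = interaction_criteria(),
                          his_protonated = FALSE) {
  conv <- pose_convergence(poses, ligand, site, criteria, his_protonated)
  clust <- cluster_poses(poses, site = site, ligand = ligand)
  list(convergence = conv, clustering = clust)
}
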