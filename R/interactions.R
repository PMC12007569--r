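# Geometric protein-ligand interaction typing and fingerprints.
#
# The typing criteria follow the published conventions of the standard
# interaction profilers (distance/angle cutoffs below, all overridable):
# the structures this package targets carry no hydrogens, so hydrogen bonds
# use the heavy donor-acceptor distance criterion.

#' Geometric criteria for interaction typing
#'
#' @param hbond_dist Max heavy donor-acceptor distance, Angstrom (3.5
#'   without explicit hydrogens; 3.6 plus a >= 100 degree D-H...A angle
#'   when hydrogens are present).
#' @param hbond_angle_min Min D-H...A angle, degrees (used only with
#'   hydrogens).
#' @param ionic_dist Max charged-group centroid distance.
#' @param pi_parallel_dist,pi_parallel_angle_max,pi_parallel_offset_max
#'   Parallel stacking: centroid distance, interplanar angle, lateral
#'   offset.
#' @param pi_perp_dist,pi_perp_angle_range Perpendicular (T-shaped)
#'   stacking: centroid distance and interplanar angle window.
#' @param hydrophobic_dist Max apolar carbon-carbon distance.
#' @return Named list of criteria.
#' @export
interaction_criteria <- function(hbond_dist = 3.5, hbond_angle_min = 100,
                                 ionic_dist = 5.5,
                                 pi_parallel_dist = 5.5,
                                 pi_parallel_angle_max = 30,
                                 pi_parallel_offset_max = 2.0,
                                 pi_perp_dist = 6.0,
                                 pi_perp_angle_range = c(60, 90),
                                 hydrophobic_dist = 4.0) {
  as.list(environment())
}

ring_geometry <- function(xyz) {
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2L, centroid)
  normal <- svd(centered, nu = 0, nv = 3)$v[, 3L]
  list(centroid = centroid, normal = normal / sqrt(sum(normal^2)))
}

vec_angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, max(-1, ca))) * 180 / pi
}

atoms_of <- function(atoms, names_wanted) {
  atoms[atoms$atom_name %in% names_wanted, , drop = FALSE]
}

#' Detect protein-ligand interactions in one complex
#'
#' Types hydrogen bonds, ionic contacts, parallel and perpendicular
#' pi-stacking and hydrophobic contacts between one HETATM ligand and the
#' binding-site residues, from geometry alone. Protein-side chemistry comes
#' from a built-in standard-residue dictionary; ligand chemistry from the
#' [ligand_spec()]. Hydrophobic contacts are collapsed to one record per
#' protein residue (minimum distance). Records are sorted by
#' (kind, chain, residue) and each record carries the measured geometry.
#'
#' @param model `StructureModel` holding protein and ligand.
#' @param ligand [ligand_spec()] naming the HETATM residue.
#' @param site [group_spec()] or list: binding-site residues to scan.
#' @param criteria [interaction_criteria()].
#' @param his_protonated Treat histidine as positively charged (doubly
#'   protonated imidazolium).
#' @return `data.frame` with columns `kind`, `chain_id`, `res_seq`,
#'   `res_name`, `protein_atom`, `ligand_atom`, `distance`, `angle`.
#' @export
detect_interactions <- function(model, ligand, site,
                                criteria = interaction_criteria(),
                                his_protonated = FALSE) {
  check_that(inherits(ligand, "ligand_spec"), "ligand must be a ligand_spec")
  lig <- model$atoms[model$atoms$het & model$atoms$res_name == ligand$res_name,
                     , drop = FALSE]
  check_that(nrow(lig) > 0L, "ligand residue '%s' not present in model '%s'",
             ligand$res_name, model$model_id)
  lig <- lig[!lig$is_hydrogen, , drop = FALSE]
  site_atoms <- select_atoms(model, site)
  site_atoms <- site_atoms[!site_atoms$het, , drop = FALSE]
  recs <- list()
  add <- function(kind, pa, la, dist, angle = NA_real_, res_row) {
    recs[[length(recs) + 1L]] <<- data.frame(
      kind = kind, chain_id = res_row$chain_id, res_seq = res_row$res_seq,
      res_name = res_row$res_name, protein_atom = pa, ligand_atom = la,
      distance = dist, angle = angle, stringsAsFactors = FALSE
    )
  }
  lig_ring_geoms <- lapply(ligand$rings, function(ring) {
    sel <- atoms_of(lig, ring)
    check_that(nrow(sel) == length(ring),
               "ligand ring atoms missing from pose")
    ring_geometry(coords(sel))
  })
  lig_charges <- lapply(ligand$charged_groups, function(g) {
    sel <- atoms_of(lig, g$atoms)
    check_that(nrow(sel) == length(g$atoms),
               "ligand charged-group atoms missing from pose")
    list(centroid = colMeans(coords(sel)), sign = g$sign,
         label = paste(g$atoms, collapse = "+"))
  })

  res_key <- paste(site_atoms$chain_id, site_atoms$res_seq)
  for (key in unique(res_key)) {
    res_atoms <- site_atoms[res_key == key, , drop = FALSE]
    res_row <- res_atoms[1L, ]
    chem <- protein_chem(res_row$res_name, his_protonated)
    # backbone polarity applies to every residue type
    donors <- c(if (res_row$res_name != "PRO") "N", chem$donors)
    acceptors <- c("O", chem$acceptors)

    # hydrogen bonds: protein donor -> ligand acceptor and vice versa,
    # heavy-atom distance criterion (no hydrogens in these models)
    d_at <- atoms_of(res_atoms, donors)
    a_lig <- atoms_of(lig, ligand$acceptors)
    if (nrow(d_at) && nrow(a_lig)) {
      dm <- pair_dists(coords(d_at), coords(a_lig))
      hits <- which(dm <= criteria$hbond_dist, arr.ind = TRUE)
      for (h in seq_len(nrow(hits))) {
        add("hbond", d_at$atom_name[hits[h, 1L]],
            a_lig$atom_name[hits[h, 2L]], dm[hits[h, , drop = FALSE]],
            res_row = res_row)
      }
    }
    a_at <- atoms_of(res_atoms, acceptors)
    d_lig <- atoms_of(lig, ligand$donors)
    if (nrow(a_at) && nrow(d_lig)) {
      dm <- pair_dists(coords(a_at), coords(d_lig))
      hits <- which(dm <= criteria$hbond_dist, arr.ind = TRUE)
      for (h in seq_len(nrow(hits))) {
        add("hbond", a_at$atom_name[hits[h, 1L]],
            d_lig$atom_name[hits[h, 2L]], dm[hits[h, , drop = FALSE]],
            res_row = res_row)
      }
    }

    # ionic: opposite-sign charged-group centroids
    for (pg in chem$charged %||% list()) {
      sel <- atoms_of(res_atoms, pg$atoms)
      if (nrow(sel) != length(pg$atoms)) next  # side chain not resolved
      pc <- colMeans(coords(sel))
      for (lg in lig_charges) {
        if (pg$sign * lg$sign >= 0) next
        d <- sqrt(sum((pc - lg$centroid)^2))
        if (d <= criteria$ionic_dist) {
          add("ionic", paste(pg$atoms, collapse = "+"), lg$label, d,
              res_row = res_row)
        }
      }
    }

    # pi stacking: ring-ring geometry
    for (pr in chem$rings %||% list()) {
      sel <- atoms_of(res_atoms, pr)
      if (nrow(sel) != length(pr)) next
      pg <- ring_geometry(coords(sel))
      for (li in seq_along(lig_ring_geoms)) {
        lg <- lig_ring_geoms[[li]]
        d <- sqrt(sum((pg$centroid - lg$centroid)^2))
        ang <- vec_angle_deg(pg$normal, lg$normal)
        sep <- lg$centroid - pg$centroid
        offset <- sqrt(max(0, sum(sep^2) - sum(sep * pg$normal)^2))
        lab <- paste0("ring", li)
        if (d <= criteria$pi_parallel_dist &&
            ang <= criteria$pi_parallel_angle_max &&
            offset <= criteria$pi_parallel_offset_max) {
          add("pi_parallel", paste(pr, collapse = "+"), lab, d, ang, res_row)
        } else if (d <= criteria$pi_perp_dist &&
                   ang >= criteria$pi_perp_angle_range[1L] &&
                   ang <= criteria$pi_perp_angle_range[2L]) {
          add("pi_perpendicular", paste(pr, collapse = "+"), lab, d, ang,
              res_row)
        }
      }
    }

    # hydrophobic: apolar carbon pairs, one record per residue
    h_at <- atoms_of(res_atoms, chem$apolar %||% character())
    h_lig <- atoms_of(lig, ligand$apolar)
    if (nrow(h_at) && nrow(h_lig)) {
      dm <- pair_dists(coords(h_at), coords(h_lig))
      if (min(dm) <= criteria$hydrophobic_dist) {
        best <- which(dm == min(dm), arr.ind = TRUE)[1L, ]
        add("hydrophobic", h_at$atom_name[best[1L]],
            h_lig$atom_name[best[2L]], min(dm), res_row = res_row)
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(kind = character(), chain_id = character(),
               res_seq = integer(), res_name = character(),
               protein_atom = character(), ligand_atom = character(),
               distance = numeric(), angle = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$kind, out$chain_id, out$res_seq, out$protein_atom,
                   out$ligand_atom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

pair_dists <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Canonical interaction fingerprint
#'
#' Order-independent set of `kind:chain:residue` tokens: two poses with the
#' same typed residue contacts get identical fingerprints regardless of
#' record order, distances within cutoffs, or atom-level detail.
#'
#' @param records `data.frame` from [detect_interactions()].
#' @return Sorted character vector of unique tokens.
#' @export
fingerprint <- function(records) {
  if (!nrow(records)) return(character())
  tok <- unique(paste(records$kind, records$chain_id, records$res_seq,
                      sep = ":"))
  tok[lex_order(tok)]
}

#' Modal fingerprint and convergence of a docking pose set
#'
#' Computes each pose's fingerprint, takes the most frequent one as the
#' modal (converged) interaction set - ties broken towards the fingerprint
#' with more contacts, then lexicographically - and reports the fraction of
#' poses whose fingerprint contains the modal set.
#'
#' @param poses List of `StructureModel` poses.
#' @param ligand [ligand_spec()].
#' @param site Binding-site [group_spec()] (or list).
#' @param criteria [interaction_criteria()].
#' @param his_protonated Passed through to [detect_interactions()].
#' @return List: `modal_fingerprint`, `convergence_fraction`,
#'   `fingerprints` (per pose), `n`.
#' @export
pose_convergence <- function(poses, ligand, site,
                             criteria = interaction_criteria(),
                             his_protonated = FALSE) {
  check_that(length(poses) >= 1L, "need at least one pose")
  fps <- lapply(poses, function(p) {
    fingerprint(detect_interactions(p, ligand, site, criteria,
                                    his_protonated))
  })
  keys <- vapply(fps, function(f) paste(f, collapse = "|"), character(1L))
  tab <- table(keys)
  top <- max(tab)
  cand <- names(tab)[tab == top]
  if (length(cand) > 1L) {
    sizes <- vapply(cand, function(k) {
      if (!nzchar(k)) 0L else length(strsplit(k, "|", fixed = TRUE)[[1L]])
    }, integer(1L))
    cand <- cand[sizes == max(sizes)]
    cand <- lex_min(cand)
  }
  modal <- if (nzchar(cand)) strsplit(cand, "|", fixed = TRUE)[[1L]] else
    character()
  frac <- mean(vapply(fps, function(f) all(modal %in% f), logical(1L)))
  list(modal_fingerprint = modal, convergence_fraction = frac,
       fingerprints = fps, n = length(poses))
}
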