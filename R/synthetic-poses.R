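# Synthetic docking-pose generator: pose sets with a controlled modal
# interaction fingerprint, for validating interaction typing, convergence
# statistics and pose clustering against known ground truth.
#
# The scaffold is a minimal binding site on chain B - a lysine (residue 49,
# full side chain to NZ) and an asparagine (residue 100, side chain to
# ND2/OD1) - mirroring the essential lysine and the amide contact of the
# pyruvate site. The modal pose places the pyruvate carboxylate against the
# lysine ammonium (ionic + hydrogen bond) and the ketone oxygen against the
# asparagine amide (hydrogen bond); decoy poses are displaced far enough to
# break those criteria with a safety margin.

syn_site_atoms <- function() {
  mk <- function(res_seq, res_name, names, elements, xyz) {
    data.frame(chain_id = "B", res_seq = res_seq, res_name = res_name,
               atom_name = names, element = elements,
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], het = FALSE,
               stringsAsFactors = FALSE)
  }
  lys <- mk(49L, "LYS",
            c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
            c("N", "C", "C", "O", "C", "C", "C", "C", "N"),
            rbind(c(-7.4, 1.3, 0.3), c(-6.8, 0.0, 0.0), c(-7.5, -1.2, -0.3),
                  c(-8.7, -1.3, -0.4), c(-5.4, 0.6, 0.0), c(-4.1, 0.0, 0.4),
                  c(-2.8, 0.8, 0.0), c(-1.5, 0.0, 0.0), c(0.0, 0.0, 0.0)))
  asn <- mk(100L, "ASN",
            c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
            c("N", "C", "C", "O", "C", "C", "O", "N"),
            rbind(c(11.2, 4.3, 4.5), c(10.6, 4.9, 3.4), c(11.3, 6.1, 2.9),
                  c(12.4, 6.5, 3.3), c(9.2, 5.0, 3.6), c(8.5, 3.9, 3.0),
                  c(9.0, 2.8, 3.2), c(7.3, 3.3, 2.6)))
  rbind(lys, asn)
}

# modal pyruvate placement: carboxylate (C1/O1/O2) against LYS NZ at the
# origin, ketone O3 hydrogen-bonded to ASN ND2
syn_ligand_atoms <- function() {
  data.frame(
    chain_id = "L", res_seq = 1L, res_name = "PYR",
    atom_name = c("C1", "O1", "O2", "C2", "O3", "C3"),
    element = c("C", "O", "O", "C", "O", "C"),
    x = c(3.6, 2.9, 3.6, 5.0, 5.6, 5.7),
    y = c(0.4, 0.0, 1.1, 0.6, 1.6, -0.5),
    z = c(0.15, 0.0, -0.8, 0.4, 0.9, 0.0),
    het = TRUE, stringsAsFactors = FALSE
  )
}

#' Binding-site selection of the synthetic pose scaffold
#'
#' @return A [group_spec()] covering the scaffold's lysine and asparagine.
#' @export
syn_pose_site <- function() group_spec("B", c(49L, 100L))

#' Generate a synthetic docking pose set with known convergence
#'
#' Builds `round(n * modal_fraction)` poses satisfying the designated modal
#' fingerprint (ionic + hydrogen bond to the scaffold lysine, hydrogen bond
#' to the scaffold asparagine) up to a margin-safe jitter, and displaces the
#' remaining poses so that at least one criterion is broken by a safe
#' margin. Deterministic given the seed.
#'
#' @param n Number of poses (>= 1).
#' @param modal_fraction Fraction of poses carrying the modal fingerprint.
#' @param ligand [ligand_spec()]; the default pyruvate spec matches the
#'   built-in scaffold.
#' @param seed Integer seed.
#' @return List: `poses` (list of `StructureModel`), `truth` (`data.frame`
#'   with `pose_id`, `modal`), `ligand`, `site`.
#' @export
generate_pose_set <- function(n = 80, modal_fraction = 0.7,
                              ligand = pyruvate_spec(), seed = 1) {
  check_that(n >= 1, "n must be >= 1")
  check_that(modal_fraction >= 0 && modal_fraction <= 1,
             "modal_fraction must be in [0, 1]")
  n_modal <- round(n * modal_fraction)
  site_at <- syn_site_atoms()
  lig_at <- syn_ligand_atoms()
  poses <- vector("list", n)
  modal <- rep(FALSE, n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      la <- lig_at
      if (i <= n_modal) {
        # margin-safe jitter: all modal criteria stay inside their cutoffs
        shift <- stats::runif(3L, -0.12, 0.12)
        modal[i] <- TRUE
      } else {
        # displace upward and sideways: ionic and hydrogen-bond criteria
        # break with >= 0.2 A margin, decoys scatter for clustering
        shift <- c(stats::runif(1L, -1.5, 1.5), stats::runif(1L, -1.5, 1.5),
                   stats::runif(1L, 5.6, 7.5))
      }
      la[, c("x", "y", "z")] <- sweep(as.matrix(la[, c("x", "y", "z")]), 2L,
                                      shift, `+`)
      poses[[i]] <- structure_model(
        sprintf("pose#%03d", i), rbind(site_at, la),
        meta = list(modal = modal[i], seed = seed)
      )
    }
  })
  truth <- data.frame(
    pose_id = vapply(poses, function(p) p$model_id, character(1L)),
    modal = modal, stringsAsFactors = FALSE
  )
  list(poses = poses, truth = truth, ligand = ligand, site = syn_pose_site())
}
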