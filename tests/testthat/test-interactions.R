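# Geometric interaction typing, fingerprints, convergence, pose clustering.

pyr_site <- function() group_spec("B", 49L)

test_that("hydrogen-bond and ionic criteria classify just-inside/outside geometries", {
  lig <- pyruvate_spec()
  # carboxylate O 2.9 A from lysine NZ: ionic plus hydrogen bond
  close <- structure_model("c1#1", rbind(lys_fragment(),
                                         carboxylate_ligand(c(2.9, 0, 0))))
  rec <- detect_interactions(close, lig, pyr_site())
  expect_setequal(unique(rec$kind), c("hbond", "ionic"))
  expect_true(any(rec$kind == "ionic" & rec$res_seq == 49L))
  # just outside the hydrogen-bond cutoff but inside ionic
  mid <- structure_model("c2#1", rbind(lys_fragment(),
                                       carboxylate_ligand(c(3.9, 0, 0))))
  rec_mid <- detect_interactions(mid, lig, pyr_site())
  expect_identical(unique(rec_mid$kind), "ionic")
  # centroid beyond 5.5 A: nothing
  far <- structure_model("c3#1", rbind(lys_fragment(),
                                       carboxylate_ligand(c(6.2, 0, 0))))
  expect_identical(nrow(detect_interactions(far, lig, pyr_site())), 0L)
  # everything >= 10 A away: empty record list
  apart <- structure_model("c4#1", rbind(lys_fragment(),
                                         carboxylate_ligand(c(20, 0, 0))))
  expect_identical(nrow(detect_interactions(apart, lig, pyr_site())), 0L)
})

test_that("pi-stacking geometry windows are honored", {
  ring_names_p <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  ring_names_l <- paste0("L", 1:6)
  lig_spec <- ligand_spec("LIG", rings = list(ring_names_l))
  site <- group_spec("B", 71L)
  mk <- function(center, normal) {
    structure_model("pi#1", rbind(
      hexagon_atoms("B", 71L, "PHE", ring_names_p, c(0, 0, 0), c(0, 0, 1)),
      hexagon_atoms("L", 1L, "LIG", ring_names_l, center, normal, het = TRUE)
    ))
  }
  tilt <- function(deg) c(sin(deg * pi / 180), 0, cos(deg * pi / 180))
  # parallel: distance 4.0, interplanar 5 degrees, offset 1.0
  par_in <- detect_interactions(mk(c(1.0, 0, sqrt(16 - 1)), tilt(5)),
                                lig_spec, site)
  expect_identical(unique(par_in$kind), "pi_parallel")
  # interplanar angle 45 degrees: neither window
  none_ang <- detect_interactions(mk(c(1.0, 0, sqrt(16 - 1)), tilt(45)),
                                  lig_spec, site)
  expect_identical(nrow(none_ang), 0L)
  # lateral offset 2.5 breaks the parallel window
  off_out <- detect_interactions(mk(c(2.5, 0, 3.55), tilt(0)), lig_spec, site)
  expect_identical(nrow(off_out), 0L)
  # T-shaped: 85 degrees at 5.0 A
  perp_in <- detect_interactions(mk(c(0, 0, 5.0), tilt(85)), lig_spec, site)
  expect_identical(unique(perp_in$kind), "pi_perpendicular")
  # T-shaped beyond 6.0 A
  perp_out <- detect_interactions(mk(c(0, 0, 6.5), tilt(85)), lig_spec, site)
  expect_identical(nrow(perp_out), 0L)
})

test_that("hydrophobic contacts collapse to one record per residue", {
  leu <- atoms_df("B", 82L, c("CB", "CG", "CD1", "CD2"), rep("C", 4L),
                  c(0, 0, 0, 1.5, 0, 0, 2.6, 0.9, 0, 2.6, -0.9, 0),
                  res_name = "LEU")
  lig_near <- atoms_df("L", 1L, "C3", "C", c(2.6, 0.9, 3.8),
                       res_name = "PYR", het = TRUE)
  lig_spec <- ligand_spec("PYR", apolar = "C3")
  m <- structure_model("h#1", rbind(leu, lig_near))
  rec <- detect_interactions(m, lig_spec, group_spec("B", 82L))
  expect_identical(rec$kind, "hydrophobic")
  expect_identical(nrow(rec), 1L)  # collapsed over the four carbons
  expect_equal(rec$distance, 3.8, tolerance = 1e-9)
  lig_far <- atoms_df("L", 1L, "C3", "C", c(2.6, 0.9, 4.3),
                      res_name = "PYR", het = TRUE)
  m2 <- structure_model("h#2", rbind(leu, lig_far))
  expect_identical(nrow(detect_interactions(m2, lig_spec,
                                            group_spec("B", 82L))), 0L)
})

test_that("histidine protonation switches on the ionic channel", {
  his <- rbind(
    hexagon_atoms("B", 86L, "HIS", c("CG", "ND1", "CD2", "CE1", "NE2", "XX"),
                  c(0, 0, 0), c(0, 0, 1), radius = 1.17)[1:5, ],
    atoms_df("B", 86L, "CB", "C", c(-2.2, 0, -0.6), res_name = "HIS")
  )
  his$element[his$atom_name %in% c("ND1", "NE2")] <- "N"
  lig <- carboxylate_ligand(c(4.0, 0, 1.2))
  m <- structure_model("his#1", rbind(his, lig))
  site <- group_spec("B", 86L)
  neutral <- detect_interactions(m, pyruvate_spec(), site)
  expect_false(any(neutral$kind == "ionic"))
  prot <- detect_interactions(m, pyruvate_spec(), site, his_protonated = TRUE)
  expect_true(any(prot$kind == "ionic"))
})

test_that("every emitted record satisfies its own cutoff (self-audit)", {
  crit <- interaction_criteria()
  ps <- generate_pose_set(n = 20, modal_fraction = 0.5, seed = 11)
  for (p in ps$poses) {
    rec <- detect_interactions(p, ps$ligand, ps$site, crit)
    for (i in seq_len(nrow(rec))) {
      lim <- switch(rec$kind[i],
                    hbond = crit$hbond_dist,
                    ionic = crit$ionic_dist,
                    pi_parallel = crit$pi_parallel_dist,
                    pi_perpendicular = crit$pi_perp_dist,
                    hydrophobic = crit$hydrophobic_dist)
      expect_lte(rec$distance[i], lim)
    }
  }
})

test_that("detect_interactions is invariant under rigid transforms", {
  ps <- generate_pose_set(n = 4, modal_fraction = 1, seed = 5)
  p <- ps$poses[[1L]]
  base <- detect_interactions(p, ps$ligand, ps$site)
  R <- rot_matrix(c(2, -1, 1), 63)
  moved <- set_coords(p, coords(p) %*% t(R) +
                        matrix(c(13, -7, 4), nrow(p$atoms), 3L, byrow = TRUE))
  got <- detect_interactions(moved, ps$ligand, ps$site)
  expect_identical(got[, c("kind", "res_seq", "protein_atom", "ligand_atom")],
                   base[, c("kind", "res_seq", "protein_atom", "ligand_atom")])
  expect_equal(got$distance, base$distance, tolerance = 1e-9)
})

test_that("fingerprints are canonical sets over typed residue contacts", {
  expect_identical(fingerprint(data.frame(kind = character(),
                                          chain_id = character(),
                                          res_seq = integer())), character())
  rec <- data.frame(kind = c("hbond", "ionic", "hbond"),
                    chain_id = c("B", "B", "B"),
                    res_seq = c(100L, 49L, 100L), stringsAsFactors = FALSE)
  fp <- fingerprint(rec)
  expect_identical(fp, c("hbond:B:100", "ionic:B:49"))
  # permutation invariance
  expect_identical(fingerprint(rec[c(3, 1, 2), ]), fp)
  # distance changes within the cutoffs leave the fingerprint unchanged
  ps <- generate_pose_set(n = 6, modal_fraction = 1, seed = 9)
  fps <- lapply(ps$poses, function(p) {
    fingerprint(detect_interactions(p, ps$ligand, ps$site))
  })
  expect_true(all(vapply(fps, identical, logical(1L), fps[[1L]])))
})

test_that("pose convergence counts the modal fingerprint", {
  ps <- generate_pose_set(n = 80, modal_fraction = 0.70, seed = 2)
  res <- pose_convergence(ps$poses, ps$ligand, ps$site)
  expect_identical(res$convergence_fraction, 56 / 80)
  # independent counting oracle over the per-pose fingerprints
  keys <- vapply(res$fingerprints, paste, character(1L), collapse = "|")
  expect_identical(unname(sort(table(keys), decreasing = TRUE)[1L]), 56L)
  expect_identical(res$modal_fingerprint,
                   sort(c("hbond:B:100", "hbond:B:49", "ionic:B:49")))
  # all poses identical: full convergence
  all_same <- generate_pose_set(n = 10, modal_fraction = 1, seed = 3)
  expect_identical(
    pose_convergence(all_same$poses, all_same$ligand, all_same$site)$convergence_fraction,
    1)
})

test_that("average-linkage heights match the brute-force agglomeration", {
  withr::with_seed(44, {
    poses <- lapply(1:12, function(i) {
      point_pose(sprintf("p#%02d", i), runif(3, 0, 20))
    })
  })
  cl <- cluster_poses(poses)
  brute <- brute_average_linkage_heights(cl$distance_matrix)
  expect_equal(sort(cl$linkage$height), brute, tolerance = 1e-9)
})

test_that("the Kelley criterion recovers planted pose groups", {
  centers <- list(c(0, 0, 0), c(25, 0, 0), c(0, 25, 0))
  withr::with_seed(17, {
    poses <- list()
    truth <- integer()
    for (g in seq_along(centers)) {
      for (i in 1:10) {
        poses[[length(poses) + 1L]] <-
          point_pose(sprintf("g%d_%02d", g, i), centers[[g]] + rnorm(3, 0, 0.4))
        truth <- c(truth, g)
      }
    }
  })
  cl <- cluster_poses(poses)
  expect_identical(cl$chosen_k, 3L)
  expect_equal(adjusted_rand(cl$assignment, truth), 1)
  expect_false(cl$degenerate)
  # penalty defined and finite over the whole level range
  expect_identical(names(cl$kelley_penalty), as.character(2:(length(poses) - 1L)))
  expect_true(all(is.finite(cl$kelley_penalty)))
  # stable under pose order permutation
  perm <- withr::with_seed(1, sample(length(poses)))
  cl_p <- cluster_poses(poses[perm])
  expect_identical(cl_p$chosen_k, 3L)
  expect_equal(adjusted_rand(cl_p$assignment, truth[perm]), 1)
})

test_that("identical poses degrade to the flagged k = 2 tie rule", {
  poses <- lapply(1:6, function(i) point_pose(sprintf("same#%d", i), c(1, 2, 3)))
  cl <- cluster_poses(poses)
  expect_identical(cl$chosen_k, 2L)
  expect_true(cl$degenerate)
})

test_that("pose clustering rejects mismatched atom composition", {
  p1 <- point_pose("a#1", c(0, 0, 0))
  p2 <- point_pose("b#1", c(1, 0, 0))
  p3 <- structure_model("c#1", atoms_df("L", 2L, "C9", "C", c(2, 0, 0),
                                        res_name = "LIG", het = TRUE))
  expect_error(cluster_poses(list(p1, p2, p3)), "composition")
})
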