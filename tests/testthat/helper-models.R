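# Shared fixtures and independent oracles, all built in code.

# compact atom-table builder: one row per atom
atoms_df <- function(chain, res, name, element, xyz, res_name = "GLY",
                     het = FALSE) {
  xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
  data.frame(chain_id = chain, res_seq = res, res_name = res_name,
             atom_name = name, element = element,
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], het = het,
             stringsAsFactors = FALSE)
}

# n pseudo-random heavy atoms on one chain, one residue per atom
random_atom_model <- function(n, chain = "A", spread = 10, id = "rand#1") {
  structure_model(id, atoms_df(
    chain = chain, res = seq_len(n), name = "CA", element = "C",
    xyz = as.vector(t(matrix(stats::runif(3 * n, -spread, spread), n, 3L)))
  ))
}

# independent oracle: the printed rational switching function, summed with
# an explicit double loop
naive_coordination <- function(x1, x2, r0) {
  total <- 0
  for (i in seq_len(nrow(x1))) {
    for (j in seq_len(nrow(x2))) {
      r <- sqrt(sum((x1[i, ] - x2[j, ])^2))
      x <- r / r0
      total <- total + if (abs(x - 1) < 1e-9) 0.5 else
        (1 - x^6) / (1 - x^12)
    }
  }
  total
}

# independent oracle: brute-force average-linkage agglomeration, O(n^3);
# returns the sorted merge heights
brute_average_linkage_heights <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        d <- mean(dmat[clusters[[a]], clusters[[b]]])
        if (d < best_d) {
          best_d <- d
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  sort(heights)
}

# exhaustive search oracle for the most central cluster member
brute_representative <- function(pts) {
  dm <- as.matrix(stats::dist(pts))
  which.min(rowSums(dm))
}

# rotation matrix about a unit axis (Rodrigues), independent of the package
rot_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# single-atom pose models for clustering tests
point_pose <- function(id, xyz) {
  structure_model(id, atoms_df("L", 1L, "C1", "C",
                               xyz, res_name = "LIG", het = TRUE))
}

adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    mclust::adjustedRandIndex(a, b)
  } else {
    # small self-contained ARI fallback
    tab <- table(a, b)
    comb2 <- function(x) sum(choose(x, 2))
    sum_ij <- comb2(as.vector(tab))
    sum_a <- comb2(rowSums(tab))
    sum_b <- comb2(colSums(tab))
    n2 <- choose(sum(tab), 2)
    exp_idx <- sum_a * sum_b / n2
    (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
  }
}

# default synthetic-ensemble selections used across tests
syn_fixed_selection <- function() {
  list(group_spec("A", 20:40), group_spec("B", 30:50))
}
syn_mobile_selection <- function(chain = "A") {
  if (chain == "A") list(group_spec("A", c(44:58, 65:85)))
  else list(group_spec("B", c(58:72, 79:99)))
}

# regular polygon of carbons in the plane with the given unit normal
hexagon_atoms <- function(chain, res, res_name, names, center, normal,
                          radius = 1.39, het = FALSE) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2L] * e1[3L] - n[3L] * e1[2L],
          n[3L] * e1[1L] - n[1L] * e1[3L],
          n[1L] * e1[2L] - n[2L] * e1[1L])
  ang <- seq(0, 2 * pi, length.out = 7L)[1:6]
  xyz <- t(vapply(ang, function(a) {
    center + radius * (cos(a) * e1 + sin(a) * e2)
  }, numeric(3L)))
  atoms_df(chain, res, names, rep("C", 6L), as.vector(t(xyz)),
           res_name = res_name, het = het)
}

# lysine side-chain fragment ending at NZ (default at the origin)
lys_fragment <- function(nz = c(0, 0, 0)) {
  atoms_df("B", 49L, c("CB", "CG", "CD", "CE", "NZ"),
           c("C", "C", "C", "C", "N"),
           c(nz + c(-5.4, 0.6, 0), nz + c(-4.1, 0, 0.4), nz + c(-2.8, 0.8, 0),
             nz + c(-1.5, 0, 0), nz),
           res_name = "LYS")
}

# schematic carboxylate ligand: O1 at the given point, O2/C1 around it
carboxylate_ligand <- function(o1, tilt = c(0.7, 1.1, -0.8)) {
  o2 <- o1 + tilt
  c1 <- (o1 + o2) / 2 + c(0.6, -0.4, 0.2)
  atoms_df("L", 1L, c("C1", "O1", "O2"), c("C", "O", "O"),
           c(c1, o1, o2), res_name = "PYR", het = TRUE)
}
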