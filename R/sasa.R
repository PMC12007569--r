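# Solvent-accessible surface area (Shrake-Rupley with a deterministic
# Fibonacci sphere lattice) and buried interface area between two chains.

# Bondi van der Waals radii (Angstrom), keyed by element symbol.
# Unknown elements are a hard error rather than a silent default.
VDW_RADII <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  bad <- unique(element[is.na(r)])
  check_that(length(bad) == 0L,
             "no van der Waals radius for element(s): %s",
             paste(bad, collapse = ", "))
  unname(r)
}

# Deterministic unit-sphere lattice (golden-angle spiral); no RNG, so SASA
# values are bit-stable across runs.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# Per-atom solvent-accessible area for one atom set (the only occluders are
# the atoms passed in).
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  sph <- fibonacci_sphere(n_points)
  rr <- radii + probe
  out <- numeric(n)
  # neighbour cut: two expanded spheres can only intersect within this sum
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (rr[i] + rr)^2 & seq_len(n) != i)
    pts <- sph * rr[i]
    pts <- sweep(pts, 2L, xyz[i, ], `+`)
    if (length(nb)) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(acc)) break
        dj <- rowSums(sweep(pts[acc, , drop = FALSE], 2L, xyz[j, ])^2)
        acc[acc] <- dj > rr[j]^2
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    out[i] <- frac * 4 * pi * rr[i]^2
  }
  out
}

#' Solvent-accessible surface area of an atom set
#'
#' Shrake-Rupley sampling on a deterministic Fibonacci point lattice.
#'
#' @param atoms Atom `data.frame` (e.g. from [select_atoms()]) or a
#'   `StructureModel`.
#' @param probe Probe radius in Angstrom (water, 1.4).
#' @param n_points Lattice points per atom sphere.
#' @return Total SASA in Angstrom^2.
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960) {
  if (inherits(atoms, "StructureModel")) atoms <- atoms$atoms
  sum(shrake_rupley(coords(atoms), vdw_radius(atoms$element),
                    probe = probe, n_points = n_points))
}

#' Buried interface area between two chains
#'
#' Half the solvent-accessible surface lost on complex formation:
#' `(SASA_A + SASA_B - SASA_AB) / 2`, each term computed over the named
#' chain(s) only. Heavy atoms are used by default; set `atoms = "all"` to
#' include hydrogens when the model has them.
#'
#' @param model A `StructureModel` containing both chains.
#' @param chain_a,chain_b Chain identifiers.
#' @param probe Probe radius, Angstrom.
#' @param n_points Sphere lattice points per atom.
#' @param atoms `"heavy"` (default) or `"all"`.
#' @return Buried area in Angstrom^2 (non-negative up to lattice noise).
#' @export
buried_interface_area <- function(model, chain_a, chain_b, probe = 1.4,
                                  n_points = 960, atoms = c("heavy", "all")) {
  atoms <- match.arg(atoms)
  at <- model$atoms
  for (ch in c(chain_a, chain_b)) {
    check_that(any(at$chain_id == ch),
               "model '%s' has no chain '%s'", model$model_id, ch)
  }
  check_that(chain_a != chain_b, "chain_a and chain_b must differ")
  if (atoms == "heavy") at <- at[!at$is_hydrogen, , drop = FALSE]
  a <- at[at$chain_id == chain_a, , drop = FALSE]
  b <- at[at$chain_id == chain_b, , drop = FALSE]
  ab <- rbind(a, b)
  s <- function(d) sum(shrake_rupley(coords(d), vdw_radius(d$element),
                                     probe = probe, n_points = n_points))
  (s(a) + s(b) - s(ab)) / 2
}
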