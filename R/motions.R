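# Rigid-body rotation analysis between two conformations: fixed-selection
# alignment, then the residual rotation of a mobile helix bundle. This is a
# deliberate fixed-selection analysis (selections supplied by the caller),
# not an automatic dynamic-domain decomposition.

#' Rigid-body rotation of a helix bundle between two states
#'
#' Superposes `state_b` onto `state_a` using the fixed selection, then
#' computes the residual rigid transform best mapping the aligned mobile
#' atoms of `state_b` onto those of `state_a`. The rotation angle comes from
#' the matrix trace (clamped arccos), the axis from the rotation's invariant
#' direction, and the screw translation is the component of the residual
#' translation along the axis.
#'
#' @param state_a,state_b `StructureModel`s sharing the selected atoms.
#' @param fixed [group_spec()] or list: the frame of reference (e.g. the
#'   partner protomer or the static helices).
#' @param mobile [group_spec()] or list: the rotating bundle (e.g. H2-H3).
#' @return A `rotation_analysis`: `angle_deg` in `[0, 180]`, unit `axis`,
#'   `screw_translation` (Angstrom), `rmsd_fixed` (residual of the fixed
#'   alignment), `rmsd_mobile_after` (residual of the mobile fit), and the
#'   selections used.
#' @export
bundle_rotation <- function(state_a, state_b, fixed, mobile) {
  fa <- select_atoms(state_a, fixed)
  fb <- select_atoms(state_b, fixed)
  ma <- select_atoms(state_a, mobile)
  mb <- select_atoms(state_b, mobile)
  check_that(nrow(fa) == nrow(fb) && nrow(ma) == nrow(mb),
             "selections resolve to different atom counts in the two states")
  check_that(all(fa$atom_name == fb$atom_name) && all(ma$atom_name == mb$atom_name),
             "selections pair different atoms in the two states")
  frame_fit <- superpose(coords(fb), coords(fa))
  mb_aligned <- apply_transform(coords(mb), frame_fit)
  res_fit <- superpose(mb_aligned, coords(ma))
  rot <- res_fit$rotation
  angle <- rotation_angle(rot)
  axis <- rotation_axis(rot)
  # screw component: projection of the net displacement of the mobile
  # centroid onto the rotation axis
  disp <- colMeans(coords(ma)) - colMeans(mb_aligned)
  screw <- sum(axis * disp)
  # orient the axis so the screw translation is non-negative (sign of the
  # axis is otherwise arbitrary for an angle in [0, 180])
  if (screw < 0) {
    axis <- -axis
    screw <- -screw
  }
  structure(list(
    fixed_selection = fixed,
    mobile_selection = mobile,
    angle_deg = angle,
    axis = axis,
    screw_translation = screw,
    rmsd_fixed = frame_fit$rmsd,
    rmsd_mobile_after = res_fit$rmsd
  ), class = "rotation_analysis")
}

#' @export
print.rotation_analysis <- function(x, ...) {
  cat(sprintf(
    "rotation_analysis: %.3f deg about (%.3f, %.3f, %.3f), screw %.3f A\n",
    x$angle_deg, x$axis[1L], x$axis[2L], x$axis[3L], x$screw_translation))
  cat(sprintf("  rmsd: fixed %.4f A, mobile after fit %.4f A\n",
              x$rmsd_fixed, x$rmsd_mobile_after))
  invisible(x)
}

# invariant direction of a rotation matrix (unit eigenvector for eigenvalue
# 1), with the skew-part shortcut away from 0/180 degrees
rotation_axis <- function(rot) {
  skew <- c(rot[3L, 2L] - rot[2L, 3L],
            rot[1L, 3L] - rot[3L, 1L],
            rot[2L, 1L] - rot[1L, 2L])
  n <- sqrt(sum(skew^2))
  if (n > 1e-8) return(skew / n)
  # near 0 or 180 degrees: eigen-decomposition of the symmetric part
  ev <- eigen(rot)
  i <- which.min(abs(ev$values - 1))
  ax <- Re(ev$vectors[, i])
  ax / sqrt(sum(ax^2))
}

#' Per-residue displacement table with hinge-candidate window
#'
#' After aligning `state_b` onto `state_a` on the fixed selection, reports
#' each residue's C-alpha displacement and flags the candidate hinge: the
#' window (in author numbering, among consecutively present residues) with
#' the maximal displacement gradient, i.e. where the structure switches from
#' staying put to moving. A simplified localization of the bending/pivot
#' region between the fixed frame and the mobile bundle.
#'
#' @param state_a,state_b `StructureModel`s.
#' @param fixed [group_spec()] or list used for the alignment.
#' @param window Half-width (in residues) of the flagged hinge window.
#' @param min_motion Displacement (Angstrom) below which no hinge is
#'   reported.
#' @return `data.frame`: `chain_id`, `res_seq`, `displacement`, `hinge`
#'   (logical window flag).
#' @export
hinge_report <- function(state_a, state_b, fixed, window = 3,
                         min_motion = 0.5) {
  fa <- select_atoms(state_a, fixed)
  fb <- select_atoms(state_b, fixed)
  fit <- superpose(coords(fb), coords(fa))
  ca_a <- state_a$atoms[state_a$atoms$atom_name == "CA", , drop = FALSE]
  ca_b <- state_b$atoms[state_b$atoms$atom_name == "CA", , drop = FALSE]
  check_that(nrow(ca_a) > 0L, "state_a has no C-alpha atoms")
  key_a <- paste(ca_a$chain_id, ca_a$res_seq)
  key_b <- paste(ca_b$chain_id, ca_b$res_seq)
  common <- intersect(key_a, key_b)
  check_that(length(common) > 0L, "no shared C-alpha atoms between states")
  ca_a <- ca_a[match(common, key_a), , drop = FALSE]
  ca_b <- ca_b[match(common, key_b), , drop = FALSE]
  moved <- apply_transform(coords(ca_b), fit)
  disp <- sqrt(rowSums((coords(ca_a) - moved)^2))
  out <- data.frame(chain_id = ca_a$chain_id, res_seq = ca_a$res_seq,
                    displacement = disp, hinge = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain_id, out$res_seq), , drop = FALSE]
  rownames(out) <- NULL
  for (ch in unique(out$chain_id)) {
    rows <- which(out$chain_id == ch)
    d <- out$displacement[rows]
    if (max(d) < min_motion) next  # chain does not move: no hinge
    grad <- abs(diff(d))
    j <- which.max(grad)  # steepest change between consecutive residues
    lo <- max(1L, j - window + 1L)
    hi <- min(length(rows), j + window)
    out$hinge[rows[lo:hi]] <- TRUE
  }
  out
}
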