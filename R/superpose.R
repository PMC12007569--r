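# Least-squares rigid-body superposition (Kabsch) and plain RMSD.

#' Superpose one coordinate set onto another
#'
#' Computes the least-squares rigid transform (proper rotation plus
#' translation) mapping `mobile` onto `reference` over positionally paired
#' atoms, via singular value decomposition of the covariance matrix with the
#' usual determinant correction so the rotation is never a reflection.
#'
#' @param mobile,reference n x 3 coordinate matrices (or objects accepted by
#'   [coords()]), n >= 3, positionally paired.
#' @return A `superposition` object: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom). The transform acts as
#'   `x %*% t(rotation) + translation`.
#' @export
superpose <- function(mobile, reference) {
  m <- coords_matrix(mobile)
  r <- coords_matrix(reference)
  check_that(nrow(m) == nrow(r), "coordinate sets differ in length (%d vs %d)",
             nrow(m), nrow(r))
  check_that(nrow(m) >= 3L, "superposition needs at least 3 paired atoms")
  cm <- colMeans(m)
  cr <- colMeans(r)
  mc <- sweep(m, 2L, cm)
  rc <- sweep(r, 2L, cr)
  h <- crossprod(mc, rc)  # 3x3 covariance
  sv <- svd(h)
  # guard against degenerate (collinear) geometry: rank of the centred
  # coordinates must be >= 2 for a unique rotation
  if (sv$d[2L] <= max(sv$d) * 1e-10) {
    stop("degenerate geometry: paired coordinates are (near-)collinear",
         call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- as.numeric(cr - rot %*% cm)
  moved <- m %*% t(rot) + matrix(trans, nrow(m), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - r)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A, rotation angle %.3f deg\n",
              x$rmsd, rotation_angle(x$rotation)))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix (or object accepted by [coords()]).
#' @param transform A `superposition` object.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  m <- coords_matrix(xyz)
  m %*% t(transform$rotation) +
    matrix(transform$translation, nrow(m), 3L, byrow = TRUE)
}

#' Root-mean-square deviation without fitting
#'
#' Paired RMSD in the common frame: no superposition is applied. This is the
#' "without fitting" distance used for docking-pose clustering.
#'
#' @param a,b Paired n x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_unaligned <- function(a, b) {
  a <- coords_matrix(a)
  b <- coords_matrix(b)
  check_that(nrow(a) == nrow(b), "coordinate sets differ in length (%d vs %d)",
             nrow(a), nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

# angle (degrees, in [0, 180]) of a rotation matrix, trace formula with
# clamping against round-off
rotation_angle <- function(rot) {
  arg <- (sum(diag(rot)) - 1) / 2
  acos(min(1, max(-1, arg))) * 180 / pi
}

coords_matrix <- function(x) {
  if (inherits(x, "StructureModel") || is.data.frame(x)) return(coords(x))
  m <- as.matrix(x)
  check_that(ncol(m) == 3L, "coordinates must be an n x 3 matrix")
  storage.mode(m) <- "double"
  check_that(all(is.finite(m)), "non-finite coordinates")
  m
}
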