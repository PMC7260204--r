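#' Dipole moment of a superparamagnetic bead
#'
#' The bead magnetizes along the applied field with an effective
#' susceptibility chi, giving a point-dipole moment
#' `m = chi * H_ext * (4/3) pi r_mb^3` (A m^2).  chi is a fitted scaling
#' constant and the bead-volume factor is absorbed consistently here and in
#' the potential computation.
#'
#' @param bead a [bead_spec()].
#' @param H_ext external field 3-vector in A/m.
#' @return dipole moment 3-vector in A m^2 (zero field gives zero moment).
#' @export
bead_moment <- function(bead, H_ext) {
  stopifnot(length(H_ext) == 3, all(is.finite(H_ext)))
  bead$chi * as.numeric(H_ext) * bead_volume(bead)
}

#' Stray field of a point dipole
#'
#' `H(r) = (1/4pi) (3 rhat (m . rhat) - m) / |r|^3` in A/m.  Accepts a
#' single displacement or a matrix of displacements (rows).
#'
#' @param m dipole moment 3-vector (A m^2).
#' @param r displacement 3-vector in metres, or an `n x 3` matrix.
#' @return field 3-vector (A/m), or an `n x 3` matrix.
#' @export
dipole_field <- function(m, r) {
  m <- as.numeric(m)
  stopifnot(length(m) == 3)
  single <- is.null(dim(r))
  R <- if (single) matrix(as.numeric(r), ncol = 3) else as.matrix(r)
  if (ncol(R) != 3) stop("'r' must be a 3-vector or an n x 3 matrix")
  r2 <- rowSums(R^2)
  if (any(r2 == 0)) stop("dipole_field() is singular at |r| = 0")
  mdr <- R %*% m
  H <- (3 * R * as.vector(mdr) - matrix(m, nrow(R), 3, byrow = TRUE) * r2) /
    (4 * pi * r2^2.5)
  if (single) as.vector(H) else H
}
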