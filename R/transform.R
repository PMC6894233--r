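#' Rigid transforms between follow-up and baseline space
#'
#' A 6-degree-of-freedom rotation + translation. The stored convention maps
#' *follow-up (moving) physical coordinates into baseline (fixed) physical
#' coordinates*: `x_baseline = R %*% x_followup + t`. Rotations are composed
#' as `R = R1(a1) %*% R2(a2) %*% R3(a3)` about the array axes (axis 1 is
#' axial), angles in radians.
#'
#' @param angles_rad rotation angles (radians) about axes 1..3.
#' @param translation_mm translation vector, mm.
#' @param rotation optional 3x3 orthonormal rotation matrix overriding
#'   `angles_rad`.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles_rad = c(0, 0, 0), translation_mm = c(0, 0, 0),
                            rotation = NULL) {
  if (is.null(rotation)) {
    rotation <- rotation_from_angles(angles_rad)
  } else {
    check_rotation(rotation)
    angles_rad <- angles_from_rotation(rotation)
  }
  structure(list(rotation = rotation,
                 angles_rad = as.numeric(angles_rad),
                 translation_mm = as.numeric(translation_mm),
                 convention = "followup_to_baseline"),
            class = "rigid_transform")
}

rotation_from_angles <- function(a) {
  stopifnot(length(a) == 3)
  r1 <- matrix(c(1, 0, 0,
                 0, cos(a[1]), -sin(a[1]),
                 0, sin(a[1]), cos(a[1])), 3, 3, byrow = TRUE)
  r2 <- matrix(c(cos(a[2]), 0, sin(a[2]),
                 0, 1, 0,
                 -sin(a[2]), 0, cos(a[2])), 3, 3, byrow = TRUE)
  r3 <- matrix(c(cos(a[3]), -sin(a[3]), 0,
                 sin(a[3]), cos(a[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  r1 %*% r2 %*% r3
}

# Euler extraction for the R1 R2 R3 convention used above.
angles_from_rotation <- function(R) {
  a2 <- asin(max(-1, min(1, R[1, 3])))
  if (abs(cos(a2)) > 1e-8) {
    a1 <- atan2(-R[2, 3], R[3, 3])
    a3 <- atan2(-R[1, 2], R[1, 1])
  } else {  # gimbal lock
    a1 <- atan2(R[3, 2], R[2, 2])
    a3 <- 0
  }
  c(a1, a2, a3)
}

check_rotation <- function(R) {
  if (!is.matrix(R) || any(dim(R) != 3))
    stop("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  invisible(TRUE)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> (%s)\n  angles: %s deg\n  translation: %s mm\n",
              x$convention,
              paste(format(x$angles_rad * 180 / pi, digits = 4), collapse = ", "),
              paste(format(x$translation_mm, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param transform a [rigid_transform].
#' @return 4x4 matrix acting on homogeneous physical coordinates (mm).
#' @export
tf_matrix <- function(transform) {
  M <- diag(4)
  M[1:3, 1:3] <- transform$rotation
  M[1:3, 4] <- transform$translation_mm
  M
}

#' Compose, invert and apply rigid transforms
#'
#' `tf_compose(a, b)` returns the transform applying `b` first, then `a`;
#' `tf_inverse` satisfies `compose(T, inverse(T)) = identity` to machine
#' precision; `tf_apply` maps an `n x 3` matrix of physical points.
#'
#' @param a,b,transform [rigid_transform] objects.
#' @return a [rigid_transform], or for `tf_apply` an `n x 3` matrix.
#' @export
tf_compose <- function(a, b) {
  rigid_transform(rotation = a$rotation %*% b$rotation,
                  translation_mm = as.numeric(a$rotation %*% b$translation_mm) +
                    a$translation_mm)
}

#' @rdname tf_compose
#' @export
tf_inverse <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(rotation = Rt,
                  translation_mm = as.numeric(-Rt %*% transform$translation_mm))
}

#' @rdname tf_compose
#' @param points `n x 3` matrix (or length-3 vector) of physical coordinates, mm.
#' @export
tf_apply <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  sweep(points %*% t(transform$rotation), 2, transform$translation_mm, "+")
}

#' Rotation angle between two rigid transforms, in degrees
#'
#' The geodesic angle of `Ra %*% t(Rb)`; with `b` missing, the angle of `a`
#' itself. Used to express registration error as a single rotation magnitude.
#'
#' @param a,b [rigid_transform] objects.
#' @return angle in degrees.
#' @export
tf_rotation_angle_deg <- function(a, b = NULL) {
  R <- if (is.null(b)) a$rotation else a$rotation %*% t(b$rotation)
  cosang <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Serialize a rigid transform as a plain-text matrix file
#'
#' Writes a small header (convention) followed by the homogeneous 4x4 matrix,
#' whitespace separated; `read_transform` inverts the operation.
#'
#' @param transform a [rigid_transform].
#' @param path output text file.
#' @export
write_transform <- function(transform, path) {
  lines <- c(paste("# convention:", transform$convention),
             apply(tf_matrix(transform), 1,
                   function(r) paste(format(r, digits = 17), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  M <- do.call(rbind, lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  rigid_transform(rotation = M[1:3, 1:3], translation_mm = M[1:3, 4])
}

# Rigid transform built from a 6-parameter vector (3 angles, 3 shifts) acting
# about a rotation centre: x -> R (x - c) + c + shift.
rigid_about_center <- function(angles, shift, center) {
  R <- rotation_from_angles(angles)
  rigid_transform(rotation = R,
                  translation_mm = as.numeric(center + shift - R %*% center))
}

# Evaluate an expression with a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
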