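# Rigid (6-parameter) transforms: rotation about a fixed centre followed by
# translation. These model session-to-session head repositioning; the pipeline
# applies KNOWN transforms (simulator ground truth or user-supplied) — it does
# not estimate registration.

#' Construct a rigid transform
#'
#' Maps a world point `x` to `R %*% (x - center) + center + translation`,
#' where `R = Rz %*% Ry %*% Rx` (intrinsic rotations about the world axes, in
#' degrees, applied in x-y-z order).
#'
#' @param translation Length-3 translation (mm). Default zero.
#' @param rotation_deg Length-3 rotation angles about x, y, z (degrees).
#'   Default zero.
#' @param center Length-3 rotation centre (mm). Default the world origin;
#'   session simulation uses the volume centre.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0),
                            rotation_deg = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  translation <- as.numeric(translation)
  rotation_deg <- as.numeric(rotation_deg)
  center <- as.numeric(center)
  stopifnot(length(translation) == 3, length(rotation_deg) == 3,
            length(center) == 3, all(is.finite(c(translation, rotation_deg, center))))
  structure(list(translation = translation, rotation_deg = rotation_deg,
                 center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%s) mm; rot = (%s) deg about (%s)\n",
              paste(format(x$translation), collapse = ", "),
              paste(format(x$rotation_deg), collapse = ", "),
              paste(format(x$center), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Apply or invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @param points n x 3 matrix (or length-3 vector) of world points (mm).
#' @return `apply_transform`: transformed points (n x 3).
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  R <- transform_rotation(transform)
  out <- sweep(pts, 2, transform$center, "-") %*% t(R)
  sweep(out, 2, transform$center + transform$translation, "+")
}

#' @rdname apply_transform
#' @return `invert_transform`: the inverse `rigid_transform` (as a general
#'   rotation + translation; composing the two is the identity to
#'   floating-point precision).
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  # Inverse of x -> R (x - c) + c + t is y -> R^T (y - c - t) + c.
  # Expressed in the same parameterisation with the same centre c:
  #   y -> R^T (y - c) + c + t'  with  t' = -R^T t.
  R <- transform_rotation(transform)
  inv <- rigid_transform(translation = as.numeric(-t(R) %*% transform$translation),
                         rotation_deg = c(0, 0, 0),
                         center = transform$center)
  inv$rotation_matrix <- t(R)
  inv
}

# Internal: rotation matrix of a transform, honouring a stored explicit matrix
# (set by invert_transform, where the Euler decomposition is not needed).
transform_rotation <- function(transform) {
  if (!is.null(transform$rotation_matrix)) transform$rotation_matrix
  else rotation_matrix(transform$rotation_deg)
}
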