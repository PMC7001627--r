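#' 3-D affine transform
#'
#' A transform `p' = L p + t` acting on physical (micrometre) coordinates.
#' Stored as a 3x3 linear part and a length-3 translation.
#'
#' @param linear 3x3 matrix (must be invertible)
#' @param translation length-3 numeric, micrometres
#' @return an object of class `affine3d`
#' @export
affine3d <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3)
  if (abs(det(linear)) <= 1e-9)
    stop("affine3d: linear part is singular")
  structure(list(linear = linear, translation = translation),
            class = "affine3d")
}

#' Identity transform
#' @return an `affine3d`
#' @export
affine_identity <- function() affine3d()

#' Compose two transforms
#'
#' Returns the transform `a(b(p))`.
#' @param a,b `affine3d` objects
#' @return an `affine3d`
#' @export
affine_compose <- function(a, b) {
  affine3d(a$linear %*% b$linear,
           as.numeric(a$linear %*% b$translation) + a$translation)
}

#' Invert a transform
#' @param tf an `affine3d`
#' @return an `affine3d`
#' @export
affine_invert <- function(tf) {
  li <- solve(tf$linear)
  affine3d(li, -as.numeric(li %*% tf$translation))
}

#' Apply a transform to points
#' @param tf an `affine3d`
#' @param pts n x 3 matrix (or length-3 vector) of coordinates
#' @return n x 3 matrix of transformed coordinates
#' @export
affine_apply <- function(tf, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  t(tf$linear %*% t(pts) + tf$translation)
}

#' Rotation about the vertical (y) axis
#'
#' @param angle_deg rotation angle in degrees (right-handed about +y)
#' @param center_um rotation centre in micrometres
#' @return an `affine3d`
#' @export
rotation_y <- function(angle_deg, center_um = c(0, 0, 0)) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), 0, -sin(th),
                0,       1,  0,
                sin(th), 0,  cos(th)), 3, 3, byrow = TRUE)
  affine3d(R, center_um - as.numeric(R %*% center_um))
}

#' Serialize a transform to the 3x4 row-major JSON convention
#' @param tf an `affine3d`
#' @param path optional file to write to
#' @return JSON string (invisibly when writing to a file)
#' @export
affine_to_json <- function(tf, path = NULL) {
  m <- cbind(tf$linear, tf$translation)
  js <- jsonlite::toJSON(list(matrix_3x4_row_major = as.numeric(t(m))),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a transform from its JSON serialization
#' @param x JSON string or file path
#' @return an `affine3d`
#' @export
affine_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  m <- matrix(as.numeric(obj$matrix_3x4_row_major), 3, 4, byrow = TRUE)
  affine3d(m[, 1:3], m[, 4])
}

#' @export
print.affine3d <- function(x, ...) {
  cat("affine3d (um): [L | t] =\n")
  print(cbind(x$linear, t = x$translation))
  invisible(x)
}
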