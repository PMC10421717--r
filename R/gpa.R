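#' Reflect and relabel a landmark configuration
#'
#' Produces the mirror image used in object-symmetry analysis: the first
#' coordinate axis (x) is negated and the rows of each bilateral pair are
#' swapped, so left landmarks take the right labels and vice versa; midline
#' landmarks keep their rows. The operation is an involution. Because
#' Procrustes superimposition later removes orientation, the reflection need
#' not coincide with the anatomical midsagittal plane — any fixed reflection
#' serves.
#'
#' @param coords n_landmarks x 3 coordinate matrix, or a [landmark_config()].
#' @param scheme a [landmark_scheme()].
#' @return object of the same kind as the input, mirrored and relabeled.
#' @export
reflect_relabel <- function(coords, scheme) {
  if (inherits(coords, "landmark_config")) {
    out <- coords
    out$coords <- reflect_relabel(coords$coords, scheme)
    return(out)
  }
  if (nrow(coords) != scheme$n_landmarks)
    stop("expected ", scheme$n_landmarks, " landmarks, found ", nrow(coords))
  m <- coords
  m[, 1] <- -m[, 1]
  swapped <- m
  swapped[scheme$pairs[, 1], ] <- m[scheme$pairs[, 2], ]
  swapped[scheme$pairs[, 2], ] <- m[scheme$pairs[, 1], ]
  swapped
}

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of all landmarks from their
#' centroid; the scale measure removed by Procrustes superimposition.
#'
#' @param coords landmark coordinate matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(coords) {
  cc <- sweep(coords, 2, colMeans(coords))
  sqrt(sum(cc^2))
}

# center at origin and scale to unit centroid size
center_scale <- function(coords) {
  cc <- sweep(coords, 2, colMeans(coords))
  s <- sqrt(sum(cc^2))
  if (s < .Machine$double.eps^0.5)
    stop("degenerate configuration: centroid size is zero")
  cc / s
}

# optimal proper rotation G (det +1) minimizing ||X G - target||_F
optimal_rotation <- function(x, target) {
  a <- crossprod(x, target)           # 3x3
  sv <- svd(a)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Generalized Procrustes superimposition
#'
#' Iterative least-squares alignment: every configuration is centered,
#' scaled to unit centroid size, and rotated (proper rotations only) to the
#' running consensus; the consensus is the re-standardized mean, iterated
#' until its root-mean-square change falls below `tol`. For object-symmetry
#' analyses the input list should contain each original configuration and
#' its [reflect_relabel()] mirror; with `symmetrize = TRUE` (the default
#' when `scheme` is supplied) the consensus is averaged with its own
#' reflection each iteration, pinning the exact reflection invariance that
#' such a set has in the limit.
#'
#' @param coord_list list of n_landmarks x 3 matrices (or a single matrix).
#' @param scheme optional [landmark_scheme()]; enables consensus
#'   symmetrization.
#' @param tol convergence tolerance on the consensus RMS change.
#' @param max_iter iteration cap.
#' @return list with `consensus` (unit-size mean shape), `aligned` (list of
#'   aligned matrices), `iterations`, and `rms_change`.
#' @export
gpa <- function(coord_list, scheme = NULL, tol = 1e-10, max_iter = 100L) {
  if (is.matrix(coord_list)) coord_list <- list(coord_list)
  if (!length(coord_list)) stop("no configurations to superimpose")
  k <- nrow(coord_list[[1]])
  aligned <- lapply(coord_list, function(x) {
    if (nrow(x) != k) stop("configurations differ in landmark count")
    center_scale(x)
  })
  consensus <- aligned[[1]]
  if (!is.null(scheme))
    consensus <- center_scale(consensus + reflect_relabel(consensus, scheme))
  iter <- 0L
  rms <- Inf
  repeat {
    iter <- iter + 1L
    aligned <- lapply(aligned, function(x) x %*% optimal_rotation(x, consensus))
    new_cons <- Reduce(`+`, aligned) / length(aligned)
    new_cons <- center_scale(new_cons)
    if (!is.null(scheme))
      new_cons <- center_scale(new_cons + reflect_relabel(new_cons, scheme))
    rms <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (rms < tol || iter >= max_iter) break
  }
  # final alignment pass against the converged consensus
  aligned <- lapply(aligned, function(x) x %*% optimal_rotation(x, consensus))
  list(consensus = consensus, aligned = aligned,
       iterations = iter, rms_change = rms)
}

#' Full Procrustes distance between two configurations
#'
#' Root summed squared difference after centering, unit-size scaling and
#' optimal proper rotation of `x` onto `y`.
#'
#' @param x,y landmark coordinate matrices of equal dimension.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(x, y) {
  xs <- center_scale(x); ys <- center_scale(y)
  sqrt(sum((xs %*% optimal_rotation(xs, ys) - ys)^2))
}
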