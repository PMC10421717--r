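#' Define a bilateral landmark scheme
#'
#' A landmark scheme records which landmark indices form left/right bilateral
#' pairs and which lie on the midline (midsagittal) plane. With `p` pairs and
#' `u` midline points the configuration has `2p + u` landmarks; in 3D the
#' symmetric and asymmetric shape subspaces after superimposition have
#' dimensions `3p + 2u - 4` and `3p + u - 3` respectively.
#'
#' @param pairs two-column integer matrix (or list of length-2 vectors) of
#'   (left, right) landmark indices, 1-based.
#' @param midline integer vector of midline landmark indices, 1-based.
#' @param dimension landmark dimensionality; only 3 is supported.
#'
#' @return An object of class `"landmark_scheme"`: a list with elements
#'   `n_landmarks`, `pairs` (p x 2 integer matrix), `midline`, `dimension`.
#'
#' @details Every index from 1 to `n_landmarks` must occur exactly once across
#'   `pairs` and `midline`; violations raise an error.
#'
#' @examples
#' sc <- landmark_scheme(pairs = rbind(c(2, 3)), midline = 1)
#' sc$n_landmarks
#' @seealso [macaque_cranial_scheme()] for the 34-landmark cranial scheme.
#' @export
landmark_scheme <- function(pairs, midline = integer(0), dimension = 3L) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("left", "right")))
  midline <- as.integer(midline)
  if (dimension != 3L)
    stop("only 3D landmark schemes are supported")
  if (nrow(pairs) < 1L)
    stop("a landmark scheme needs at least one bilateral pair")
  idx <- c(as.vector(pairs), midline)
  n <- 2L * nrow(pairs) + length(midline)
  if (anyDuplicated(idx))
    stop("landmark indices occur more than once across pairs and midline: ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "))
  if (!setequal(idx, seq_len(n)))
    stop("pairs and midline must cover indices 1..", n, " exactly; got {",
         paste(sort(idx), collapse = ", "), "}")
  structure(
    list(n_landmarks = n, pairs = pairs, midline = midline,
         dimension = 3L),
    class = "landmark_scheme"
  )
}

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme:", x$n_landmarks, "landmarks (",
      nrow(x$pairs), "bilateral pairs,", length(x$midline),
      "midline points), dimension", x$dimension, "\n")
  invisible(x)
}

#' Number of bilateral pairs / midline points in a scheme
#' @param scheme a [landmark_scheme()].
#' @return integer count.
#' @export
n_pairs <- function(scheme) nrow(scheme$pairs)

#' @rdname n_pairs
#' @export
n_midline <- function(scheme) length(scheme$midline)

#' Shape-space dimensions under object symmetry
#'
#' For `p` bilateral pairs and `u` midline landmarks in 3D, the symmetric
#' component of shape spans `3p + 2u - 4` dimensions and the asymmetric
#' component `3p + u - 3` dimensions (translation, rotation and scale having
#' been removed by superimposition, with the reflection constraint splitting
#' the remainder).
#'
#' @param p number of bilateral landmark pairs.
#' @param u number of midline landmarks.
#' @return named integer vector with elements `sym` and `asym`.
#' @examples
#' symmetry_dims(13, 8)  # 51 and 44
#' @export
symmetry_dims <- function(p, u) {
  p <- as.integer(p); u <- as.integer(u)
  stopifnot(p >= 1L, u >= 0L)
  c(sym = 3L * p + 2L * u - 4L, asym = 3L * p + u - 3L)
}

#' The 34-landmark rhesus macaque cranial scheme
#'
#' Thirteen bilateral landmark pairs plus eight midline points placed on the
#' macaque cranium (nasion, premaxillary suture, nasospinale, alveolare,
#' incisive fossa, interpalatine suture, basion and opisthion on the midline;
#' paired points on orbit, zygomatic, alveolus, auditory meatus and cranial
#' base). Landmark numbering is 1-based and matches the published digitizing
#' protocol.
#'
#' @return a [landmark_scheme()] with 34 landmarks.
#' @export
macaque_cranial_scheme <- function() {
  landmark_scheme(
    pairs = rbind(
      c(5L, 6L), c(7L, 8L), c(9L, 10L), c(11L, 12L), c(13L, 14L),
      c(15L, 18L), c(16L, 19L), c(17L, 20L),
      c(25L, 26L), c(27L, 28L), c(29L, 30L), c(31L, 32L), c(33L, 34L)
    ),
    midline = c(1L, 2L, 3L, 4L, 21L, 22L, 23L, 24L)
  )
}
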