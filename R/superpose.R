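#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two conformations of the same atom set, via singular value
#' decomposition of the covariance matrix with the determinant sign
#' corrected so reflections are excluded.
#'
#' @param X,Y n x 3 coordinate matrices (Angstrom), equal n >= 3.
#' @param selection Optional integer atom indices used for the fit
#'   (default: all atoms).
#' @return List: `rmsd` (Angstrom), `rotation` (3 x 3, row-vector
#'   convention: `Xc %*% rotation` superposes onto `Yc`), `translation`
#'   (length 3) such that `X %*% rotation + translation` approximates `Y`.
#' @export
superpose <- function(X, Y, selection = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!is.null(selection)) {
    X <- X[selection, , drop = FALSE]
    Y <- Y[selection, , drop = FALSE]
  }
  if (!all(dim(X) == dim(Y))) stop("coordinate sets differ in size")
  if (ncol(X) != 3L) stop("coordinates must be n x 3")
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 atoms")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Xc, Yc))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate (collinear) atom configuration")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  diff <- Xc %*% R - Yc
  rmsd <- sqrt(sum(diff * diff) / n)
  list(rmsd = rmsd, rotation = R, translation = as.numeric(cy - cx %*% R))
}

#' Pairwise RMSD matrix over trajectory frames
#'
#' @param traj A [traj_frames()] object.
#' @param selection Integer atom indices used for the superposition;
#'   default all non-hydrogen atoms.
#' @return Symmetric matrix of superposed RMSDs, Angstrom.
#' @export
rmsd_matrix <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "traj_frames"))
  if (is.null(selection))
    selection <- which(toupper(traj$element) != "H")
  if (!length(selection)) stop("empty atom selection")
  nf <- length(traj$coords)
  m <- matrix(0, nf, nf)
  if (nf > 1L) {
    for (i in 1:(nf - 1L)) for (j in (i + 1L):nf) {
      m[i, j] <- m[j, i] <-
        superpose(traj$coords[[i]], traj$coords[[j]], selection)$rmsd
    }
  }
  m
}

#' RMSD-cutoff conformational clustering (greedy neighbor count)
#'
#' GROMOS-style clustering: from the pairwise superposed-RMSD matrix,
#' repeatedly take the frame with the most neighbors within the cutoff as
#' the next cluster centroid (ties broken by lowest frame index), assign
#' it and its neighbors to that cluster, remove them, and repeat. Clusters
#' are numbered by decreasing size, ties by lowest centroid index.
#'
#' @param traj A [traj_frames()] object (or a precomputed RMSD matrix via
#'   `rmsd`).
#' @param selection Atom indices for the superposition; default
#'   non-hydrogen atoms.
#' @param cutoff Neighbor cutoff, Angstrom (default 2.5).
#' @param rmsd Optional precomputed pairwise RMSD matrix.
#' @return List of class `cluster_assignment`: `assignment` (frame ->
#'   cluster id), `clusters` (per cluster: `centroid`, `members`),
#'   `cutoff`.
#' @export
cluster_frames <- function(traj, selection = NULL, cutoff = 2.5,
                           rmsd = NULL) {
  if (is.null(rmsd)) rmsd <- rmsd_matrix(traj, selection)
  nf <- nrow(rmsd)
  if (!nf) stop("no frames to cluster")
  alive <- rep(TRUE, nf)
  clusters <- list()
  neighbor <- rmsd <= cutoff          # includes self on the diagonal
  while (any(alive)) {
    counts <- colSums(neighbor[alive, , drop = FALSE])
    counts[!alive] <- -1L
    centroid <- which.max(counts)     # which.max takes the lowest index tie
    members <- which(alive & neighbor[, centroid])
    clusters[[length(clusters) + 1L]] <-
      list(centroid = centroid, members = members)
    alive[members] <- FALSE
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
  cents <- vapply(clusters, function(cl) cl$centroid, 0L)
  ord <- order(-sizes, cents)
  clusters <- clusters[ord]
  assignment <- integer(nf)
  for (k in seq_along(clusters)) assignment[clusters[[k]]$members] <- k
  structure(list(assignment = assignment, clusters = clusters,
                 cutoff = cutoff),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 0L)
  cat(sprintf("%d cluster(s) at %.2f A cutoff; sizes: %s\n",
              length(sizes), x$cutoff, paste(sizes, collapse = ", ")))
  invisible(x)
}
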