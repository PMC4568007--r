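#' Minimum spanning tree of a distance matrix
#'
#' Thin wrapper around [vegan::spantree()] returning the tree as an edge
#' list together with its longest edge, which is the standard truncation
#' distance for PCNM spatial eigenfunctions.
#'
#' @param distances symmetric nonnegative distance matrix (or `dist`).
#' @return list of class `"mst"`: `edges` (data.frame `from`, `to`,
#'   `length`) and `max_edge`.
#' @export
minimum_spanning_tree <- function(distances) {
  D <- as.matrix(distances)
  if (nrow(D) < 2) stop("at least 2 points are required")
  if (anyNA(D) || any(!is.finite(D))) stop("distances must be finite")
  if (any(D < 0) || max(abs(D - t(D))) > 1e-10)
    stop("distances must be nonnegative and symmetric")
  tr <- vegan::spantree(as.dist(D))
  edges <- data.frame(from = 2:nrow(D), to = tr$kid, length = tr$dist)
  structure(list(edges = edges, max_edge = max(tr$dist)), class = "mst")
}

#' PCNM spatial eigenfunctions
#'
#' Principal coordinates of neighbour matrices: the Euclidean distance
#' matrix is truncated at `t` (by default the longest edge of the minimum
#' spanning tree, the largest threshold keeping all points connected);
#' distances beyond `t` are replaced by `4 t`; and the modified matrix is
#' submitted to principal-coordinate analysis (Gower double-centring of
#' `-d^2/2`). The eigenvectors with positive eigenvalues describe spatial
#' variation at all scales the sampling resolves and serve as spatial
#' predictors in constrained ordination.
#'
#' Eigenvectors are returned unit-norm (set `scaling = "sqrt_lambda"` for
#' eigenvalue-scaled scores) and sign-fixed so that each vector's
#' largest-magnitude element is positive.
#'
#' @param coords two-column matrix/data.frame of point coordinates.
#' @param truncation truncation distance `t`; `NULL` (default) uses the MST
#'   longest edge. A user value below it warns (the spatial graph
#'   disconnects).
#' @param scaling `"unit"` or `"sqrt_lambda"`.
#' @param tol positive-eigenvalue tolerance, relative to the largest.
#' @return list of class `"pcnm_basis"`: `vectors` (n x k, columns
#'   `V1..Vk`), `values` (positive eigenvalues, decreasing), `truncation`,
#'   `scaling`.
#' @export
pcnm <- function(coords, truncation = NULL, scaling = c("unit", "sqrt_lambda"),
                 tol = 1e-10) {
  scaling <- match.arg(scaling)
  xy <- as.matrix(coords)
  if (nrow(xy) < 3) stop("at least 3 points are required")
  D <- as.matrix(dist(xy))
  if (max(D) == 0) stop("all points are identical")
  mst <- minimum_spanning_tree(D)
  if (is.null(truncation)) {
    truncation <- mst$max_edge
  } else if (truncation < mst$max_edge) {
    warning("truncation below the MST longest edge: the neighbour graph disconnects")
  }
  Dstar <- D
  Dstar[Dstar > truncation] <- 4 * truncation

  G <- .gower_center(Dstar)
  eig <- eigen(G, symmetric = TRUE)
  keep <- eig$values > tol * max(eig$values)
  vec <- eig$vectors[, keep, drop = FALSE]
  val <- eig$values[keep]
  # reproducible sign: largest-magnitude element of each axis made positive
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  if (scaling == "sqrt_lambda") vec <- sweep(vec, 2, sqrt(val), "*")
  dimnames(vec) <- list(rownames(xy), paste0("V", seq_len(ncol(vec))))
  structure(list(vectors = vec, values = val, truncation = truncation,
                 scaling = scaling), class = "pcnm_basis")
}

# Gower double-centring of -0.5 * D^2.
.gower_center <- function(D) {
  A <- -0.5 * D^2
  rm <- rowMeans(A); gm <- mean(A)
  sweep(sweep(A, 1, rm), 2, rm) + gm
}

#' @export
print.pcnm_basis <- function(x, ...) {
  cat(sprintf("PCNM basis: %d positive axes (truncation t = %.4g, %s scaling)\n",
              length(x$values), x$truncation, x$scaling))
  invisible(x)
}

#' Polynomial trend-surface predictors
#'
#' Monomials `x^a y^b` with `1 <= a + b <= degree` of the centred
#' coordinates, the classical alternative spatial-predictor set for
#' variation partitioning (a degree-`d` surface has `d(d+3)/2` terms). The
#' columns are centred after construction.
#'
#' @param coords two-column coordinate matrix/data.frame.
#' @param degree polynomial degree (default cubic).
#' @return matrix with labelled columns (`x`, `y`, `x2`, `xy`, `y2`, ...),
#'   attribute `"degree"`.
#' @export
trend_surface <- function(coords, degree = 3) {
  if (degree < 1) stop("'degree' must be at least 1")
  xy <- as.matrix(coords)
  if (max(dist(xy)) == 0) stop("all points are identical")
  x <- xy[, 1] - mean(xy[, 1])
  y <- xy[, 2] - mean(xy[, 2])
  cols <- list(); labs <- character(0)
  for (d in seq_len(degree)) {
    for (a in d:0) {
      b <- d - a
      cols[[length(cols) + 1]] <- x^a * y^b
      labs <- c(labs, paste0(
        if (a > 0) paste0("x", if (a > 1) a else "") else "",
        if (b > 0) paste0("y", if (b > 1) b else "") else ""))
    }
  }
  M <- do.call(cbind, cols)
  dimnames(M) <- list(rownames(xy), labs)
  M <- .center(M)
  attr(M, "degree") <- degree
  M
}
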