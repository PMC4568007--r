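#' Generate a nested, spatially explicit sampling design
#'
#' Lays out a rectangular plot with a regular grid of basal nodes. From each
#' node two series of sample points are walked outwards with geometrically
#' decreasing step distances, each step taken in a uniformly random compass
#' direction (drawn to the nearest grade, 1/400 of a circle). Additional
#' "infill" points are placed deterministically in the least-sampled areas so
#' that short and long inter-point distances are both well represented -- the
#' nested survey layout used for small-plot geostatistics of soil fauna.
#'
#' With the defaults (12 nodes; series steps 3.2, 1.6, 1.0, 0.8, 0.6, 0.4,
#' 0.2, 0 m, one series starting at 3.2 m and the other at 1.6 m; 23 infill
#' points; a 35 x 25 m plot) the design has 12 x 16 = 192 node/series points
#' and 215 points in total.
#'
#' @param n_nodes number of basal grid nodes.
#' @param series_a_distances step distances (m) of the longer series walked
#'   from each node; the last step may be 0 ("immediately adjacent").
#' @param series_b_distances step distances (m) of the shorter series.
#' @param n_infill number of deterministic infill points.
#' @param plot_dims plot width and height in metres, `c(width, height)`.
#' @param seed optional integer seed; the same seed reproduces the design.
#' @param max_retries how often a random direction that would leave the plot
#'   is re-drawn before erroring.
#'
#' @return A `data.frame` of class `"sample_points"` with columns `point_id`,
#'   `x`, `y`, `node_id`, `series_id` (`"node"`, `"A"`, `"B"` or `"infill"`)
#'   and `step_distance` (nominal spacing to the previous point of the
#'   series; `NA` for nodes and infill points).
#' @examples
#' pts <- generate_nested_design(seed = 1)
#' nrow(pts)                      # 215
#' table(pts$series_id)
#' @export
generate_nested_design <- function(n_nodes = 12,
                                   series_a_distances = c(3.2, 1.6, 1.0, 0.8, 0.6, 0.4, 0.2, 0),
                                   series_b_distances = c(1.6, 1.0, 0.8, 0.6, 0.4, 0.2, 0),
                                   n_infill = 23,
                                   plot_dims = c(35, 25),
                                   seed = NULL,
                                   max_retries = 1000) {
  if (n_nodes < 1) stop("'n_nodes' must be positive")
  if (n_infill < 0) stop("'n_infill' must be nonnegative")
  if (length(plot_dims) != 2 || any(plot_dims <= 0))
    stop("'plot_dims' must be two positive lengths (width, height)")
  steps <- c(series_a_distances, series_b_distances)
  if (any(steps < 0)) stop("series step distances must be nonnegative")
  if (any(steps > min(plot_dims)))
    stop("series step distances exceed the plot dimensions")
  .set_seed(seed)

  w <- plot_dims[1]; h <- plot_dims[2]
  nodes <- .node_grid(n_nodes, w, h)

  rows <- vector("list", n_nodes)
  for (k in seq_len(n_nodes)) {
    node_id <- sprintf("N%02d", k)
    out <- data.frame(point_id = node_id, x = nodes[k, 1], y = nodes[k, 2],
                      node_id = node_id, series_id = "node",
                      step_distance = NA_real_)
    for (ser in c("A", "B")) {
      dists <- if (ser == "A") series_a_distances else series_b_distances
      cur <- c(nodes[k, 1], nodes[k, 2])
      for (j in seq_along(dists)) {
        cur <- .step_point(cur, dists[j], w, h, max_retries)
        out <- rbind(out, data.frame(
          point_id = sprintf("%s%s%d", node_id, ser, j),
          x = cur[1], y = cur[2], node_id = node_id, series_id = ser,
          step_distance = dists[j]))
      }
    }
    rows[[k]] <- out
  }
  pts <- do.call(rbind, rows)

  if (n_infill > 0) {
    fill <- .infill_points(cbind(pts$x, pts$y), n_infill, w, h)
    pts <- rbind(pts, data.frame(
      point_id = sprintf("F%02d", seq_len(n_infill)),
      x = fill[, 1], y = fill[, 2], node_id = NA_character_,
      series_id = "infill", step_distance = NA_real_))
  }
  rownames(pts) <- pts$point_id
  attr(pts, "plot_dims") <- plot_dims
  class(pts) <- c("sample_points", "data.frame")
  pts
}

# Regular node grid: the factor pair nx * ny = n that best matches the plot
# aspect ratio; falls back to the next composite layout for awkward n.
.node_grid <- function(n, w, h) {
  best <- NULL; best_score <- Inf
  for (nx in seq_len(n)) {
    if (n %% nx != 0) next
    ny <- n / nx
    score <- abs(w / nx - h / ny)
    if (score < best_score) { best <- c(nx, ny); best_score <- score }
  }
  nx <- best[1]; ny <- best[2]
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  cbind((g$ix - 0.5) * w / nx, (g$iy - 0.5) * h / ny)[seq_len(n), , drop = FALSE]
}

# One random-direction step of length d from 'cur', redrawn until inside the
# plot. Directions are drawn to the nearest grade (400 per full circle).
.step_point <- function(cur, d, w, h, max_retries) {
  if (d == 0) return(cur)
  for (i in seq_len(max_retries)) {
    ang <- (sample.int(400L, 1L) - 1L) * pi / 200
    cand <- cur + d * c(cos(ang), sin(ang))
    if (cand[1] >= 0 && cand[1] <= w && cand[2] >= 0 && cand[2] <= h)
      return(cand)
  }
  stop("could not place a series point inside the plot after ",
       max_retries, " direction draws")
}

# Deterministic infill: each point sits at the centre of the largest empty
# circle, found by grid search at 0.5 m resolution (row-major tie-break).
.infill_points <- function(existing, n, w, h) {
  gx <- seq(0.25, w - 0.25, by = 0.5)
  gy <- seq(0.25, h - 0.25, by = 0.5)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  out <- matrix(NA_real_, n, 2)
  pts <- existing
  mind <- .min_dist_to(grid, pts)
  for (k in seq_len(n)) {
    i <- which.max(mind)
    out[k, ] <- grid[i, ]
    d2 <- (grid[, 1] - grid[i, 1])^2 + (grid[, 2] - grid[i, 2])^2
    mind <- pmin(mind, sqrt(d2))
  }
  out
}

.min_dist_to <- function(grid, pts) {
  d2 <- outer(grid[, 1], pts[, 1], "-")^2 + outer(grid[, 2], pts[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' @export
print.sample_points <- function(x, ...) {
  dims <- attr(x, "plot_dims")
  cat(sprintf("Nested sampling design: %d points in a %g x %g m plot\n",
              nrow(x), dims[1], dims[2]))
  print(table(series = x$series_id))
  invisible(x)
}

#' Remove lost samples and moisture outliers from a dataset
#'
#' Emulates sample attrition during processing: `n_lost` samples are removed
#' uniformly at random, then `n_outliers` further samples are removed as
#' soil-moisture outliers (the retained samples with the most extreme
#' moisture relative to the median; random if the dataset carries no
#' environment table). All tables of the dataset stay row-aligned.
#'
#' @param dataset a [marsh_dataset()] (or a bare `sample_points` table).
#' @param n_lost number of samples lost at random.
#' @param n_outliers number of additional samples flagged as moisture
#'   outliers.
#' @param seed optional integer seed.
#' @return The dataset with rows removed; attribute `"removed"` records the
#'   ids and the reason for each removal.
#' @export
apply_sample_loss <- function(dataset, n_lost = 40, n_outliers = 3, seed = NULL) {
  points_only <- inherits(dataset, "sample_points")
  pts <- if (points_only) dataset else dataset$points
  n <- nrow(pts)
  if (n_lost < 0 || n_outliers < 0) stop("removal counts must be nonnegative")
  if (n_lost + n_outliers >= n)
    stop(sprintf("cannot remove %d of %d samples", n_lost + n_outliers, n))
  .set_seed(seed)

  ids <- pts$point_id
  lost <- if (n_lost > 0) sample(ids, n_lost) else character(0)
  keep <- setdiff(ids, lost)

  env <- if (points_only) NULL else dataset$env
  if (n_outliers > 0) {
    if (!is.null(env) && "soil_moisture" %in% colnames(env)) {
      m <- env[keep, "soil_moisture"]
      dev <- abs(m - median(m))
      outl <- keep[order(dev, decreasing = TRUE)[seq_len(n_outliers)]]
    } else {
      outl <- sample(keep, n_outliers)
    }
    keep <- setdiff(keep, outl)
  } else outl <- character(0)

  removed <- data.frame(
    point_id = c(lost, outl),
    reason = rep(c("lost", "moisture_outlier"), c(length(lost), length(outl))))

  subset_pts <- pts[keep, , drop = FALSE]
  class(subset_pts) <- class(pts)
  attr(subset_pts, "plot_dims") <- attr(pts, "plot_dims")
  if (points_only) {
    attr(subset_pts, "removed") <- removed
    return(subset_pts)
  }
  out <- dataset
  out$points <- subset_pts
  if (!is.null(out$env)) out$env <- out$env[keep, , drop = FALSE]
  if (!is.null(out$abundance)) out$abundance <- out$abundance[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}
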