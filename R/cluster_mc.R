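# Nonparametric Monte Carlo estimation of the cluster-extent threshold
# controlling whole-volume family-wise error for voxelwise-thresholded
# z maps (smoothed Gaussian noise volumes, no volume mask).

#' Configuration of the cluster-threshold Monte Carlo simulation
#'
#' @param grid_dim Volume dimensions in voxels (length-3 integer).
#' @param voxel_size_mm Isotropic voxel edge length, mm.
#' @param fwhm_mm Gaussian smoothing kernel full width at half maximum,
#'   mm (>= 0; 0 disables smoothing).
#' @param voxel_p Uncorrected one-tailed voxel-level p threshold, in
#'   (0, 0.5).
#' @param n_iterations Monte Carlo iterations (>= 100).
#' @param fwe_alpha Target whole-volume family-wise error rate.
#' @param connectivity Voxel neighborhood: 6 (faces), 18 (faces + edges,
#'   default) or 26 (faces + edges + corners).
#' @param seed RNG seed.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(grid_dim = c(102L, 102L, 66L), voxel_size_mm = 2,
                      fwhm_mm = 8, voxel_p = 0.001,
                      n_iterations = 1000L, fwe_alpha = 0.05,
                      connectivity = 18L, seed = 1L) {
  stopifnot(length(grid_dim) == 3L, all(grid_dim >= 2L))
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0", call. = FALSE)
  if (voxel_p <= 0 || voxel_p >= 0.5)
    stop("`voxel_p` must be in (0, 0.5)", call. = FALSE)
  if (n_iterations < 100L)
    stop("`n_iterations` must be >= 100", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  if (fwe_alpha <= 0 || fwe_alpha >= 1)
    stop("`fwe_alpha` must be in (0, 1)", call. = FALSE)
  structure(list(grid_dim = as.integer(grid_dim),
                 voxel_size_mm = voxel_size_mm, fwhm_mm = fwhm_mm,
                 voxel_p = voxel_p, n_iterations = as.integer(n_iterations),
                 fwe_alpha = fwe_alpha,
                 connectivity = as.integer(connectivity),
                 seed = as.integer(seed)),
            class = "mc_config")
}

# 1-D smoothing matrix with rows scaled to unit L2 norm, so smoothing an
# i.i.d. standard normal volume leaves every voxel exactly unit variance
# (no edge-variance bias from kernel truncation).
.smooth_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  K <- outer(seq_len(n), seq_len(n),
             function(i, j) stats::dnorm(i - j, sd = sigma_vox))
  K / sqrt(rowSums(K^2))
}

# separable 3-D smoothing by axis-wise matrix products
.smooth_volume <- function(vol, sigma_vox) {
  d <- dim(vol)
  if (sigma_vox <= 0) return(vol)
  K1 <- .smooth_matrix(d[1L], sigma_vox)
  K2 <- .smooth_matrix(d[2L], sigma_vox)
  K3 <- .smooth_matrix(d[3L], sigma_vox)
  vol <- array(K1 %*% matrix(vol, d[1L]), d)
  vol <- aperm(array(K2 %*% matrix(aperm(vol, c(2L, 1L, 3L)), d[2L]),
                     d[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
  aperm(array(K3 %*% matrix(aperm(vol, c(3L, 1L, 2L)), d[3L]),
              d[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
}

#' Simulate one suprathreshold null volume
#'
#' Draws an i.i.d. standard normal volume on the configured grid,
#' smooths it with a separable Gaussian kernel (sigma = FWHM /
#' (2 sqrt(2 ln 2)) per axis, converted to voxel units), re-standardizes
#' the volume to zero mean and unit variance so the voxel threshold maps
#' to a fixed z cut, and thresholds one-tailed at
#' `qnorm(1 - voxel_p)`.
#'
#' @param config An [mc_config()]. The current RNG state is consumed.
#' @return A logical 3-D array marking suprathreshold voxels.
#' @export
simulate_null_volume <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  sigma_vox <- config$fwhm_mm / (2 * sqrt(2 * log(2))) /
    config$voxel_size_mm
  vol <- array(stats::rnorm(prod(config$grid_dim)), config$grid_dim)
  vol <- .smooth_volume(vol, sigma_vox)
  vol <- (vol - mean(vol)) / stats::sd(vol)
  vol > stats::qnorm(1 - config$voxel_p)
}

# neighbor offsets for a connectivity scheme (half-space only, so each
# undirected neighbor pair is generated once)
.conn_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  g <- g[ord <= switch(as.character(connectivity),
                       `6` = 1L, `18` = 2L, `26` = 3L), ]
  g[g$dz > 0 | (g$dz == 0 & (g$dy > 0 | (g$dy == 0 & g$dx > 0))), ]
}

#' Size of the largest connected suprathreshold cluster
#'
#' Connected components are computed on the graph whose vertices are the
#' suprathreshold voxels and whose edges join voxels that are neighbors
#' under the chosen connectivity (via [igraph::components()]).
#'
#' @param mask Logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return Largest cluster size in voxels (0 for an empty mask).
#' @export
max_cluster_size <- function(mask, connectivity = 18L) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(0L)
  coords <- arrayInd(idx, d)
  off <- .conn_offsets(connectivity)
  edges <- NULL
  for (r in seq_len(nrow(off))) {
    nx <- coords[, 1L] + off$dx[r]
    ny <- coords[, 2L] + off$dy[r]
    nz <- coords[, 3L] + off$dz[r]
    inside <- nx >= 1L & nx <= d[1L] & ny >= 1L & ny <= d[2L] &
      nz >= 1L & nz <= d[3L]
    nidx <- (nz[inside] - 1L) * d[1L] * d[2L] +
      (ny[inside] - 1L) * d[1L] + nx[inside]
    hit <- match(nidx, idx)
    found <- !is.na(hit)
    if (any(found))
      edges <- rbind(edges, cbind(which(inside)[found], hit[found]))
  }
  if (is.null(edges)) return(1L)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) -
                                     igraph::vcount(g)))
  max(igraph::components(g)$csize)
}

#' Estimate the cluster-extent threshold by Monte Carlo simulation
#'
#' Over `n_iterations` independent smoothed null volumes, records the
#' largest suprathreshold cluster of each iteration and returns the
#' smallest integer extent k whose exceedance probability
#' `P(max cluster >= k)` falls below `fwe_alpha`: clusters of at least k
#' voxels then control the whole-volume family-wise error at that level.
#'
#' @param config An [mc_config()].
#' @return An object of class `mc_threshold_result`: list with
#'   `extent_threshold`, `achieved_fwe`, `max_cluster_sizes` (the
#'   empirical distribution over iterations), and `config`.
#' @export
estimate_extent_threshold <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  set.seed(config$seed)
  maxes <- integer(config$n_iterations)
  for (i in seq_len(config$n_iterations))
    maxes[i] <- max_cluster_size(simulate_null_volume(config),
                                 config$connectivity)
  k <- 1L
  while (mean(maxes >= k) >= config$fwe_alpha) k <- k + 1L
  structure(list(extent_threshold = k,
                 achieved_fwe = mean(maxes >= k),
                 max_cluster_sizes = maxes,
                 config = config),
            class = "mc_threshold_result")
}

#' @export
print.mc_threshold_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Monte Carlo cluster-extent threshold: %d voxels\n",
                     "  grid %dx%dx%d @ %g mm, FWHM %g mm, voxel p %g, ",
                     "%d iterations\n",
                     "  achieved FWE %.3f (target %.2f), ",
                     "connectivity %d\n"),
              x$extent_threshold, cfg$grid_dim[1L], cfg$grid_dim[2L],
              cfg$grid_dim[3L], cfg$voxel_size_mm, cfg$fwhm_mm,
              cfg$voxel_p, cfg$n_iterations, x$achieved_fwe,
              cfg$fwe_alpha, cfg$connectivity))
  invisible(x)
}
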