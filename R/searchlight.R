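# Whole-volume information mapping: sliding-sphere decoding plus group
# cluster inference by sign-flip max-cluster-size permutation.

#' Integer offsets of a spherical searchlight
#'
#' All integer lattice displacements with Euclidean norm at most
#' `radius_voxels`; always contains (0,0,0) and is symmetric under
#' negation. Radius 3 yields 123 offsets.
#'
#' @param radius_voxels sphere radius in voxels (default 3).
#' @return integer matrix, one offset per row (columns dx, dy, dz).
#' @export
sphere_offsets <- function(radius_voxels = 3) {
  if (radius_voxels < 0) stop("radius must be non-negative")
  r <- floor(radius_voxels)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[rowSums(g^2) <= radius_voxels^2, , drop = FALSE]
}

#' Searchlight decoding accuracy map for one bin
#'
#' For every in-mask center voxel, runs leave-one-run-out decoding on the
#' beta patterns restricted to the sphere around it (clipped to the volume
#' and the mask) and stores the accuracy at the center.
#'
#' @param bs a `beta_series` whose voxel axis covers the full grid.
#' @param mask 3-D logical array of voxels to evaluate (and to restrict
#'   sphere neighbourhoods to).
#' @param bin FIR bin index to decode.
#' @param sphere offsets from [sphere_offsets()].
#' @param cost SVM regularization constant.
#' @return 3-D accuracy array (percent), `NA` outside the mask.
#' @export
searchlight_map <- function(bs, mask, bin, sphere = sphere_offsets(3),
                            cost = svm_cost_default) {
  dims <- dim(mask)
  stopifnot(prod(dims) == dim(bs$runs[[1]]$betas)[3])
  samples <- beta_samples_for_bin(bs, bin)
  centers <- which(mask, arr.ind = TRUE)
  out <- array(NA_real_, dims)
  for (i in seq_len(nrow(centers))) {
    pos <- sweep(sphere, 2, centers[i, ], `+`)
    ok <- pos[, 1] >= 1 & pos[, 1] <= dims[1] &
      pos[, 2] >= 1 & pos[, 2] <= dims[2] &
      pos[, 3] >= 1 & pos[, 3] <= dims[3]
    pos <- pos[ok, , drop = FALSE]
    vox <- pos[, 1] + (pos[, 2] - 1) * dims[1] +
      (pos[, 3] - 1) * dims[1] * dims[2]
    vox <- vox[mask[vox]]
    if (length(vox) == 0) next
    sub <- lapply(samples, function(s)
      list(x = s$x[, vox, drop = FALSE], y = s$y))
    out[centers[i, 1], centers[i, 2], centers[i, 3]] <-
      loro_decode(sub, cost)
  }
  out
}

#' Gaussian smoothing of an accuracy volume
#'
#' Separable Gaussian kernel with sigma = fwhm / (2 sqrt(2 ln 2)) per
#' axis, truncated at 4 sigma. Missing voxels are excluded by
#' renormalizing the kernel mass over observed neighbours, so masked maps
#' are not diluted towards the mask edge.
#'
#' @param vol 3-D array, `NA` outside the mask.
#' @param fwhm_mm full width at half maximum in mm (0 = identity).
#' @param voxel_size_mm isotropic voxel size (default 3).
#' @return smoothed array, `NA` pattern preserved.
#' @export
gaussian_smooth_volume <- function(vol, fwhm_mm, voxel_size_mm = 3) {
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  obs <- !is.na(vol)
  v <- vol
  v[!obs] <- 0
  smooth_axis <- function(a, axis) {
    out <- array(0, dim(a))
    for (j in -r:r) {
      shifted <- shift_array(a, j, axis)
      out <- out + k[j + r + 1] * shifted
    }
    out
  }
  num <- v
  den <- array(as.numeric(obs), dim(vol))
  for (ax in 1:3) {
    num <- smooth_axis(num, ax)
    den <- smooth_axis(den, ax)
  }
  res <- num / den
  res[!obs] <- NA
  res
}

# Shift a 3-D array by j along one axis, zero-padding.
shift_array <- function(a, j, axis) {
  d <- dim(a)
  out <- array(0, d)
  if (abs(j) >= d[axis]) return(out)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  n <- d[axis]
  if (j >= 0) { src[[axis]] <- 1:(n - j); dst[[axis]] <- (1 + j):n }
  else { src[[axis]] <- (1 - j):n; dst[[axis]] <- 1:(n + j) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Connected components of a logical 3-D array under 26-connectivity
# (corner-touching voxels join). Returns an integer label array.
label_components_26 <- function(mask3d) {
  d <- dim(mask3d)
  lab <- array(0L, d)
  idx <- which(mask3d)
  if (length(idx) == 0) return(lab)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  cur <- 0L
  coords <- arrayInd(idx, d)
  keyed <- new.env(hash = TRUE)
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = keyed)
  for (i in seq_along(idx)) {
    if (lab[idx[i]] != 0L) next
    cur <- cur + 1L
    queue <- idx[i]
    lab[idx[i]] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      p <- arrayInd(v, d)
      for (nrow_i in seq_len(nrow(nb))) {
        q <- p + nb[nrow_i, ]
        if (any(q < 1) || any(q > d)) next
        vi <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (mask3d[vi] && lab[vi] == 0L) {
          lab[vi] <- cur
          queue <- c(queue, vi)
        }
      }
    }
  }
  lab
}

#' Group cluster inference on accuracy maps
#'
#' Voxel-wise one-tailed one-sample t-test of accuracy against 50 percent
#' across subjects; suprathreshold voxels (voxel-level p < `voxel_p`) are
#' grouped by 26-connectivity and cluster extents are tested against the
#' max-cluster-size null distribution obtained by randomly sign-flipping
#' each subject's (map - 50) around chance, the standard permutation
#' scheme for one-sample designs.
#'
#' @param maps list of per-subject 3-D accuracy arrays on a common grid.
#' @param voxel_p primary voxel-level threshold (default 0.001).
#' @param cluster_p cluster-level threshold (default 0.05).
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param seed RNG seed.
#' @return list with `clusters` (data.frame id, n_voxels, peak_accuracy,
#'   peak_x/y/z, p), `thresholded` (map of surviving clusters, NA
#'   elsewhere), `t_map` and `null_max_size`.
#' @export
cluster_threshold_group <- function(maps, voxel_p = 0.001,
                                    cluster_p = 0.05, n_perm = 1000,
                                    seed = NULL) {
  if (length(maps) < 6) stop("need at least 6 subjects")
  if (n_perm < 100) stop("n_perm < 100 gives an unstable null tail")
  d <- dim(maps[[1]])
  stopifnot(all(vapply(maps, function(m) identical(dim(m), d), TRUE)))
  n <- length(maps)
  stack <- vapply(maps, function(m) as.numeric(m) - 50,
                  numeric(prod(d)))  # voxels x subjects
  inside <- rowSums(is.na(stack)) == 0
  tthr <- qt(1 - voxel_p, df = n - 1)
  tmap_of <- function(x) {
    mu <- rowMeans(x)
    s <- sqrt(rowSums((x - mu)^2) / (n - 1))
    tv <- mu / (s / sqrt(n))
    tv[s == 0] <- ifelse(mu[s == 0] > 0, Inf, ifelse(mu[s == 0] < 0, -Inf, 0))
    tv
  }
  supra_sizes <- function(tv) {
    m <- array(FALSE, d)
    m[inside] <- tv[inside] > tthr
    lab <- label_components_26(m)
    if (max(lab) == 0) return(list(lab = lab, sizes = integer(0)))
    list(lab = lab, sizes = tabulate(lab[lab > 0]))
  }
  obs_t <- tmap_of(stack)
  obs <- supra_sizes(obs_t)
  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    sz <- supra_sizes(tmap_of(sweep(stack, 2, flips, `*`)))$sizes
    if (length(sz) == 0) 0L else max(sz)
  }, integer(1)))
  n_clu <- length(obs$sizes)
  clusters <- data.frame(id = integer(0), n_voxels = integer(0),
                         peak_accuracy = numeric(0), peak_x = integer(0),
                         peak_y = integer(0), peak_z = integer(0),
                         p = numeric(0))
  mean_map <- array(rowMeans(stack) + 50, d)
  thresholded <- array(NA_real_, d)
  for (ci in seq_len(n_clu)) {
    vox <- which(obs$lab == ci)
    pk <- vox[which.max(mean_map[vox])]
    pkc <- arrayInd(pk, d)
    p <- (1 + sum(null_max >= obs$sizes[ci])) / (1 + n_perm)
    clusters <- rbind(clusters, data.frame(
      id = ci, n_voxels = obs$sizes[ci], peak_accuracy = mean_map[pk],
      peak_x = pkc[1], peak_y = pkc[2], peak_z = pkc[3], p = p))
    if (p < cluster_p) thresholded[vox] <- mean_map[vox]
  }
  tm <- array(NA_real_, d)
  tm[inside] <- obs_t[inside]
  list(clusters = clusters, thresholded = thresholded, t_map = tm,
       null_max_size = null_max)
}
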