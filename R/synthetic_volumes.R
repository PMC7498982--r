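# Synthetic labeled volumes ---------------------------------------------
#
# Small block-world volumes with known regional values and planted lesions,
# so the voxel-level extraction (erosion, FA thresholding, lesion
# exclusion) can be checked against ground truth computed by the generator
# itself via direct voxel enumeration. No attempt at realistic anatomy:
# axis-aligned blocks suffice to exercise every masking rule.

#' A rectangular block of voxels for one region
#'
#' @param lo,hi Inclusive 1-based voxel index bounds, length 3.
#' @return List with `lo` and `hi` integer vectors.
#' @export
region_block <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(hi < lo))
    stop_invariant("region_block needs lo <= hi, each length 3")
  list(lo = lo, hi = hi)
}

default_region_layout <- function() {
  list(FT = region_block(c(2, 2, 2), c(8, 8, 8)),
       PO = region_block(c(10, 2, 2), c(16, 8, 8)),
       CC = region_block(c(18, 2, 2), c(23, 8, 8)),
       BS = region_block(c(2, 10, 2), c(8, 16, 8)),
       BT = region_block(c(10, 10, 2), c(16, 16, 8)))
}

default_region_values <- function() {
  list(FA = c(FT = 0.45, PO = 0.46, CC = 0.58, BS = 0.52, BT = 0.33),
       MD = c(FT = 7.6e-4, PO = 7.5e-4, CC = 7.2e-4, BS = 7.4e-4, BT = 8.0e-4))
}

#' A spherical lesion planted in the metric volumes
#'
#' @param center Voxel coordinates (1-based), length 3.
#' @param radius Radius in voxel units (Euclidean in index space).
#' @param values Named vector of metric values painted inside the sphere
#'   (e.g. `c(FA = 0.35, MD = 1.2e-3)`); metrics not named keep their
#'   regional value. The default FA of 0.35 passes the usual 0.3 threshold,
#'   so removing these voxels is genuinely the job of the exclusion mask.
#' @return List of class `lesion_sphere`.
#' @export
lesion_sphere <- function(center, radius, values = c(FA = 0.35, MD = 1.2e-3)) {
  if (length(center) != 3L || radius <= 0)
    stop_invariant("lesion_sphere needs a length-3 center and positive radius")
  structure(list(center = as.numeric(center), radius = radius,
                 values = values), class = "lesion_sphere")
}

#' Configuration of a synthetic volume set
#'
#' @param grid_shape Voxels per axis, length 3.
#' @param voxel_size mm per voxel, length 3 (anisotropic allowed).
#' @param region_layout Named list of [region_block()]s, one per region in
#'   [pta_regions()]; blocks must be pairwise disjoint, lie inside the
#'   grid, and measure at least 3 voxels per axis (so each survives
#'   1-voxel erosion with at least one voxel).
#' @param region_values Named list of per-region value vectors, one per
#'   metric (defaults: FA and MD levels typical of the five regions).
#' @param value_noise_sd Voxelwise Gaussian noise SD added to each metric,
#'   either a single number or named per metric.
#' @param lesion_spheres List of [lesion_sphere()]s; all must lie fully
#'   inside the grid.
#' @param seed Integer seed (needed when `value_noise_sd > 0`).
#' @return List of class `volume_config`.
#' @export
volume_config <- function(grid_shape = c(24, 24, 12),
                          voxel_size = c(2.3, 2.3, 2.3),
                          region_layout = default_region_layout(),
                          region_values = default_region_values(),
                          value_noise_sd = 0,
                          lesion_spheres = list(),
                          seed = NULL) {
  regions <- pta_regions()
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 3L))
    stop_invariant("grid_shape must be 3 integers >= 3")
  if (!identical(sort(names(region_layout)), sort(regions)))
    stop_invariant("region_layout must name all five regions")
  region_layout <- region_layout[regions]
  occupied <- array(FALSE, grid_shape)
  for (r in regions) {
    b <- region_layout[[r]]
    if (any(b$lo < 1L) || any(b$hi > grid_shape))
      stop_invariant("region block ", r, " extends outside the grid")
    if (any(b$hi - b$lo + 1L < 3L))
      stop_invariant("region block ", r,
                     " must span >= 3 voxels per axis to survive erosion")
    sl <- occupied[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]]
    if (any(sl))
      stop_invariant("region blocks overlap at region ", r)
    occupied[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <- TRUE
  }
  for (m in names(region_values))
    region_values[[m]] <- check_region_vector(region_values[[m]],
                                              paste0("region_values$", m))
  for (s in lesion_spheres) {
    if (!inherits(s, "lesion_sphere"))
      stop_invariant("lesion_spheres must be lesion_sphere objects")
    if (any(s$center - s$radius < 1) || any(s$center + s$radius > grid_shape))
      stop_invariant("lesion sphere at (",
                     paste(s$center, collapse = ","),
                     ") extends outside the grid")
  }
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 region_layout = region_layout,
                 region_values = region_values,
                 value_noise_sd = value_noise_sd,
                 lesion_spheres = lesion_spheres,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "volume_config")
}

# brute-force 26-neighbourhood erosion by direct per-voxel scan; kept
# deliberately independent of erode_mask() so the generator can serve as an
# oracle for it
brute_erode <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    if (any(v == 1L) || any(v == d)) next
    nb <- mask[(v[1] - 1L):(v[1] + 1L), (v[2] - 1L):(v[2] + 1L),
               (v[3] - 1L):(v[3] + 1L)]
    if (all(nb)) out[v[1], v[2], v[3]] <- TRUE
  }
  out
}

sphere_mask <- function(grid_shape, center, radius) {
  ax <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - center[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  d2 <= radius^2
}

#' Generate a synthetic volume set with enumerated ground truth
#'
#' Paints each region block with its metric value (plus optional voxel
#' noise), paints lesion spheres into the metric volumes and records them
#' in the exclusion mask, then computes -- by direct enumeration over the
#' voxels it painted, independently of the extraction code -- the true
#' regional means before and after lesion exclusion under the stated
#' processing rules (26-neighbourhood erosion; strict FA threshold for the
#' white-matter regions FT, PO, CC, BS; no threshold for BT).
#'
#' @param config A [volume_config()].
#' @param fa_threshold FA threshold used for the ground-truth means of the
#'   white-matter regions (default 0.3, strict).
#' @return List with `volumes` (a [volume_set()]) and `truth`, a data frame
#'   with one row per region and metric: `mean_pre`/`n_pre` before and
#'   `mean_post`/`n_post` after lesion exclusion.
#' @export
#' @examples
#' vs <- generate_volume_set(volume_config(
#'   lesion_spheres = list(lesion_sphere(c(5, 5, 5), 2))))
#' subset(vs$truth, metric == "FA")
generate_volume_set <- function(config, fa_threshold = 0.3) {
  if (!inherits(config, "volume_config"))
    stop_invariant("config must be created with volume_config()")
  gs <- config$grid_shape
  regions <- pta_regions()
  if (config$value_noise_sd > 0 || length(config$value_noise_sd) > 1) {
    if (is.null(config$seed))
      stop_invariant("config$seed is required when value_noise_sd > 0")
    set.seed(config$seed)
  }

  label <- array(0L, gs)
  for (i in seq_along(regions)) {
    b <- config$region_layout[[regions[i]]]
    label[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]] <- i
  }

  noise_sd <- config$value_noise_sd
  if (length(noise_sd) == 1L && is.null(names(noise_sd)))
    noise_sd <- setNames(rep(noise_sd, length(config$region_values)),
                         names(config$region_values))
  metrics <- lapply(names(config$region_values), function(m) {
    vol <- array(0, gs)
    for (i in seq_along(regions)) {
      in_r <- label == i
      vol[in_r] <- config$region_values[[m]][[regions[i]]]
    }
    sdm <- noise_sd[[m]] %||% 0
    if (sdm > 0) vol[label > 0L] <- vol[label > 0L] +
        rnorm(sum(label > 0L), sd = sdm)
    vol
  })
  names(metrics) <- names(config$region_values)

  exclusion <- array(FALSE, gs)
  for (s in config$lesion_spheres) {
    sm <- sphere_mask(gs, s$center, s$radius)
    exclusion <- exclusion | sm
    for (m in names(s$values))
      if (m %in% names(metrics)) metrics[[m]][sm] <- s$values[[m]]
  }

  # ground truth by direct enumeration
  truth <- list()
  fa <- metrics[["FA"]]
  for (i in seq_along(regions)) {
    r <- regions[i]
    base <- brute_erode(label == i)
    if (r %in% wm_regions()) {
      if (is.null(fa))
        stop_invariant("FA volume required for white-matter region truth")
      base <- base & (fa > fa_threshold)
    }
    post <- base & !exclusion
    for (m in names(metrics)) {
      vpre <- metrics[[m]][base]
      vpost <- metrics[[m]][post]
      truth[[length(truth) + 1L]] <- data.frame(
        region = r, metric = m,
        mean_pre = if (length(vpre)) mean(vpre) else NA_real_,
        n_pre = length(vpre),
        mean_post = if (length(vpost)) mean(vpost) else NA_real_,
        n_post = length(vpost), stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)

  list(volumes = volume_set(label = label, metrics = metrics,
                            exclusion = exclusion,
                            voxel_size = config$voxel_size),
       truth = truth)
}

#' Write a volume set as NIfTI-1 files
#'
#' Writes `labels.nii.gz`, one `<metric>.nii.gz` per metric volume, and
#' `exclusion.nii.gz` into `dir`.
#'
#' @param vs A [volume_set()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_volume_set <- function(vs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti(vs$label, file.path(dir, "labels.nii.gz"),
              voxel_size = vs$voxel_size)
  for (m in names(vs$metrics))
    write_nifti(vs$metrics[[m]], file.path(dir, paste0(m, ".nii.gz")),
                voxel_size = vs$voxel_size)
  write_nifti(vs$exclusion, file.path(dir, "exclusion.nii.gz"),
              voxel_size = vs$voxel_size)
  invisible(dir)
}

#' Read a volume set from NIfTI-1 files written by [write_volume_set()]
#'
#' @param dir Directory holding `labels.nii.gz`, metric volumes and
#'   optionally `exclusion.nii.gz`.
#' @param metrics Metric volume names to read (default `FA`, `MD`).
#' @return A [volume_set()].
#' @export
read_volume_set <- function(dir, metrics = c("FA", "MD")) {
  find1 <- function(stem) {
    for (ext in c(".nii.gz", ".nii")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
    NULL
  }
  lab_path <- find1("labels")
  if (is.null(lab_path)) stop_invariant("no labels volume found in ", dir)
  label <- read_nifti(lab_path)
  vox <- attr(label, "voxel_size")
  mets <- list()
  for (m in metrics) {
    p <- find1(m)
    if (!is.null(p)) mets[[m]] <- read_nifti(p)
  }
  exc_path <- find1("exclusion")
  exclusion <- if (is.null(exc_path)) NULL else read_nifti(exc_path) > 0
  volume_set(label = array(as.integer(round(label)), dim(label)),
             metrics = mets, exclusion = exclusion, voxel_size = vox)
}
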