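# Regional metric extraction --------------------------------------------
#
# Turns co-registered label / metric / exclusion-mask volumes into the
# five-region mean-metric table. Processing per region: erode the label
# mask by one voxel in all dimensions (26-neighbourhood), apply the strict
# FA threshold to the four white-matter regions (BT, grey matter, is
# exempt), then remove lesion/microbleed voxels via the exclusion mask to
# obtain normal-appearing tissue. Means ignore non-finite metric voxels.

#' Bundle co-registered volumes for extraction
#'
#' @param label Integer 3-D array; 0 = background, 1..5 = the regions in
#'   [pta_regions()] order (FT, PO, CC, BS, BT).
#' @param metrics Named list of numeric 3-D arrays on the same grid. An
#'   `FA` entry, when present, must lie in \[0, 1\] wherever finite.
#' @param exclusion Optional logical 3-D array; `TRUE` marks lesion or
#'   microbleed voxels to exclude. `NULL` means nothing is excluded.
#' @param voxel_size mm per voxel along each axis (used for physical
#'   distances in [assign_wm_to_nearest_label()]).
#' @return List of class `volume_set`.
#' @export
volume_set <- function(label, metrics, exclusion = NULL,
                       voxel_size = c(1, 1, 1)) {
  if (length(dim(label)) != 3L)
    stop_invariant("label must be a 3-D array")
  if (!all(unique(as.vector(label)) %in% 0:5))
    stop_invariant("label values must be 0 (background) or 1..5 (FT,PO,CC,BS,BT)")
  if (!length(metrics) || is.null(names(metrics)))
    stop_invariant("metrics must be a named list of arrays")
  for (m in names(metrics)) {
    if (!identical(dim(metrics[[m]]), dim(label)))
      stop_invariant("metric volume ", m, " does not match the label grid")
  }
  if ("FA" %in% names(metrics)) {
    fa <- metrics[["FA"]]
    fin <- fa[is.finite(fa)]
    if (length(fin) && (min(fin) < 0 || max(fin) > 1))
      stop_invariant("finite FA values must lie in [0, 1]")
  }
  if (!is.null(exclusion)) {
    if (!identical(dim(exclusion), dim(label)))
      stop_invariant("exclusion mask does not match the label grid")
    exclusion <- exclusion & TRUE  # coerce to logical
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_invariant("voxel_size must be 3 positive numbers")
  structure(list(label = label, metrics = metrics, exclusion = exclusion,
                 voxel_size = as.numeric(voxel_size)),
            class = "volume_set")
}

# shift a 3-D logical array by (dx,dy,dz), padding with FALSE
shift3d <- function(mask, dx, dy, dz) {
  d <- dim(mask)
  out <- array(FALSE, d)
  sx <- max(1L, 1L + dx):min(d[1], d[1] + dx)
  sy <- max(1L, 1L + dy):min(d[2], d[2] + dy)
  sz <- max(1L, 1L + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- mask[sx - dx, sy - dy, sz - dz]
  out
}

#' Erode a binary mask by one voxel in all dimensions
#'
#' A voxel survives iff its complete 3x3x3 (26-connected) neighbourhood is
#' inside the mask; voxels on the grid border never survive.
#'
#' @param mask Logical 3-D array.
#' @return Logical 3-D array.
#' @export
erode_mask <- function(mask) {
  if (length(dim(mask)) != 3L || !is.logical(mask))
    stop_invariant("erode_mask() expects a logical 3-D array")
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0L && dy == 0L && dz == 0L) next
    out <- out & shift3d(mask, dx, dy, dz)
  }
  # border voxels are treated as having neighbours outside the mask
  d <- dim(out)
  out[c(1L, d[1]), , ] <- FALSE
  out[, c(1L, d[2]), ] <- FALSE
  out[, , c(1L, d[3])] <- FALSE
  out
}

#' Assign white-matter voxels to the nearest cortical label
#'
#' Every voxel of `wm_mask` receives the label of the Euclidean-nearest
#' labeled voxel of `cortical_labels`, with distances measured in physical
#' mm via `voxel_size` (anisotropic voxels supported). Exact distance ties
#' go to the lowest label id. Voxels outside the white-matter mask keep
#' their `cortical_labels` value.
#'
#' @param wm_mask Logical 3-D array of white-matter voxels to assign.
#' @param cortical_labels Integer 3-D array; 0 = unlabeled.
#' @param voxel_size mm per voxel, length 3.
#' @return Integer 3-D array.
#' @export
assign_wm_to_nearest_label <- function(wm_mask, cortical_labels,
                                       voxel_size = c(1, 1, 1)) {
  if (!identical(dim(wm_mask), dim(cortical_labels)))
    stop_invariant("wm_mask and cortical_labels must share a grid")
  lab_idx <- which(cortical_labels > 0L)
  if (!length(lab_idx))
    stop_invariant("no labeled voxel present in cortical_labels")
  out <- cortical_labels
  wm_idx <- which(wm_mask)
  if (!length(wm_idx)) return(out)

  d <- dim(wm_mask)
  coords <- function(idx) {
    i <- idx - 1L
    x <- i %% d[1]
    y <- (i %/% d[1]) %% d[2]
    z <- i %/% (d[1] * d[2])
    cbind(x, y, z)
  }
  lab_xyz <- sweep(coords(lab_idx), 2L, voxel_size, `*`)
  labs <- as.integer(cortical_labels[lab_idx])
  # sort candidates by label id so that among equidistant voxels the first
  # (lowest-id) hit wins
  ord <- order(labs)
  lab_xyz <- lab_xyz[ord, , drop = FALSE]
  labs <- labs[ord]

  wm_xyz <- sweep(coords(wm_idx), 2L, voxel_size, `*`)
  chunk <- max(1L, floor(2e6 / length(lab_idx)))
  assigned <- integer(length(wm_idx))
  lab_sq <- rowSums(lab_xyz^2)
  for (start in seq(1L, length(wm_idx), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(wm_idx))
    w <- wm_xyz[sel, , drop = FALSE]
    cross <- lab_xyz %*% t(w)                               # n_lab x n_sel
    d2 <- outer(lab_sq, rowSums(w^2), `+`) - 2 * cross      # squared distance
    best <- apply(d2, 2L, function(col) {
      m <- min(col)
      which(col <= m + 1e-9 * max(1, abs(m)))[1L]  # first = lowest label id
    })
    assigned[sel] <- labs[best]
  }
  out[wm_idx] <- assigned
  out
}

#' Build the per-region analysis masks
#'
#' For FT, PO, CC and BS: the eroded label mask, restricted to voxels with
#' `FA > fa_threshold` (strict), minus exclusion-mask voxels. For BT: the
#' eroded label mask minus exclusion voxels, with no FA condition.
#'
#' @param volumes A [volume_set()].
#' @param fa_threshold Strict FA threshold for the white-matter regions.
#' @param erode Apply the 1-voxel erosion first (default `TRUE`).
#' @return Named list of logical arrays, one per region; regions left with
#'   no voxels carry attribute `empty = TRUE`.
#' @export
build_region_masks <- function(volumes, fa_threshold = 0.3, erode = TRUE) {
  if (!inherits(volumes, "volume_set"))
    stop_invariant("volumes must be a volume_set")
  regions <- pta_regions()
  fa <- volumes$metrics[["FA"]]
  if (is.null(fa) && any(wm_regions() %in% regions))
    stop_invariant("an FA volume is required to threshold the white-matter regions")
  masks <- list()
  for (i in seq_along(regions)) {
    r <- regions[i]
    m <- volumes$label == i
    if (erode) m <- erode_mask(m)
    if (r %in% wm_regions()) m <- m & !is.na(fa) & (fa > fa_threshold)
    if (!is.null(volumes$exclusion)) m <- m & !volumes$exclusion
    if (!any(m)) attr(m, "empty") <- TRUE
    masks[[r]] <- m
  }
  masks
}

#' Extract the regional mean-metric table from volumes
#'
#' Arithmetic mean of each requested metric over the region masks of
#' [build_region_masks()]; non-finite metric voxels are dropped from both
#' the mean and the reported voxel count. A region with no usable voxels
#' raises an error naming the region (means are never silently zero).
#'
#' @param volumes A [volume_set()].
#' @param metrics Metric names to extract (default: all present).
#' @param subject Subject id recorded in the table.
#' @param fa_threshold,erode Passed to [build_region_masks()].
#' @return Data frame with columns `subject`, `region`, `metric`, `mean`,
#'   `n_voxels`; exactly 5 region rows per metric.
#' @export
#' @examples
#' vs <- generate_volume_set(volume_config())
#' extract_regional_metrics(vs$volumes, subject = "P01")
extract_regional_metrics <- function(volumes, metrics = names(volumes$metrics),
                                     subject = "s1", fa_threshold = 0.3,
                                     erode = TRUE) {
  masks <- build_region_masks(volumes, fa_threshold = fa_threshold,
                              erode = erode)
  out <- list()
  for (r in names(masks)) {
    if (isTRUE(attr(masks[[r]], "empty")))
      stop_invariant("region ", r, " is empty after masking; refusing to average")
    for (m in metrics) {
      vol <- volumes$metrics[[m]]
      if (is.null(vol))
        stop_invariant("requested metric ", m, " is not present in the volume set")
      v <- vol[masks[[r]]]
      v <- v[is.finite(v)]
      if (!length(v))
        stop_invariant("region ", r, " has no finite ", m,
                       " voxels; refusing to average")
      out[[length(out) + 1L]] <- data.frame(
        subject = subject, region = r, metric = m,
        mean = mean(v), n_voxels = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a regional-metric table as CSV
#'
#' @param table Data frame from [extract_regional_metrics()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_regional_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
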