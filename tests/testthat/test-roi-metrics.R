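test_that("erosion keeps exactly the voxels whose full 26-neighbourhood is inside", {
  cube <- array(FALSE, c(5, 5, 5))
  cube[2:4, 2:4, 2:4] <- TRUE
  er <- erode_mask(cube)
  expect_identical(which(er), which(array(seq_len(125), c(5, 5, 5)) == 63))

  empty <- array(FALSE, c(4, 4, 4))
  expect_identical(erode_mask(empty), empty)

  set.seed(8)
  for (rep in 1:5) {
    m <- array(runif(8^3) > 0.3, c(8, 8, 8))
    expect_identical(erode_mask(m), oracle_erode(m))
  }
})

test_that("white-matter voxels go to the nearest cortical label in physical distance", {
  d <- c(5, 5, 5)
  labels <- array(0L, d)
  labels[1, 1, 1] <- 1L
  labels[5, 5, 5] <- 2L
  wm <- array(TRUE, d); wm[labels > 0] <- FALSE

  out <- assign_wm_to_nearest_label(wm, labels, c(1, 1, 1))
  expect_identical(out, oracle_nearest(wm, labels, c(1, 1, 1)))

  # anisotropic voxels change the assignment and must match brute force
  vox <- c(1, 1, 3)
  out2 <- assign_wm_to_nearest_label(wm, labels, vox)
  expect_identical(out2, oracle_nearest(wm, labels, vox))
  expect_false(identical(out, out2))

  # a single label claims everything
  labels1 <- array(0L, d); labels1[3, 3, 3] <- 4L
  wm1 <- array(TRUE, d); wm1[3, 3, 3] <- FALSE
  out3 <- assign_wm_to_nearest_label(wm1, labels1, c(1, 1, 1))
  expect_true(all(out3[wm1] == 4L))

  expect_error(assign_wm_to_nearest_label(wm, array(0L, d)), "no labeled voxel")
})

test_that("exact distance ties resolve to the lowest label id", {
  d <- c(3, 3, 3)
  labels <- array(0L, d)
  labels[1, 2, 2] <- 2L
  labels[3, 2, 2] <- 1L
  wm <- array(FALSE, d); wm[2, 2, 2] <- TRUE   # equidistant to both
  out <- assign_wm_to_nearest_label(wm, labels, c(1, 1, 1))
  expect_identical(out[2, 2, 2], 1L)
})

test_that("region masks apply erosion, strict FA threshold and exclusion in order", {
  vs <- generate_volume_set(volume_config())$volumes

  # FA well above threshold everywhere relevant: WM masks = eroded labels
  masks <- build_region_masks(vs)
  for (i in 1:4)
    expect_identical(unname(which(masks[[i]])),
                     which(oracle_erode(vs$label == i)))

  # FA exactly at the threshold: strict inequality empties the WM regions
  vs2 <- vs
  vs2$metrics$FA[] <- 0.3
  masks2 <- build_region_masks(vs2)
  for (r in c("FT", "PO", "CC", "BS")) {
    expect_true(isTRUE(attr(masks2[[r]], "empty")))
    expect_identical(sum(masks2[[r]]), 0L)
  }
  expect_gt(sum(masks2$BT), 0)  # grey matter is exempt from the threshold
  expect_error(extract_regional_metrics(vs2, subject = "s"), "FT")

  # a lesion sphere in CC removes exactly its voxels from the CC mask
  sph <- lesion_sphere(c(20, 5, 5), 2, values = c(FA = 0.4, MD = 1e-3))
  wl <- generate_volume_set(volume_config(lesion_spheres = list(sph)))$volumes
  masks3 <- build_region_masks(wl)
  ref <- oracle_erode(wl$label == 3L) & (wl$metrics$FA > 0.3) & !wl$exclusion
  expect_identical(unname(which(masks3$CC)), which(ref))
})

test_that("masks are nested and exclusion growth never adds voxels", {
  sph <- lesion_sphere(c(5, 5, 5), 2)
  vs <- generate_volume_set(volume_config(value_noise_sd = 0.02, seed = 6,
                                          lesion_spheres = list(sph)))$volumes
  vs$metrics$FA <- pmin(pmax(vs$metrics$FA, 0), 1)
  masks <- build_region_masks(vs)
  for (i in seq_along(masks)) {
    lab <- vs$label == i
    er <- erode_mask(lab)
    expect_true(all(which(masks[[i]]) %in% which(er)))
    expect_true(all(which(er) %in% which(lab)))
  }
  # enlarging the exclusion mask never increases any region's voxel count
  set.seed(31)
  bigger <- vs
  bigger$exclusion <- vs$exclusion | (array(runif(length(vs$label)),
                                            dim(vs$label)) < 0.2)
  masks_big <- build_region_masks(bigger)
  for (r in names(masks)) {
    expect_lte(sum(masks_big[[r]]), sum(masks[[r]]))
    expect_true(all(which(masks_big[[r]]) %in% which(masks[[r]])))
  }
})

test_that("regional means drop non-finite voxels and are padding-invariant", {
  vs <- generate_volume_set(volume_config())$volumes
  tab <- extract_regional_metrics(vs, subject = "s")

  # poison two FT voxels: mean unchanged if computed over finite voxels only
  idx <- which(build_region_masks(vs)$FT)[1:2]
  vs2 <- vs
  vs2$metrics$MD[idx] <- c(NaN, Inf)
  tab2 <- extract_regional_metrics(vs2, subject = "s")
  ft_md <- tab$metric == "MD" & tab$region == "FT"
  expect_identical(tab2$n_voxels[ft_md], tab$n_voxels[ft_md] - 2L)
  expect_equal(tab2$mean[ft_md], tab$mean[ft_md], tolerance = 1e-12)

  # padding the grid with background changes nothing
  pad <- function(a, fill) {
    out <- array(fill, dim(a) + 2L)
    out[2:(dim(a)[1] + 1), 2:(dim(a)[2] + 1), 2:(dim(a)[3] + 1)] <- a
    out
  }
  vs3 <- volume_set(label = pad(vs$label, 0L),
                    metrics = lapply(vs$metrics, pad, fill = 0),
                    exclusion = NULL, voxel_size = vs$voxel_size)
  tab3 <- extract_regional_metrics(vs3, subject = "s")
  expect_equal(tab3$mean, tab$mean)
  expect_identical(tab3$n_voxels, tab$n_voxels)
})

test_that("a three-voxel unthresholded region averages by hand", {
  d <- c(9, 5, 5)
  label <- array(0L, d)
  label[2:4, 2:4, 2:4] <- 1L   # FT placeholder so WM thresholding has FA
  label[6:8, 2:4, 2:4] <- 2L
  fa <- array(0.5, d)
  md <- array(0, d)
  # BT region of exactly three voxels, no erosion, no FA condition
  label[c(2, 3, 4), 5, 5] <- 5L
  md[cbind(c(2, 3, 4), 5, 5)] <- c(0.2, 0.4, 0.6)
  vs <- volume_set(label, metrics = list(FA = fa, MD = md))
  masks <- build_region_masks(vs, erode = FALSE)
  expect_identical(sum(masks$BT), 3L)
  expect_identical(mean(md[masks$BT]), 0.4)
})
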