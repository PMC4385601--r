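test_that("load_label_mask handles empty, binary and labeled PNGs", {
  d <- withr::local_tempdir()

  zeros <- file.path(d, "zeros.png")
  png::writePNG(matrix(0, 5, 5), zeros)
  expect_equal(n_labels(load_label_mask(zeros)), 0L)

  # two disjoint 2x2 blocks stored as a 0/255 binary image
  bin <- matrix(0, 5, 5)
  bin[1:2, 1:2] <- 1
  bin[4:5, 4:5] <- 1
  binpath <- file.path(d, "bin.png")
  png::writePNG(bin, binpath)
  expect_equal(n_labels(load_label_mask(binpath)), 2L)

  # direct grayscale label values survive a roundtrip
  lab <- matrix(0L, 6, 6)
  lab[2:3, 2:3] <- 1L
  lab[5, 5] <- 7L
  m <- labeled_mask(lab)
  p <- file.path(d, "lab.png")
  write_label_mask(m, p)
  expect_identical(load_label_mask(p)$labels, lab)

  expect_error(load_label_mask(file.path(d, "nope.png")), "cannot read")
  expect_error(load_label_mask(file.path(d, "x.tif")), "TIFF")
})

test_that("RGB base-256 encoding roundtrips label ids above 255", {
  d <- withr::local_tempdir()
  lab <- matrix(0L, 8, 8)
  lab[1:2, 1:2] <- 300L
  lab[5:6, 5:6] <- 70000L
  p <- file.path(d, "big.png")
  write_label_mask(labeled_mask(lab), p)
  expect_identical(load_label_mask(p)$labels, lab)
})

test_that("synthetic fixture mask labels match the generator's ground truth", {
  sc <- make_population(8, seed = 11)
  d <- withr::local_tempdir()
  write_scene(sc, d)
  cm <- load_label_mask(file.path(d, "cell_mask.png"))
  nm <- load_label_mask(file.path(d, "nucleus_mask.png"))
  expect_equal(n_labels(cm), nrow(sc$truth))
  expect_equal(n_labels(nm), nrow(sc$truth))
  expect_identical(cm$labels, sc$cell_mask$labels)
})

test_that("morph_cleanup fills holes, opens idempotently, and validates ops", {
  ann <- as_mask(annulus_mask(10, 4))
  hole <- sum(disk_mask(4, 10))
  filled <- morph_cleanup(ann, "fill")
  expect_equal(sum(filled$labels > 0), sum(ann$labels > 0) + hole)
  # the filled result is a solid disk
  expect_equal(sum(filled$labels > 0), sum(disk_mask(10)))

  disk <- as_mask(disk_mask(12))
  opened <- morph_cleanup(disk, "open", radius = 1)
  expect_identical(opened$labels, disk$labels)

  # dilation then erosion (closing) is a superset of the original, and the
  # growth is bounded by the dilated boundary band
  dil_ero <- morph_cleanup(disk, c("dilate", "erode"), radius = 2)
  expect_true(all(dil_ero$labels[disk$labels > 0] > 0))
  dil <- morph_cleanup(disk, "dilate", radius = 2)
  expect_true(all(dil$labels[dil_ero$labels > 0] > 0))

  expect_error(morph_cleanup(disk, "smooth"), "unknown morphological")
  expect_error(morph_cleanup(disk, "open", radius = 0), "radius")
})

test_that("extract_regions reports exact areas and centroids", {
  # single 3x3 square with corner at the origin
  lab <- matrix(0L, 8, 8)
  lab[1:3, 1:3] <- 1L
  r <- extract_regions(labeled_mask(lab))[[1]]
  expect_equal(r$area, 9L)
  expect_equal(r$centroid, c(x = 1, y = 1))

  # single pixel at (x, y) = (4, 7)
  lab <- matrix(0L, 10, 10)
  lab[8, 5] <- 2L
  r <- extract_regions(labeled_mask(lab))[[1]]
  expect_equal(r$area, 1L)
  expect_equal(r$centroid, c(x = 4, y = 7))
  expect_true("degenerate" %in% r$flags)

  # digitized disk: area within 2% of pi r^2, and equal to the brute-force
  # lattice count exactly
  for (rad in c(20, 35)) {
    m <- disk_mask(rad)
    r <- region_of(m)
    expect_equal(r$area, sum(m))
    expect_lt(abs(r$area - pi * rad^2) / (pi * rad^2), 0.02)
  }

  expect_length(extract_regions(labeled_mask(matrix(0L, 4, 4))), 0)
})

test_that("centroids equal pixel-coordinate means for arbitrary blobs", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(FALSE, 30, 30)
    seedpt <- sample(5:25, 2)
    m[seedpt[1], seedpt[2]] <- TRUE
    m <- binary_dilate(m, sample(2:6, 1))
    m[sample(which(m), 5)] <- FALSE # poke holes
    regs <- extract_regions(labeled_mask(label_components(m)))
    for (r in regs) {
      expect_equal(unname(r$centroid["x"]), mean(r$pixels[, 2]) - 1)
      expect_equal(unname(r$centroid["y"]), mean(r$pixels[, 1]) - 1)
    }
  }
})

test_that("traced boundary equals the outer contour pixel set", {
  for (m in list(disk_mask(15), star_mask(3, 0.3, 20), square_mask(12))) {
    r <- region_of(m)
    # oracle: region pixels 4-adjacent to the background component that
    # touches the image border (an 8-connected Moore chain pairs with
    # 4-connected background contact)
    bg <- label_components(!m)
    border_ids <- setdiff(unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)])), 0L)
    outside <- matrix(bg %in% border_ids, nrow(bg), ncol(bg))
    grown <- binary_dilate(outside, 1) # 4-neighborhood cross
    contour <- which(m & grown, arr.ind = TRUE)
    got <- unique(r$boundary[, c("y", "x"), drop = FALSE] + 1L)
    expect_setequal(
      paste(contour[, 1], contour[, 2]),
      paste(got[, 1], got[, 2])
    )
  }
})

test_that("nucleus-cell pairing follows minimum centroid distance", {
  blob_at <- function(lab, r0, c0, size = 3L, id = 1L) {
    lab[r0:(r0 + size - 1L), c0:(c0 + size - 1L)] <- id
    lab
  }
  cells_lab <- blob_at(blob_at(matrix(0L, 30, 30), 2, 2, 7, 1L), 20, 20, 7, 2L)
  nuc_lab <- blob_at(blob_at(matrix(0L, 30, 30), 4, 4, 3, 1L), 22, 22, 3, 2L)
  cells <- extract_regions(labeled_mask(cells_lab))
  nuclei <- extract_regions(labeled_mask(nuc_lab))
  pairs <- pair_nucleus_to_cell(cells, nuclei)
  expect_equal(vapply(pairs, function(p) p$cell$label, integer(1)), 1:2)
  expect_equal(pairs[[1]]$centroid_distance, 0)

  expect_error(pair_nucleus_to_cell(list(), nuclei), "empty cell")
})

test_that("equidistant nuclei resolve to the lower cell label", {
  lab <- matrix(0L, 20, 40)
  lab[9:11, 4:6] <- 5L # cell labeled 5 centered at x = 4
  lab[9:11, 34:36] <- 2L # cell labeled 2 centered at x = 34
  cells <- extract_regions(labeled_mask(lab))
  nuc_lab <- matrix(0L, 20, 40)
  nuc_lab[10, 20] <- 1L # exactly between the two centroids
  nuclei <- extract_regions(labeled_mask(nuc_lab))
  p <- pair_nucleus_to_cell(cells, nuclei)[[1]]
  expect_equal(p$cell$label, 2L)
  expect_true("outside_cell" %in% p$flags)
})

test_that("pairing is invariant under label permutation", {
  set.seed(7)
  sc <- make_population(10, seed = 5)
  cells <- extract_regions(sc$cell_mask)
  nuclei <- extract_regions(sc$nucleus_mask)
  p1 <- pair_nucleus_to_cell(cells, nuclei)
  perm <- sample(length(cells))
  p2 <- pair_nucleus_to_cell(cells[perm], nuclei)
  key <- function(pp) {
    vapply(pp, function(p) paste(p$nucleus$label, p$cell$label), character(1))
  }
  expect_setequal(key(p1), key(p2))
})
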