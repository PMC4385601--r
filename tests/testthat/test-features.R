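test_that("size ratios are exact arithmetic with guarded preconditions", {
  expect_equal(area_ratio(900, 900), 1)
  expect_equal(area_ratio(250, 100), 2.5)
  expect_error(area_ratio(100, 0), "config error")

  # scale property: common rescaling cancels; linear in A at fixed reference
  set.seed(1)
  for (i in 1:20) {
    A <- runif(1, 100, 5000)
    An <- runif(1, 100, 5000)
    s <- runif(1, 0.1, 10)
    expect_equal(area_ratio(s * A, s * An), area_ratio(A, An))
    expect_equal(area_ratio(3 * A, An), 3 * area_ratio(A, An))
  }

  expect_equal(nc_ratio(100, 200), 1)
  expect_equal(nc_ratio(50, 550), 0.1)
  expect_equal(nc_ratio(50, 550, denominator = "cell"), 50 / 550)
  expect_error(nc_ratio(200, 200), "geometry error")
  expect_error(nc_ratio(300, 200), "geometry error")
})

test_that("circularity matches closed forms and digitized-shape oracles", {
  # ideal continuous circle and square via the closed form
  expect_equal(circularity(list(area = pi * 10^2, perimeter = 2 * pi * 10)), 1)
  s <- 40
  expect_equal(circularity(list(area = s^2, perimeter = 4 * s)), pi / 4)

  # digitized disks stay within 0.05 of 1
  for (rad in c(12, 20, 40)) {
    expect_lt(abs(circularity(region_of(disk_mask(rad))) - 1), 0.05 + 1e-9)
  }

  # digitized 2:1 ellipse vs the Ramanujan-perimeter analytic value
  a <- 40
  b <- 20
  C_analytic <- 4 * pi * (pi * a * b) / ellipse_perimeter(a, b)^2
  expect_lt(abs(circularity(region_of(ellipse_mask(a, b))) - C_analytic), 0.05)

  # degenerate single pixel
  lab <- matrix(0L, 5, 5)
  lab[3, 3] <- 1L
  expect_equal(circularity(extract_regions(labeled_mask(lab))[[1]]), 1)
})

test_that("solidity matches hull oracles; extent uses the bounding box", {
  # convex shapes: exactly 1 for a square, within digitization tolerance
  # for smooth outlines at moderate scale
  expect_equal(compactness(region_of(square_mask(30))), 1)
  expect_lt(abs(compactness(region_of(disk_mask(40))) - 1), 0.02)
  expect_lt(abs(compactness(region_of(ellipse_mask(60, 45))) - 1), 0.02)

  # plus-sign pentomino: 5 px over corner-hull area 7 (hand-computed:
  # 3x3 bounding square of area 9 minus four half-unit corner triangles)
  m <- matrix(FALSE, 7, 7)
  m[3:5, 4] <- TRUE
  m[4, 3:5] <- TRUE
  expect_equal(compactness(region_of(m)), 5 / 7)

  # deep 4-lobed star is far from solid
  star <- region_of(star_mask(4, 0.5, 35))
  expect_lt(compactness(star), 0.7)

  # extent variant: square fills its bounding box exactly
  expect_equal(compactness(region_of(square_mask(20)), variant = "extent"), 1)
})

test_that("circularity strictly orders disk, 2:1 ellipse and 4-lobed star at equal area", {
  A <- 3000
  Cs <- c(
    circularity(region_of(disk_mask(sqrt(A / pi)))),
    circularity(region_of(ellipse_mask(sqrt(2 * A / pi), sqrt(A / (2 * pi))))),
    circularity(region_of(star_mask(4, 0.5, sqrt(A / (pi * (1 + 0.5^2 / 2))))))
  )
  expect_true(all(diff(Cs) < 0))
})

test_that("radial signature reproduces constant, elliptic and square profiles", {
  rad <- 25
  sig <- radial_signature(region_of(disk_mask(rad)))
  expect_true(all(sig$distances >= rad - 1 & sig$distances <= rad + 1))
  expect_true(all(diff(sig$angles) > 0))

  a <- 40
  b <- 20
  sig <- radial_signature(region_of(ellipse_mask(a, b)))
  near <- function(theta, tol = 0.15) abs((sig$angles - theta + pi) %% (2 * pi) - pi) < tol
  expect_lt(abs(max(sig$distances[near(0)]) - a), 1.5)
  expect_lt(abs(max(sig$distances[near(pi)]) - a), 1.5)
  expect_lt(abs(min(sig$distances[near(pi / 2)]) - b), 1.5)

  # square: 4 maxima at the corners, each at (s-1) * sqrt(2) / 2 between
  # opposite boundary-pixel centers
  s <- 21
  sig <- radial_signature(region_of(square_mask(s)))
  corner <- (s - 1) * sqrt(2) / 2
  top4 <- sort(sig$distances, decreasing = TRUE)[1:4]
  expect_true(all(abs(top4 - corner) < 1e-6))

  lab <- matrix(0L, 4, 4)
  lab[2, 2:3] <- 1L
  expect_error(radial_signature(extract_regions(labeled_mask(lab))[[1]]), "degenerate")
})

test_that("shape descriptor N counts lobes: circle 0, ellipse 4, 3-lobed star 6", {
  expect_equal(as.integer(string_shape_descriptor(radial_signature(region_of(disk_mask(25))))), 0L)
  expect_equal(as.integer(string_shape_descriptor(radial_signature(region_of(ellipse_mask(40, 20))))), 4L)
  expect_equal(as.integer(string_shape_descriptor(radial_signature(region_of(star_mask(3, 0.3, 30))))), 6L)
})

test_that("N is invariant to rotation and boundary start point", {
  for (deg in seq(0, 165, by = 15)) {
    r <- region_of(star_mask(3, 0.3, 30, rotation = deg * pi / 180))
    expect_equal(as.integer(string_shape_descriptor(radial_signature(r))), 6L)
  }
  # start-point invariance: the signature is angle-ordered, so any cyclic
  # shift of the traced boundary yields the same N
  r <- region_of(star_mask(3, 0.3, 30))
  sig <- radial_signature(r)
  for (shift in c(10, 57, 150)) {
    r2 <- r
    n <- nrow(r2$boundary)
    r2$boundary <- r2$boundary[c((shift + 1):n, 1:shift), , drop = FALSE]
    expect_equal(
      as.integer(string_shape_descriptor(radial_signature(r2))),
      as.integer(string_shape_descriptor(sig))
    )
  }
})

test_that("color strength equals the brute-force per-pixel mean", {
  img <- array(0L, dim = c(6, 6, 3))
  img[, , 1] <- 100L
  img[, , 2] <- 50L
  img[, , 3] <- 200L
  px <- cbind(rep(1:6, 6), rep(1:6, each = 6))
  expect_equal(color_strength(img, px), c(R = 100, G = 50, B = 200))

  # half black, half (200, 100, 50)
  img2 <- array(0L, dim = c(4, 4, 3))
  img2[3:4, , 1] <- 200L
  img2[3:4, , 2] <- 100L
  img2[3:4, , 3] <- 50L
  pxall <- cbind(rep(1:4, 4), rep(1:4, each = 4))
  expect_equal(color_strength(img2, pxall), c(R = 100, G = 50, B = 25))

  set.seed(9)
  img3 <- array(sample(0:255, 8 * 8 * 3, TRUE), dim = c(8, 8, 3))
  px3 <- unique(cbind(sample(1:8, 20, TRUE), sample(1:8, 20, TRUE)))
  manual <- sapply(1:3, function(ch) {
    mean(sapply(seq_len(nrow(px3)), function(i) img3[px3[i, 1], px3[i, 2], ch]))
  })
  expect_equal(unname(color_strength(img3, px3)), manual)

  expect_error(color_strength(img3, cbind(9, 1)), "geometry error")
})

test_that("extract_features composes all descriptors with ground truth", {
  ref <- normal_reference()
  sc <- make_cell(
    cell_spec("NORMAL", shape_circle(), 900, 9900,
      c(125, 110, 205), c(205, 160, 215),
      noise_sd = 0
    ),
    seed = 2
  )
  cells <- extract_regions(sc$cell_mask)
  nuclei <- extract_regions(sc$nucleus_mask)
  fv <- extract_features(pair_nucleus_to_cell(cells, nuclei)[[1]], sc$image, ref)
  expect_lt(abs(fv$grad_A - 1), 0.05)
  expect_lt(abs(fv$grad_P - 1), 0.05)
  expect_gt(fv$C, 0.9)
  expect_gt(fv$E, 0.94)
  expect_equal(fv$N, 0L)
  expect_equal(unname(fv$nucleus_rgb), c(125, 110, 205))
  expect_equal(unname(fv$cytoplasm_rgb), c(205, 160, 215))

  # SCC-like: dark meganucleus
  sc2 <- make_cell(
    cell_spec("SCC", shape_ellipse(1.15), 2700, 4900,
      c(80, 75, 150), c(180, 150, 200),
      noise_sd = 0
    ),
    seed = 3
  )
  fv2 <- extract_features(
    pair_nucleus_to_cell(
      extract_regions(sc2$cell_mask), extract_regions(sc2$nucleus_mask)
    )[[1]],
    sc2$image, ref
  )
  expect_gt(fv2$grad_A, 2)
  expect_true(all(fv2$nucleus_rgb < c(90, 90, 190)))

  # nucleus occupying the whole cell is a precondition failure
  p <- pair_nucleus_to_cell(cells, cells)
  expect_error(extract_features(p[[1]], sc$image, ref), "geometry error|cell area")
})

test_that("estimate_reference averages normal-cell descriptors", {
  sc <- make_population(6, stage_mix = c(NORMAL = 1, LSIL = 0, HSIL = 0, SCC = 0), seed = 4)
  pairs <- pair_nucleus_to_cell(
    extract_regions(sc$cell_mask), extract_regions(sc$nucleus_mask)
  )
  est <- estimate_reference(pairs, sc$image)
  expect_lt(abs(est$A_normal - 900) / 900, 0.2)
  expect_lt(abs(est$P_normal - 0.1) / 0.1, 0.35)
  expect_gt(est$C0, 0.9)
})
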