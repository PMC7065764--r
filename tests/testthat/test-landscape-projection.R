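test_that("labelPatches delineates components under 4/8 connectivity", {
  # all-forest grid: one patch covering everything
  g <- ForestGrid(matrix(1, 5, 7), 0.09, "a")
  ps <- labelPatches(g)
  expect_equal(nrow(patchTable(ps)), 1)
  expect_equal(patchTable(ps)$n_pixels, 35)
  expect_equal(patchTable(ps)$area_ha, 35 * 0.09)

  # diagonal-only contact: one patch at 8-connectivity, two at 4
  m <- matrix(0, 3, 3); m[1, 1] <- 1; m[2, 2] <- 1
  gd <- ForestGrid(m, 0.09, "a")
  expect_equal(nrow(patchTable(labelPatches(gd, 8))), 1)
  expect_equal(nrow(patchTable(labelPatches(gd, 4))), 2)

  # single pixel area
  g1 <- ForestGrid(matrix(c(0, 0, 0, 1), 2, 2), 0.09, "a")
  expect_equal(patchTable(labelPatches(g1))$area_ha, 0.09)

  # patch ids follow raster-scan order of first pixels, deterministically
  m2 <- matrix(0, 4, 4); m2[4, 1] <- 1; m2[1, 4] <- 1; m2[2, 2] <- 1
  t2 <- patchTable(labelPatches(ForestGrid(m2, 1, "a"), 4))
  expect_equal(t2$patch_id, 1:3)
  expect_equal(t2$centroid_row, c(1, 2, 4))   # (1,4) then (2,2) then (4,1)

  # patch areas always sum to forest pixels x pixel area, exactly
  set.seed(12)
  for (i in 1:5) {
    mm <- matrix(rbinom(400, 1, 0.45), 20, 20)
    psr <- labelPatches(ForestGrid(mm, 0.3, "a"))
    expect_identical(sum(patchTable(psr)$n_pixels), sum(mm == 1))
    expect_equal(sum(patchTable(psr)$area_ha), sum(mm) * 0.3)
    # adding a bridging pixel never increases the patch count
    open <- which(mm == 0)
    if (length(open)) {
      mm2 <- mm; mm2[open[1]] <- 1
      expect_lte(nrow(patchTable(labelPatches(ForestGrid(mm2, 0.3, "a")))),
                 nrow(patchTable(psr)) + 1)
    }
  }

  expect_error(ForestGrid(matrix(c(0, 2), 1, 2), 0.09), "0/1")
})

test_that("proximityIndex sums area over squared edge-to-edge distance", {
  # pixel side 100 m (1 ha pixels); focal single pixel at (1,1),
  # a 10-pixel neighbour with a one-pixel gap -> distance 100 m
  m <- matrix(0, 3, 15)
  m[1, 1] <- 1
  m[1, 3:12] <- 1
  ps <- labelPatches(ForestGrid(m, 1, "a"), 8)
  expect_equal(nrow(patchTable(ps)), 2)
  expect_equal(proximityIndex(ps, 1, radiusM = 500), 10 / 100^2)
  # nothing within the radius -> 0
  expect_equal(proximityIndex(ps, 1, radiusM = 50), 0)
  # literal variant: sum(areas) / (sum of distances)^2 coincides for a
  # single neighbour
  expect_equal(proximityIndex(ps, 1, radiusM = 500, variant = "literal"),
               10 / 100^2)
  # diagonal gap: distance is the hypotenuse between pixel corners
  md <- matrix(0, 4, 4); md[1, 1] <- 1; md[3, 3] <- 1
  psd <- labelPatches(ForestGrid(md, 1, "a"), 4)
  expect_equal(proximityIndex(psd, 1, radiusM = 1000),
               1 / (sqrt(2) * 100)^2)
  # touching patches are excluded (distance zero)
  mt <- matrix(0, 2, 3); mt[1, 1] <- 1; mt[2, 2] <- 1; mt[1, 3] <- 1
  pst <- labelPatches(ForestGrid(mt, 1, "a"), 4)
  # patch 2 = (2,2) touches patch 1 = (1,1) diagonally: excluded at conn 4
  expect_error(proximityIndex(pst, 99), "unknown focal")

  expect_equal(CF_PROXIMITY, 1.0e9)
})

test_that("projectCFD applies the quadratic area relationship", {
  m <- matrix(0, 2, 6); m[1, 1] <- 1; m[1, 3:6] <- 1
  ps <- labelPatches(ForestGrid(m, 2.5, "a"))   # areas 2.5 and 10 ha
  pc <- projectCFD(ps)                           # b = (0, 0.35, -0.04)
  tab <- patchTable(pc)
  la10 <- log10(10)
  expect_equal(tab$cfd[tab$area_ha == 10], 0.35 - 0.04)   # 0.31
  expect_equal(tab$cfd[tab$area_ha == 2.5],
               0.35 * log10(2.5) - 0.04 * log10(2.5)^2)
  expect_equal(tab$cfd_sign, c(1, 1))

  # area of 1 ha with zero intercept gives exactly 0
  ps1 <- labelPatches(ForestGrid(matrix(1, 2, 2), 0.25, "a"))
  expect_equal(patchTable(projectCFD(ps1))$cfd, 0)
  # constant projection when both slopes vanish
  pc0 <- projectCFD(ps, projectionCoefficients(0.7, 0, 0))
  expect_true(all(patchTable(pc0)$cfd == 0.7))

  # monotone in area up to the vertex at log10(area) = -b1/(2 b2) = 4.375
  areas <- 10^seq(-2, 4.375, length.out = 50)
  cfd <- 0.35 * log10(areas) - 0.04 * log10(areas)^2
  expect_true(all(diff(cfd) > 0))
  beyond <- 10^seq(4.375, 6, length.out = 10)
  cfdB <- 0.35 * log10(beyond) - 0.04 * log10(beyond)^2
  expect_true(all(diff(cfdB) < 0))
})

test_that("chronosequenceSummary aggregates exactly per year", {
  ch <- generateChronosequence(c(40, 40), 0.09, c(a = 0.2, b = 0.6),
                               seed = 13)
  psl <- lapply(ch, function(g) projectCFD(labelPatches(g)))
  s <- chronosequenceSummary(psl)
  expect_equal(s$year, c("a", "b"))
  expect_equal(s$forest_area_ha,
               c(sum(gridCells(ch[[1]])), sum(gridCells(ch[[2]]))) * 0.09)
  expect_true(all(diff(s$forest_area_ha) <= 0))
  expect_true(all(s$area_fraction_negative >= 0 &
                    s$area_fraction_negative <= 1))
  # identical years give identical summaries
  s2 <- chronosequenceSummary(list(psl[[1]], psl[[1]]))
  expect_equal(s2$n_patches[1], s2$n_patches[2])
  # a year with no forest
  g0 <- ForestGrid(matrix(0, 4, 4), 0.09, "z")
  s0 <- chronosequenceSummary(list(projectCFD(labelPatches(g0))))
  expect_equal(s0$n_patches, 0)
  expect_equal(s0$forest_area_ha, 0)
  # inconsistent pixel areas refused
  gx <- projectCFD(labelPatches(ForestGrid(matrix(1, 2, 2), 1, "w")))
  expect_error(chronosequenceSummary(list(psl[[1]], gx)), "pixel areas")
})

test_that("transitionMetric measures loss of high-dependency forest", {
  mkps <- function(m, coeffs = projectionCoefficients(1, 0, 0))
    projectCFD(labelPatches(ForestGrid(m, 1, "t")), coeffs)
  A <- matrix(0, 4, 4); A[1:2, 1:2] <- 1      # one 4-pixel patch, cfd = 1
  psA <- mkps(A)
  # identical snapshots -> 0
  expect_equal(as.numeric(transitionMetric(psA, psA)), 0)
  # full deforestation -> 1 with the year-A denominator
  psEmpty <- mkps(matrix(0, 4, 4))
  expect_equal(as.numeric(transitionMetric(psA, psEmpty,
                                           denominator = "forest_a")), 1)
  # toy grids: 4 qualifying pixels in A, 1 left in B -> 3/4 lost
  B <- matrix(0, 4, 4); B[1, 1] <- 1
  expect_equal(as.numeric(transitionMetric(psA, mkps(B),
                                           denominator = "forest_a")),
               3 / 4)
  # year-B denominator: lost area over all remaining forest in B
  B2 <- matrix(0, 4, 4); B2[1, 1] <- 1; B2[4, 4] <- 1
  expect_equal(as.numeric(transitionMetric(psA, mkps(B2),
                                           denominator = "forest_b")),
               3 / 2)
  expect_error(transitionMetric(psA, mkps(matrix(0, 3, 3))), "extent")
  expect_error(transitionMetric(psEmpty, psEmpty), "zero denominator")
})
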