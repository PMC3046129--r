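test_that("intensity histograms normalize and validate input", {
  p <- intensity_histogram(matrix(5L, 3, 3))
  expect_equal(p[6], 1)
  expect_equal(sum(p), 1)

  two <- intensity_histogram(matrix(c(0L, 0L, 9L, 9L), 2))
  expect_equal(two[c(1, 10)], c(0.5, 0.5))

  set.seed(1)
  u <- intensity_histogram(matrix(sample(0:255, 1000, TRUE), 40, 25))
  expect_equal(sum(u), 1)

  expect_error(intensity_histogram(matrix(numeric(0), 0, 0)), "empty")
})

test_that("sub-range entropy matches closed forms", {
  delta <- replace(rep(0, 256), 43, 1)
  expect_equal(as.numeric(shannon_entropy(delta)), 0)
  expect_equal(as.numeric(shannon_entropy(rep(1 / 256, 256))), 8)
  expect_equal(as.numeric(shannon_entropy(rep(0.25, 4))), 2)
  # restriction + renormalization: half of a uniform is still uniform
  expect_equal(as.numeric(shannon_entropy(rep(1 / 256, 256), 0, 127)), 7)
  e <- shannon_entropy(rep(0, 10), 2, 5)
  expect_equal(as.numeric(e), 0)
  expect_true(attr(e, "empty"))
})

test_that("maximum-entropy cut equals the exhaustive oracle", {
  # two spikes: every admissible cut ties at 0; smallest wins
  p <- replace(rep(0, 256), c(11, 201), 0.5)
  expect_equal(max_entropy_cut(p)$cut, 10L)

  set.seed(11)
  for (i in 1:30) {
    p <- random_histogram()
    lo <- sample(0:100, 1); hi <- sample(150:255, 1)
    if (sum(p[(lo:hi) + 1]) == 0) next
    got <- max_entropy_cut(p, lo, hi)
    ora <- oracle_cut(p, lo, hi)
    if (is.na(ora$cut)) {
      expect_true(got$degenerate)
    } else {
      expect_identical(got$cut, as.integer(ora$cut))
      expect_equal(got$criterion, ora$criterion, tolerance = 1e-12)
    }
  }
})

test_that("cut of a symmetric histogram respects the mirror relation", {
  set.seed(3)
  half <- runif(128)
  p <- c(half, rev(half)); p <- p / sum(p)
  t <- max_entropy_cut(p)$cut
  crit_at <- function(t) {
    oracle_entropy(p[1:(t + 1)]) + oracle_entropy(p[(t + 2):256])
  }
  expect_equal(crit_at(t), crit_at(254 - t), tolerance = 1e-10)
})

test_that("degenerate histograms are flagged", {
  one <- replace(rep(0, 256), 101, 1)
  got <- max_entropy_cut(one)
  expect_true(got$degenerate)
  expect_equal(got$cut, 100L)
  expect_error(max_entropy_cut(rep(0, 256)), "no mass")
})

test_that("eight-layer decomposition uses per-sub-range cuts", {
  lv <- c(10L, 40L, 70L, 100L, 130L, 160L, 200L, 230L)
  set.seed(5)
  img <- matrix(sample(lv, 4000, TRUE, prob = (1:8) / 36), 50, 80)
  dec <- eight_layer_decompose(img)
  expect_setequal(unique(as.vector(dec$layers)), 0:7)
  # each distinct level lands in its own layer, in intensity order
  got <- vapply(lv, function(v) unique(dec$layers[img == v]), integer(1))
  expect_equal(got, 0:7)
  # cuts match the exhaustive oracle inside each sub-range
  p <- intensity_histogram(img)
  ranges <- list(c(0, 63), c(64, 127), c(128, 191), c(192, 255))
  for (i in 1:4)
    expect_equal(dec$cuts[i], oracle_cut(p, ranges[[i]][1], ranges[[i]][2])$cut)
  # monotone: layer index never decreases with intensity
  ord <- order(as.vector(img))
  expect_true(all(diff(dec$layers[ord]) >= 0))
})

test_that("constant and empty-sub-range images are handled with flags", {
  dec <- eight_layer_decompose(matrix(77L, 10, 10))
  expect_true(all(dec$layers == dec$layers[1, 1]))
  expect_equal(sum(dec$empty), 3L)      # the three massless sub-ranges
  expect_true(dec$degenerate[2])        # all mass at one level: no real cut
})

test_that("layer binarization separates high-density layers", {
  l16 <- matrix(c(1L, 6L), 20, 20)
  bin <- binarize_nuclei(l16)
  expect_equal(bin$mask, l16 == 6L)

  all0 <- binarize_nuclei(matrix(0L, 5, 5))
  expect_true(all0$degenerate)
  expect_false(any(all0$mask))

  # nuclei + non-nuclei partition the raster
  expect_equal(sum(bin$mask) + sum(!bin$mask), 400L)
})

test_that("mode filter equals brute-force window counting", {
  cst <- matrix(4L, 12, 9)
  expect_identical(mode_filter(cst, 3), cst)

  iso <- matrix(0L, 11, 11); iso[6, 6] <- 1L
  expect_true(all(mode_filter(iso, 3) == 0L))

  set.seed(21)
  for (r in c(1L, 3L)) {
    bin <- matrix(sample(0:1, 30 * 25, TRUE), 30, 25)
    expect_identical(mode_filter(bin, r), oracle_mode_filter(bin, r))
    lab <- matrix(sample(c(0L, 2L, 5L), 30 * 25, TRUE, c(.45, .45, .1)), 30, 25)
    expect_identical(mode_filter(lab, r), oracle_mode_filter(lab, r))
  }
  # logical in, logical out
  lg <- matrix(runif(100) < 0.5, 10, 10)
  expect_type(mode_filter(lg, 1), "logical")
})

test_that("nuclei extraction recovers planted disks", {
  set.seed(9)
  d <- disk_image()
  nuc <- extract_nuclei(d$img)
  expect_gte(jaccard(nuc$mask, d$truth), 0.9)

  # blank field -> empty mask, flagged degenerate
  blank <- extract_nuclei(matrix(0.1, 32, 32))
  expect_false(any(blank$mask))

  # invariance under order-preserving affine rescaling of the amounts
  nuc2 <- extract_nuclei(2 * d$img + 0.5)
  expect_identical(nuc2$mask, nuc$mask)
})
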