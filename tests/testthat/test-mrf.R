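test_that("singleton energy is the exact negative log Gaussian density", {
  m <- structure(list(classes = c("a", "b"), mu = c(10, 1 / (2 * pi)),
                      sigma2 = c(4, 1 / (2 * pi)), n = c(5L, 5L)),
                 class = "class_model")
  # at the class mean the quadratic term vanishes
  expect_equal(singleton_energy(10, 1, m), 0.5 * log(2 * pi * 4))
  # unit-density point: sigma^2 = 1/(2pi), f = mu -> energy 0
  expect_equal(singleton_energy(1 / (2 * pi), 2, m), 0)

  set.seed(14)
  for (i in 1:1000) {
    f <- runif(1, 0, 255); mu <- runif(1, 0, 255); s2 <- runif(1, 0.5, 900)
    mm <- structure(list(classes = "x", mu = mu, sigma2 = s2, n = 1L),
                    class = "class_model")
    expect_equal(singleton_energy(f, 1, mm),
                 -dnorm(f, mu, sqrt(s2), log = TRUE))
  }
})

test_that("clique potential is symmetric Potts", {
  expect_equal(clique_potential(2, 2, 0.9), -0.9)
  expect_equal(clique_potential(1, 3, 0.9), 0.9)
  expect_equal(clique_potential(1, 2, 0), 0)
  expect_equal(clique_potential(c(1, 1), c(1, 2), 0.5), c(-0.5, 0.5))
})

test_that("local energy sums singleton and neighbor potentials", {
  set.seed(15)
  m <- random_model(3L)
  # isolated site: no neighbors
  f1 <- matrix(100, 1, 1)
  expect_equal(local_energy(1, 1, 2, matrix(1L, 1, 1), f1, m),
               singleton_energy(100, 2, m))
  # all 8 neighbors share the candidate label
  f3 <- matrix(runif(9, 0, 255), 3)
  lab <- matrix(2L, 3, 3)
  expect_equal(local_energy(2, 2, 2, lab, f3, m, beta = 0.9),
               singleton_energy(f3[2, 2], 2, m) - 8 * 0.9)
  # local differences equal global energy differences
  for (rep in 1:5) {
    f5 <- matrix(runif(25, 0, 255), 5)
    w <- matrix(sample(1:3, 25, TRUE), 5)
    i <- sample(5, 1); j <- sample(5, 1)
    for (lam in 1:3) {
      w2 <- w; w2[i, j] <- lam
      dl <- local_energy(i, j, lam, w, f5, m, 0.9) -
            local_energy(i, j, w[i, j], w, f5, m, 0.9)
      dg <- oracle_total_energy(w2, f5, m, 0.9) -
            oracle_total_energy(w, f5, m, 0.9)
      expect_equal(dl, dg, tolerance = 1e-10)
    }
  }
})

test_that("total energy matches exhaustive enumeration on tiny images", {
  set.seed(16)
  m <- random_model(4L)
  # closed forms first
  f12 <- matrix(c(30, 40), 1, 2)
  expect_equal(total_energy(matrix(3L, 1, 2), f12, m, beta = 0.7),
               singleton_energy(30, 3, m) + singleton_energy(40, 3, m) - 0.7)
  f22 <- matrix(runif(4, 0, 255), 2)
  lab22 <- matrix(sample(1:4, 4, TRUE), 2)
  expect_equal(total_energy(lab22, f22, m, beta = 0),
               sum(singleton_energy(f22, lab22, m)))
  # all 4^4 labellings of a 2x2 image, both connectivities
  for (nb in c(4L, 8L)) {
    for (code in 0:(4^4 - 1)) {
      lab <- matrix(1L + (code %/% 4^(0:3)) %% 4L, 2)
      expect_equal(total_energy(lab, f22, m, 0.9, nb),
                   oracle_total_energy(lab, f22, m, 0.9, nb),
                   tolerance = 1e-10)
    }
  }
  # and a 2x3 raster
  f23 <- matrix(runif(6, 0, 255), 2)
  for (code in sample(0:(4^6 - 1), 200)) {
    lab <- matrix(1L + (code %/% 4^(0:5)) %% 4L, 2)
    expect_equal(total_energy(lab, f23, m, 0.9, 8L),
                 oracle_total_energy(lab, f23, m, 0.9, 8L),
                 tolerance = 1e-10)
  }
})

test_that("with beta = 0 every relaxer returns the per-pixel ML labelling", {
  set.seed(17)
  m <- random_model(4L)
  f <- matrix(runif(48 * 48, 0, 255), 48)
  ml <- ml_labelling(f, m)
  expect_identical(relax_icm(f, m, beta = 0)$labels, ml)
  for (fun in list(relax_metropolis, relax_gibbs, relax_mmd)) {
    fit <- fun(f, m, seed = 5, beta = 0, t0 = 1e-8, cooling = 0.5)
    expect_identical(fit$labels, ml)
  }
})

test_that("ICM is monotone coordinate descent with 1-flip-stable fixed points", {
  set.seed(18)
  for (rep in 1:4) {
    m <- random_model(3L)
    f <- matrix(runif(9, 0, 255), 3)
    fit <- relax_icm(f, m, beta = 0.9)
    expect_true(all(diff(fit$trace$energy) <= 1e-9))
    expect_true(fit$converged)
    # no single label flip lowers the total energy
    u0 <- oracle_total_energy(fit$labels, f, m, 0.9)
    for (i in 1:3) for (j in 1:3) for (lam in 1:3) {
      alt <- fit$labels; alt[i, j] <- lam
      expect_gte(oracle_total_energy(alt, f, m, 0.9), u0 - 1e-9)
    }
  }
})

test_that("relaxers recover a planted two-class image and never raise energy", {
  spec <- synthetic_spec(64, 64, fractions = c(0.5, 0.5, 0, 0),
                         mu = c(60, 180, 0, 0), sigma = 15)
  truth <- make_layout(spec, seed = 23)
  set.seed(23)
  f <- matrix(spec$mu[truth] + 15 * rnorm(length(truth)), 64)
  m <- structure(list(classes = c("a", "b"), mu = c(60, 180),
                      sigma2 = c(225, 225), n = c(1L, 1L)),
                 class = "class_model")
  u0 <- total_energy(ml_labelling(f, m), f, m, 0.9)
  for (relaxer in c("metropolis", "icm", "gibbs", "mmd")) {
    fit <- segment_mrf(f, m, mrf_config(relaxer = relaxer), seed = 31)
    expect_gte(mean(fit$labels == truth), 0.99)
    expect_lte(total_energy(fit$labels, f, m, 0.9), u0 + 1e-9)
    expect_equal(fit$energy, total_energy(fit$labels, f, m, 0.9),
                 tolerance = 1e-8)
  }
})

test_that("stochastic relaxation is bit-reproducible from the seed", {
  set.seed(19)
  m <- random_model(4L)
  f <- matrix(runif(40 * 40, 0, 255), 40)
  a <- relax_metropolis(f, m, seed = 99)
  b <- relax_metropolis(f, m, seed = 99)
  expect_identical(a$labels, b$labels)
  expect_identical(a$trace, b$trace)
})

test_that("Gibbs local conditionals are proper distributions", {
  set.seed(20)
  m <- random_model(4L)
  f <- matrix(runif(25, 0, 255), 5)
  lab <- matrix(sample(1:4, 25, TRUE), 5)
  for (i in 1:5) for (j in 1:5) {
    pr <- class_posterior(i, j, lab, f, m, temp = 2)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
  }
})

test_that("non-tumour subtypes merge into one class", {
  lab <- matrix(c(1L, 2L, 3L, 4L), 2)
  expect_equal(merge_non_tumour(lab), matrix(c(1L, 2L, 2L, 3L), 2))
  expect_true(all(merge_non_tumour(matrix(2L, 3, 3)) == 2L))
  # tumour pixel count is conserved; 4 histogram bins collapse to 3
  set.seed(22)
  lab2 <- matrix(sample(1:4, 100, TRUE), 10)
  merged <- merge_non_tumour(lab2)
  expect_equal(sum(merged == 1L), sum(lab2 == 1L))
  expect_equal(sum(merged == 2L), sum(lab2 %in% 2:3))
  expect_equal(sum(merged == 3L), sum(lab2 == 4L))
  expect_error(merge_non_tumour(matrix(5L, 2, 2)), "4-class")
})
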