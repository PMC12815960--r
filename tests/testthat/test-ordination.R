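test_that("community matrix sums abundance and weights covariates", {
  d <- tibble::tibble(
    stomach_id = c("a", "b", "c", "d"),
    prey_taxon = c("t1", "t2", "t3", "t4"),
    prey_family = c("famA", "famA", "famA", "famB"),
    prey_count = c(2L, 3L, 5L, 6L),
    prey_indiv_mass_g = c(1, 4, 2, 0.05),
    ices_rectangle = c("31F4", "31F4", "32F4", "31F4"),
    sst_c = c(10, 10, 12, 10),
    effort_hours = c(100, 100, 300, 100)
  )
  comm <- build_community_matrix(d, min_abundance = 1)
  expect_equal(comm$abundance["famA", "31F4"], 5)  # 2 + 3 in one cell
  expect_equal(comm$abundance["famA", "32F4"], 5)
  covs <- comm$covariates
  # abundance-weighted mean mass of (2 x 1 g, 3 x 4 g) + (5 x 2 g) cells
  expect_equal(covs$mean_mass[covs$prey_family == "famA"],
               (2 * 1 + 3 * 4 + 5 * 2) / 10)
  fam_a <- covs[covs$prey_family == "famA", ]
  expect_equal(fam_a$mean_temp, (5 * 10 + 5 * 12) / 10)
  # low-abundance family dropped with a message
  expect_message(comm2 <- build_community_matrix(d, min_abundance = 7),
                 "dropped")
  expect_false("famB" %in% rownames(comm2$abundance))
  expect_error(build_community_matrix(d["stomach_id"]), class = "ppmr_error")
})

test_that("equal dissimilarities embed stress-free; identical profiles co-locate", {
  # three mutually disjoint families (pairwise Bray-Curtis = 1) plus an
  # exact copy of the third: equilateral triangle with two co-located points
  mat <- rbind(f1 = c(10, 0, 0), f2 = c(0, 10, 0),
               f3 = c(0, 0, 10), f4 = c(0, 0, 10))
  ord <- suppressWarnings(run_nmds(mat, k = 2, seed = 1, starts = 10))
  expect_lt(ord$stress, 0.01)
  pts <- ord$points
  expect_lt(sqrt(sum((pts["f3", ] - pts["f4", ])^2)), 1e-4)
  d12 <- sqrt(sum((pts["f1", ] - pts["f2", ])^2))
  d13 <- sqrt(sum((pts["f1", ] - pts["f3", ])^2))
  d23 <- sqrt(sum((pts["f2", ] - pts["f3", ])^2))
  expect_equal(d13 / d12, 1, tolerance = 0.05)  # near-equilateral
  expect_equal(d23 / d12, 1, tolerance = 0.05)
  # determinism under the same seed and starts
  ord2 <- suppressWarnings(run_nmds(mat, k = 2, seed = 1, starts = 10))
  expect_equal(ord$points, ord2$points)
  # fully degenerate matrix errors
  same <- rbind(a = c(5, 5), b = c(5, 5), c = c(5, 5), d = c(5, 5))
  expect_error(run_nmds(same), class = "ppmr_error")
  expect_error(run_nmds(mat[1:3, ], k = 2), class = "ppmr_error")
})

test_that("environmental vectors recover axis-aligned covariates", {
  m <- small_matched(seed = 81, n = 800)
  comm <- suppressMessages(build_community_matrix(m))
  ord <- run_nmds(comm, seed = 1, starts = 10)
  n <- nrow(ord$points)
  covs <- data.frame(
    along1 = ord$points[, 1],
    against2 = -ord$points[, 2],
    flat = rep(1, n)
  )
  v <- fit_env_vectors(ord, covs, permutations = 99)
  a1 <- v[v$covariate == "along1", ]
  expect_gt(a1$r2, 0.999)
  expect_gt(abs(a1$axis1), 0.99)  # arrow along axis 1
  a2 <- v[v$covariate == "against2", ]
  expect_gt(a2$r2, 0.999)
  expect_lt(a2$axis2, -0.99)  # sign preserved
  fl <- v[v$covariate == "flat", ]
  expect_true(fl$constant)
  expect_equal(fl$r2, 0)
  # a covariate unrelated to the configuration has low R2
  set.seed(99)
  noise <- data.frame(noise = rnorm(n))
  vn <- fit_env_vectors(ord, noise, permutations = 199)
  expect_lt(vn$r2, 0.9)
  # vector R2 is invariant to affine rescaling of the covariate
  v_scaled <- fit_env_vectors(ord, data.frame(x = 3 * covs$along1 + 7),
                              permutations = 0)
  expect_equal(v_scaled$r2, a1$r2, tolerance = 1e-9)
})

test_that("stress does not increase with an extra dimension", {
  m <- small_matched(seed = 91, n = 600)
  comm <- suppressMessages(build_community_matrix(m))
  if (nrow(comm$abundance) >= 5) {
    s2 <- run_nmds(comm, k = 2, seed = 1, starts = 10)$stress
    s3 <- run_nmds(comm, k = 3, seed = 1, starts = 10)$stress
    expect_lte(s3, s2 + 1e-6)
  }
})
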