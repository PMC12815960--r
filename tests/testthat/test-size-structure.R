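test_that("size classes follow the half-open boundaries", {
  expect_equal(as.character(assign_size_class(0.05)), "small")
  expect_equal(as.character(assign_size_class(0.072)), "medium")  # boundary up
  expect_equal(as.character(assign_size_class(1.25)), "large")
  expect_equal(as.character(assign_size_class(10)), "large")
  expect_error(assign_size_class(0), class = "ppmr_error")
  expect_error(size_class_scheme(c(2, 1)))
  # classes partition all prey observations
  m <- small_matched(seed = 61, n = 300)
  m <- m[!is.na(m$prey_indiv_mass_g), ]
  cls <- assign_size_class(m$prey_indiv_mass_g,
                           empirical_size_scheme(m$prey_indiv_mass_g))
  expect_equal(sum(table(cls)), nrow(m))
})

test_that("effort terciles are equal-count with extras to lower bins", {
  t9 <- effort_terciles(1:9)
  expect_equal(t9$n, c(3L, 3L, 3L))
  expect_equal(t9$median, c(2, 5, 8))
  t10 <- effort_terciles(1:10)
  expect_equal(t10$n, c(4L, 3L, 3L))
  expect_error(effort_terciles(1:2), class = "ppmr_error")
  expect_message(td <- effort_terciles(rep(7, 9)), "degenerate")
  expect_equal(td$median, c(7, 7, 7))
  # partition with counts differing by at most one
  set.seed(2)
  tt <- effort_terciles(runif(101))
  expect_equal(sum(tt$n), 101L)
  expect_lte(max(tt$n) - min(tt$n), 1L)
})

# builds a prey table with controlled per-species slopes around 11 C
species_fixture <- function(slopes, biomass_scale, n_obs = 60, sd = 0.02,
                            seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_along(slopes), function(i) {
    temp <- runif(n_obs, 4, 19)
    tibble::tibble(
      stomach_id = sprintf("s%d_%d", i, seq_len(n_obs)),
      prey_taxon = sprintf("sp%02d", i),
      prey_count = 1L,
      prey_indiv_mass_g = biomass_scale[i] / n_obs *
        10^(slopes[i] * (temp - 11) + rnorm(n_obs, 0, sd)),
      sst_c = temp,
      ices_rectangle = sample(c("31F4", "32F4", "33F4"), n_obs, TRUE)
    )
  })
  dplyr::bind_rows(rows)
}

test_that("species classification categorises slopes and weights biomass", {
  # three species: two strong decreasers, one flat; biomasses ~ 1, 1, 98
  d <- species_fixture(slopes = c(-0.05, -0.05, 0),
                       biomass_scale = c(1, 1, 98))
  res <- classify_species_responses(d, "prey", alpha = 0.05, min_n = 30)
  cats <- setNames(as.character(res$species$category), res$species$species)
  expect_equal(unname(cats[c("sp01", "sp02", "sp03")]),
               c("decrease", "decrease", "no_change"))
  s <- res$summary
  dec <- s[s$category == "decrease", ]
  expect_equal(dec$pct_species, 100 * 2 / 3, tolerance = 1e-9)
  # percent of biomass follows the biomass, not the species count
  bm <- res$species$biomass
  expect_equal(dec$pct_biomass,
               100 * sum(bm[cats == "decrease"]) / sum(bm))
  # category percentages sum to 100
  expect_equal(sum(s$pct_species), 100, tolerance = 0.5)
  expect_equal(sum(s$pct_biomass), 100, tolerance = 0.5)
})

test_that("biomass percentages are invariant to duplicating species rows", {
  d <- species_fixture(slopes = c(-0.05, 0.05, 0),
                       biomass_scale = c(5, 5, 20))
  base <- classify_species_responses(d, "prey", min_n = 30)
  # split every row of one species into two half-count duplicates
  sp1 <- d[d$prey_taxon == "sp01", ]
  sp1$prey_count <- 1L
  d2 <- dplyr::bind_rows(d[d$prey_taxon != "sp01", ], sp1, sp1)
  d2$prey_count[d2$prey_taxon == "sp01"] <- 1L
  d$prey_count[d$prey_taxon == "sp01"] <- 2L
  with_dups <- classify_species_responses(d2, "prey", min_n = 30)
  again <- classify_species_responses(d, "prey", min_n = 30)
  expect_equal(with_dups$summary$pct_biomass, again$summary$pct_biomass,
               tolerance = 1e-9)
})

test_that("species below the minimum sample size are excluded and listed", {
  d <- species_fixture(slopes = c(-0.05, 0), biomass_scale = c(1, 1),
                       n_obs = 60)
  small <- species_fixture(slopes = 0, biomass_scale = 1, n_obs = 10)
  small$prey_taxon <- "rare01"
  res <- classify_species_responses(dplyr::bind_rows(d, small), "prey",
                                    min_n = 30)
  expect_true("rare01" %in% res$excluded)
  expect_false("rare01" %in% res$species$species)
})

test_that("predator classification uses one observation per stomach", {
  m <- small_matched(seed = 71, n = 500)
  res <- classify_species_responses(m, "predator", min_n = 10)
  expect_equal(sum(res$summary$n_species) + length(res$excluded),
               length(unique(m$predator_species)))
  # biomass accounting: each stomach's predator counted once
  one <- m[!duplicated(m$stomach_id), ]
  expect_equal(sum(res$species$biomass),
               sum(one$predator_mass_g[one$predator_species %in%
                                         res$species$species]))
})
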