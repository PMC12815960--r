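test_that("stomach tables read, group, and validate", {
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tiny_stomachs(), p)
  x <- read_stomach_table(p)
  expect_equal(nrow(x), 3)
  expect_equal(sum(x$stomach_id == "s1"), 2)  # two prey rows, one stomach

  # a bad row is rejected with a reason, not silently dropped
  bad <- tiny_stomachs()
  bad$prey_count[3] <- 0L
  readr::write_csv(bad, p)
  expect_message(x <- read_stomach_table(p), "rejected")
  expect_equal(nrow(x), 2)
  rej <- attr(x, "rejected")
  expect_equal(rej$reason, "prey count below 1")

  # missing mandatory column names the column
  readr::write_csv(tiny_stomachs()[-4], p)
  expect_error(read_stomach_table(p), "predator_mass_g")
})

test_that("temperature matching uses the previous calendar month", {
  sst <- tiny_sst()
  rec <- tiny_stomachs()[1, ]
  # sampled May 1995 -> April 1995 cell mean
  out <- match_temperature(rec, sst)
  expect_equal(out$sst_c, 5 + 4 / 100)
  # January rolls back to December of the previous year
  rec$month <- 1L
  out <- match_temperature(rec, sst)
  expect_equal(out$sst_c, 4 + 12 / 100)
  # outside the layer extent -> flagged unmatched, never zero
  rec$lat <- 70
  out <- match_temperature(rec, sst)
  expect_true(is.na(out$sst_c))
  expect_false(out$sst_matched)
})

test_that("lag matching is a pure function of year, month, and cell", {
  sst <- tiny_sst()
  rec <- tiny_stomachs()[1, ]
  months <- 2:12
  got <- vapply(months, function(m) {
    r <- rec
    r$month <- m
    match_temperature(r, sst)$sst_c
  }, numeric(1))
  # shifting the record month by +1 shifts the matched SST month by +1
  expect_equal(diff(got), rep(1 / 100, length(months) - 1))
})

test_that("effort matching joins on year and rectangle", {
  rec <- tiny_stomachs()[3, ]  # 51.2N 4.3E -> 31F4
  rec$year <- 2005L
  out <- match_effort(rec, tiny_effort())
  expect_equal(out$ices_rectangle, "31F4")
  expect_equal(out$effort_hours, 812)

  # year before coverage -> unmatched but retained
  rec$year <- 1999L
  out <- match_effort(rec, tiny_effort())
  expect_true(is.na(out$effort_hours))

  # two stomachs in the same rectangle-year get identical effort
  two <- dplyr::bind_rows(rec, rec)
  two$year <- 2005L
  two$stomach_id <- c("a", "b")
  out <- match_effort(two, tiny_effort())
  expect_equal(out$effort_hours[1], out$effort_hours[2])

  # multi-year mean mode averages across years for the rectangle
  rec39 <- tiny_stomachs()[1, ]  # 55.2N 2.1E -> 39F2
  out <- match_effort(rec39, tiny_effort(), multi_year_mean = TRUE)
  expect_equal(out$effort_hours, mean(c(500, 120)))
})

test_that("matched dataset join sizes are nested", {
  m <- small_matched(seed = 11, n = 300)
  expect_true(all(m$sst_matched))  # generator guarantees coverage
  obs <- compute_ppmr(m)
  fishing <- obs[!is.na(obs$effort_hours), ]
  expect_lte(nrow(fishing), nrow(obs))
  expect_true(all(!is.na(fishing$sst_c)))
})

test_that("duplicate grid and effort records are refused", {
  sst <- tiny_sst()
  expect_error(validate_sst_table(rbind(sst, sst[1, ])), "duplicate")
  eff <- tiny_effort()
  expect_error(validate_effort_table(rbind(eff, eff[1, ])), "duplicate")
  eff$effort_hours[1] <- -5
  expect_error(validate_effort_table(eff), "negative")
})
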