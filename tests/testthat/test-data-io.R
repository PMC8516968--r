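test_that("a well-formed single-area single-month file reads as 4 strata", {
  p <- toy_panel(1, 1)
  path <- tempfile(fileext = ".csv")
  write_count_panel(p, path)
  got <- read_count_panel(path)
  expect_equal(nrow(got), 4)
  expect_s3_class(got, "count_panel")
})

test_that("schema and integrity violations are rejected with useful errors", {
  p <- as.data.frame(toy_panel(1, 2))
  # missing column, named in the error
  expect_error(count_panel(p[, setdiff(names(p), "population")]),
               regexp = "population", class = "spzip_schema_error")
  # negative cases
  p2 <- p; p2$cases[3] <- -1
  expect_error(count_panel(p2), class = "spzip_integrity_error")
  # duplicated stratum
  p3 <- rbind(p, p[1, ])
  expect_error(count_panel(p3), regexp = "duplicate",
               class = "spzip_integrity_error")
  # non-contiguous months
  p4 <- p; p4$month_index <- p4$month_index * 2
  expect_error(count_panel(p4), class = "spzip_integrity_error")
})

test_that("a synthetic 40-area x 48-month panel round-trips exactly", {
  sc <- make_scene(5, 8, 4, n_months = 48)
  set.seed(21)
  sim <- simulate_counts(sc$geo, sc$climate, sc$pop, sc$alt,
                         ground_truth(40), seed = 22)
  path <- tempfile(fileext = ".csv")
  write_count_panel(sim$panel, path)
  got <- read_count_panel(path)
  expect_equal(as.data.frame(got), as.data.frame(sim$panel),
               tolerance = 1e-12)
})

test_that("climate panel round-trips and rejects duplicates", {
  cl <- flat_climate(c("d1", "d2"), 6)
  path <- tempfile(fileext = ".csv")
  write_climate_panel(cl, path)
  expect_equal(as.data.frame(read_climate_panel(path)), as.data.frame(cl),
               tolerance = 1e-12)
  expect_error(climate_panel(rbind(cl, cl[1, ])),
               class = "spzip_integrity_error")
})

test_that("lag truncation arithmetic: humidity lag 3 on 108 months keeps 105", {
  p <- toy_panel(2, 108)
  cl <- flat_climate("d1", 108)
  alt <- c(a1 = 2500, a2 = 200)
  d <- quiet_design(p, cl, alt)
  expect_equal(length(unique(d$month_index)), 105)
  expect_equal(nrow(d), 2 * 105 * 4)
  # altitude 2500 m scales to 25 design units
  expect_equal(unique(d$altitude[d$area == "a1"]), 25)
})

test_that("design rows match a hand-computed table on a 2-area 5-month toy", {
  p <- toy_panel(2, 5)
  cl <- climate_panel(data.frame(
    district = "d1", month_index = 1:5,
    rainfall_mm = c(10, 20, 30, 40, 50),
    rh_percent = c(50, 55, 60, 65, 70),
    tmin_c = 0, tmax_c = 11:15))
  alt <- c(a1 = 1000, a2 = 200)
  d <- quiet_design(p, cl, alt, expected = rep(1, nrow(p)))
  # humidity lag 3 drops months 1-3; months 4, 5 remain
  expect_equal(sort(unique(d$month_index)), c(4, 5))
  # hand-computed covariate values per retained month
  m4 <- d[d$month_index == 4 & d$area == "a1", ]
  m5 <- d[d$month_index == 5 & d$area == "a2", ]
  expect_equal(unique(m4$rainfall), 4.0)      # 40 mm / 10
  expect_equal(unique(m4$humidity), 5.0)      # RH(month 1) = 50% / 10
  expect_equal(unique(m4$tempmax), 14)        # no lag
  expect_equal(unique(m4$altitude), 10)       # 1000 m / 100
  expect_equal(unique(m5$rainfall), 5.0)
  expect_equal(unique(m5$humidity), 5.5)      # RH(month 2) = 55% / 10
  expect_equal(unique(m5$tempmax), 15)
  expect_equal(unique(m5$altitude), 2)
  expect_equal(unique(d$offset), 0)           # expected supplied as 1
  # indicator coding
  expect_equal(d$age, as.integer(d$age_group == "under5"))
  expect_equal(d$sexf, as.integer(d$sex == "female"))
  expect_equal(d$trend, as.numeric(d$month_index))
})

test_that("scaling is applied exactly once and row order is deterministic", {
  p <- toy_panel(2, 6)
  cl <- flat_climate("d1", 6)
  alt <- c(a1 = 100, a2 = 300)
  d <- quiet_design(p, cl, alt)
  expect_error(quiet_design(d, cl, alt), class = "spzip_invalid_argument")
  # shuffling the input rows leaves the design unchanged
  set.seed(8)
  p_shuf <- count_panel(as.data.frame(p)[sample(nrow(p)), ])
  d2 <- quiet_design(p_shuf, cl, alt)
  expect_equal(as.data.frame(d), as.data.frame(d2))
})

test_that("linkage failures name the offending area or district", {
  p <- toy_panel(2, 6)
  cl <- flat_climate("d1", 6)
  expect_error(quiet_design(p, cl, c(a1 = 100)),
               regexp = "a2", class = "spzip_linkage_error")
  cl_bad <- flat_climate("dX", 6)
  expect_error(quiet_design(p, cl_bad, c(a1 = 100, a2 = 200)),
               regexp = "d1", class = "spzip_linkage_error")
})
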