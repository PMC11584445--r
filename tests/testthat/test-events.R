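make_csv <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "events.csv")
  writeLines(lines, path)
  path
}

test_that("event tables sort by strain and break ties by energy", {
  ev <- ae_events(strain = c(0.3, 0.1, 0.2), energy = c(1, 2, 3))
  expect_equal(ev$strain, c(0.1, 0.2, 0.3))
  expect_equal(ev$energy, c(2, 3, 1))
  tie <- ae_events(strain = c(0.2, 0.2, 0.1), energy = c(1, 5, 2))
  expect_equal(tie$energy, c(2, 5, 1))    # tie at 0.2 kept, high energy first
  expect_error(ae_events(c(-0.1, 0.2), c(1, 1)), "strain")
  expect_error(ae_events(c(0.1, 0.2), c(0, 1)), "energ")
})

test_that("reading a well-formed table returns sorted events", {
  path <- make_csv(c("strain,energy,channel",
                     "0.30,5.0,central",
                     "0.10,2.0,central",
                     "0.20,9.0,guard_left"))
  ev <- read_ae_events(path)
  expect_s3_class(ev, "ae_events")
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$strain, c(0.1, 0.2, 0.3))
  expect_equal(ev$channel, c("central", "guard_left", "central"))
  expect_identical(attr(ev, "specimen_id"), "events")
})

test_that("degenerate and malformed tables are handled per contract", {
  empty <- make_csv("strain,energy,channel")
  expect_equal(nrow(read_ae_events(empty)), 0L)
  nostrain <- make_csv(c("stress,energy,channel", "1,2,c"))
  expect_error(read_ae_events(nostrain), "strain")
  badnum <- make_csv(c("strain,energy,channel", "0.1,2,c", "x,3,c"))
  expect_error(read_ae_events(badnum), "row 2")
})

test_that("read-write-read round trip is idempotent", {
  dir <- withr::local_tempdir()
  path <- make_csv(c("strain,energy,channel",
                     "0.1,2.5,central", "0.2,1.25,guard_left"), dir)
  ev1 <- read_ae_events(path)
  out <- file.path(dir, "copy.csv")
  write_ae_events(ev1, out)
  ev2 <- read_ae_events(out, specimen_id = attr(ev1, "specimen_id"))
  expect_equal(as.data.frame(ev1), as.data.frame(ev2))
  write_ae_events(ev2, out)
  ev3 <- read_ae_events(out, specimen_id = attr(ev2, "specimen_id"))
  expect_equal(as.data.frame(ev3), as.data.frame(ev2))
})

test_that("friction filtering excludes guard channels and weak signals", {
  ev <- ae_events(strain = c(0.1, 0.2, 0.3, 0.4, 0.5),
                  energy = c(5, 0.2, 7, 0.3, 9),
                  channel = c("central", "guard_left", "central",
                              "guard_right", "central"))
  kept <- filter_friction_events(ev, c("guard_left", "guard_right"), 0)
  expect_equal(nrow(kept), 3L)
  expect_true(all(kept$channel == "central"))
  # all below the energy floor
  expect_equal(nrow(filter_friction_events(ev, character(), e_min = 100)), 0L)
  # no guards, zero floor: identity
  expect_equal(as.data.frame(filter_friction_events(ev, character(), 0)),
               as.data.frame(ev))
})

test_that("friction filtering is idempotent and monotone in the threshold", {
  set.seed(9)
  ev <- ae_events(strain = sort(runif(40)), energy = rexp(40, 0.5),
                  channel = sample(c("central", "guard_left"), 40, TRUE))
  f1 <- filter_friction_events(ev, "guard_left", e_min = 1)
  f2 <- filter_friction_events(f1, "guard_left", e_min = 1)
  expect_equal(as.data.frame(f1), as.data.frame(f2))
  for (e in c(0, 0.5, 1, 2, 4)) {
    lo <- filter_friction_events(ev, "guard_left", e_min = e)
    hi <- filter_friction_events(ev, "guard_left", e_min = e + 1)
    expect_true(all(hi$strain %in% lo$strain))     # larger floor => subset
  }
})

test_that("event count and fracture strain observables", {
  ev <- ae_events(strain = c(0.1, 0.3), energy = c(1, 2))
  expect_equal(n_ae(ev), 2L)
  expect_equal(eps_max(ev), 0.3)
  empty <- filter_friction_events(ev, e_min = 10)
  expect_equal(n_ae(empty), 0L)
  expect_true(is.na(eps_max(empty)))
})

test_that("specimen records round trip at full float precision", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "records.csv")
  rec <- data.frame(specimen_id = "S01", age = 50.9, bmi = 32.6,
                    alpha = 1 / 3, lambda = exp(pi), beta = -log(1 / 3),
                    nu = 1.6180339887498949, e_m = 1, n_ae = 123L,
                    eps_max = 0.04321, mu_inf = 0.05, phi_min = 1e-9,
                    converged = TRUE, stringsAsFactors = FALSE)
  write_specimen_records(rec, path)
  back <- read_specimen_records(path)
  expect_identical(back$specimen_id, "S01")
  expect_identical(back$alpha, rec$alpha)          # bit-exact floats
  expect_identical(back$lambda, rec$lambda)
  expect_identical(back$converged, TRUE)
})

test_that("records with missing fits write nulls and append as rows", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "records.csv")
  rec <- list(specimen_id = "S02", age = 40, bmi = 30, n_ae = 10,
              eps_max = 0.02)
  write_specimen_records(rec, path)
  back <- read_specimen_records(path)
  expect_true(is.na(back$alpha))
  expect_true(is.na(back$nu))
  write_specimen_records(data.frame(specimen_id = "S03", age = 60, bmi = 35),
                         path, append = TRUE)
  expect_equal(nrow(read_specimen_records(path)), 2L)
})

test_that("metadata tables validate their columns and domains", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "meta.csv")
  meta <- data.frame(specimen_id = c("a", "b"), age = c(26, 62),
                     bmi = c(24.2, 42.7))
  write_specimen_meta(meta, path)
  expect_equal(read_specimen_meta(path), meta)
  writeLines(c("specimen_id,age,bmi", "a,-3,20"), path)
  expect_error(read_specimen_meta(path), "age")
  writeLines(c("specimen_id,years", "a,50"), path)
  expect_error(read_specimen_meta(path), "lacks")
})
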