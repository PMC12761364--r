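test_that("pKi conversion follows -log10(Ki) and rejects bad records", {
  a <- as_activities(data.frame(id = c("a", "b"), ki = c(1e-7, 2.0e-8)))
  expect_equal(a$pki[1], 7.0)
  expect_equal(a$pki[2], 7.69897000433602, tolerance = 1e-12)

  expect_error(as_activities(data.frame(id = "a", ki = 0)), "ki must be > 0")
  expect_error(as_activities(data.frame(id = "a", ki = -1e-8)), "ki must be > 0")
  expect_error(as_activities(data.frame(id = "a", ki = 1e-7, pki = 6.5)),
               "inconsistent")
  expect_silent(as_activities(data.frame(id = "a", ki = 1e-7, pki = 7)))
  expect_error(as_activities(data.frame(id = "a", foo = 1)), "ki")

  # strictly decreasing in Ki
  set.seed(4)
  ki <- sort(10^runif(25, -9, -5))
  pki <- as_activities(data.frame(id = as.character(1:25), ki = ki))$pki
  expect_true(all(diff(pki) < 0))
})

test_that("SDF round-trip preserves atoms, bonds and coordinates", {
  sks <- toy_sketches()
  tf <- withr::local_tempfile(fileext = ".sdf")
  write_sketches(sks, tf, "sdf")
  rd <- read_sketches(tf, "sdf")
  expect_length(rd, 2)
  for (i in 1:2) {
    expect_identical(rd[[i]]$id, sks[[i]]$id)
    expect_identical(rd[[i]]$atoms$element, sks[[i]]$atoms$element)
    expect_equal(rd[[i]]$atoms$x, sks[[i]]$atoms$x, tolerance = 1e-4)
    expect_equal(rd[[i]]$atoms$y, sks[[i]]$atoms$y, tolerance = 1e-4)
    expect_equal(as.numeric(rd[[i]]$bonds$a1), as.numeric(sks[[i]]$bonds$a1))
    expect_equal(as.numeric(rd[[i]]$bonds$order), as.numeric(sks[[i]]$bonds$order))
  }
  # duplicate ids rejected
  tf2 <- withr::local_tempfile(fileext = ".sdf")
  write_sketches(list(sks[[1]], sks[[1]]), tf2, "sdf")
  expect_error(read_sketches(tf2, "sdf"), "duplicate")
})

test_that("MOL2 round-trip preserves atoms, bonds and coordinates", {
  sks <- toy_sketches()
  tf <- withr::local_tempfile(fileext = ".mol2")
  write_sketches(sks, tf, "mol2")
  rd <- read_sketches(tf, "mol2")
  expect_length(rd, 2)
  for (i in 1:2) {
    expect_identical(rd[[i]]$id, sks[[i]]$id)
    expect_identical(rd[[i]]$atoms$element, sks[[i]]$atoms$element)
    expect_equal(rd[[i]]$atoms$x, sks[[i]]$atoms$x, tolerance = 1e-4)
    expect_equal(rd[[i]]$atoms$y, sks[[i]]$atoms$y, tolerance = 1e-4)
    expect_equal(as.numeric(rd[[i]]$bonds$a2), as.numeric(sks[[i]]$bonds$a2))
  }
})

test_that("3D (non-constant z) records are rejected with advice to flatten", {
  lines <- c("mol3d", "  prog", "",
             "  2  1  0  0  0  0  0  0  0  0999 V2000",
             "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
             "    1.0000    0.0000    1.5000 C   0  0  0  0  0  0  0  0  0  0  0  0",
             "  1  2  1  0  0  0  0", "M  END", "$$$$")
  tf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(lines, tf)
  expect_error(read_sketches(tf, "sdf"), "flatten")
})

test_that("core alignment check measures deviation against the reference", {
  sks <- toy_sketches()
  core <- 1:3
  al <- check_alignment(sks, core, tol = 1e-3)
  expect_true(al$pass)
  expect_equal(unname(al$max_deviation), c(0, 0))

  shifted <- sks
  shifted[[2]]$atoms$x <- shifted[[2]]$atoms$x + 2e-3
  al2 <- check_alignment(shifted, core, tol = 1e-3)
  expect_false(al2$pass)
  expect_gt(al2$max_deviation[["cmp2"]], 1e-3)

  expect_error(check_alignment(sks, c(1, 99)), "core atom missing")

  # generator jitter below tolerance still passes
  ds <- generate_dataset(generator_config(n_samples = 10, jitter_sd = 1e-4,
                                          seed = 3))
  expect_true(check_alignment(ds$sketches, core_atom_indices(),
                              tol = 1e-3)$pass)
})

test_that("element property lookups never fall back silently", {
  props <- load_property_table()
  expect_equal(element_property(props, "C", "epsilon"), 2.55)
  expect_equal(element_property(props, "Cl", "r_vdw"), 1.75)
  expect_equal(props["O", "ratio"], 1.52 / 3.44)
  expect_error(element_property(props, "Xx", "r_vdw"), "not in property table")
  expect_true(all(props$epsilon > 0) && all(props$r_vdw > 0))
})

test_that("activity join warns about orphans on either side", {
  sks <- toy_sketches()
  acts <- as_activities(data.frame(id = c("cmp1", "cmp2", "ghost"),
                                   pki = c(7, 7.5, 6)))
  expect_warning(j <- match_activities(sks, acts), "ghost")
  expect_equal(j$y, c(7, 7.5))
  acts2 <- as_activities(data.frame(id = "cmp1", pki = 7))
  expect_warning(j2 <- match_activities(sks, acts2), "cmp2")
  expect_length(j2$sketches, 1)
})
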