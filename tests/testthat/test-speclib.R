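test_that("MGF round trips preserve peaks and metadata", {
  set.seed(3)
  lib <- simulate_library(10, seed = 3,
                          config = sim_config(noise_sigma_mz = 0.005))
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(lib$spectra, f)
  back <- read_mgf(f)
  expect_length(back, 10)
  for (i in 1:10) {
    expect_equal(round(lib$spectra[[i]]$peaks$mz, 4), back[[i]]$peaks$mz)
    expect_identical(back[[i]]$id, lib$spectra[[i]]$id)
    expect_identical(back[[i]]$charge, lib$spectra[[i]]$charge)
    expect_identical(back[[i]]$metadata$NAME, lib$spectra[[i]]$metadata$NAME)
    if (!is.na(lib$spectra[[i]]$rt)) {
      expect_equal(back[[i]]$rt, lib$spectra[[i]]$rt, tolerance = 1e-4)
    }
  }
  # byte-idempotence of the normalised dialect
  f2 <- withr::local_tempfile(fileext = ".mgf")
  f3 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(back, f2)
  write_mgf(read_mgf(f2), f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("MGF edge cases: empty file, negative charge, malformed input", {
  f <- withr::local_tempfile(fileext = ".mgf")
  writeLines(character(0), f)
  expect_identical(read_mgf(f), list())
  writeLines(c("BEGIN IONS", "TITLE=t", "PEPMASS=621.0", "CHARGE=2-",
               "100.0 1", "END IONS"), f)
  sp <- read_mgf(f)[[1]]
  expect_identical(sp$charge, 2L)
  expect_identical(sp$polarity, "negative")
  writeLines(c("BEGIN IONS", "TITLE=t", "100.0 1", "END IONS"), f)
  expect_warning(out <- read_mgf(f), "PEPMASS")
  expect_length(out, 0)
  writeLines(c("BEGIN IONS", "PEPMASS=1", "oops peak", "END IONS"), f)
  expect_error(read_mgf(f), "Line 3")
  writeLines(c("BEGIN IONS", "PEPMASS=1", "100 1"), f)
  expect_error(read_mgf(f), "never closed")
})

test_that("negative-charge notation agrees with the pyteomics reference parser", {
  f <- withr::local_tempfile(fileext = ".mgf")
  sp <- ms_spectrum(c(96.9601, 241.0, 987.27), c(50, 30, 100),
                    precursor_mz = 621.21, charge = 2L,
                    polarity = "negative", rt = 7.4, id = "ref_check")
  write_mgf(list(sp), f)
  py <- paste(
    "import json, sys",
    "from pyteomics import mgf",
    "with mgf.MGF(sys.argv[1]) as r: s = next(iter(r))",
    "print(json.dumps({'charge': int(s['params']['charge'][0]),",
    "  'pepmass': s['params']['pepmass'][0],",
    "  'mz': list(s['m/z array'])}))",
    sep = "\n"
  )
  pf <- withr::local_tempfile(fileext = ".py")
  writeLines(py, pf)
  out <- system2("python", c(pf, f), stdout = TRUE)
  ref <- jsonlite::fromJSON(out)
  expect_identical(ref$charge, -2L)  # pyteomics encodes '2-' as -2
  expect_equal(ref$pepmass, 621.21, tolerance = 1e-6)
  expect_equal(ref$mz, sp$peaks$mz, tolerance = 1e-4)
})

test_that("cosine score: self-match, disjoint, and oracle equality on toys", {
  a <- toy_spectrum(c(100, 200, 300), c(10, 50, 100), precursor = 500)
  expect_equal(cosine_score(a, a)$score, 1, tolerance = 1e-12)
  expect_identical(cosine_score(a, a)$n_matched, 3L)
  b <- toy_spectrum(c(150, 250, 350), c(10, 50, 100), precursor = 500)
  expect_identical(cosine_score(a, b)$score, 0)
  # symmetric
  cc <- toy_spectrum(c(100.01, 200.02, 310), c(20, 40, 90), precursor = 500)
  expect_equal(cosine_score(a, cc)$score, cosine_score(cc, a)$score,
               tolerance = 1e-12)
  # 3-peak toys vs exhaustive optimal assignment
  set.seed(9)
  for (rep in 1:20) {
    mza <- sort(runif(3, 100, 500)); ia <- runif(3, 1, 100)
    mzb <- sort(mza + rnorm(3, 0, 0.03)); ib <- runif(3, 1, 100)
    got <- cosine_score(toy_spectrum(mza, ia, precursor = 600),
                        toy_spectrum(mzb, ib, precursor = 600), 0.05)$score
    ref <- ref_assignment_cosine(mza, ia, mzb, ib, 0.05)
    expect_lte(got, ref + 1e-12)
    expect_equal(got, ref, tolerance = 1e-9)
  }
  # empty spectrum scores 0
  e <- ms_spectrum(numeric(0), numeric(0), precursor_mz = 100)
  expect_identical(cosine_score(a, e)$score, 0)
})

test_that("library search ranks by RT gate then cosine", {
  set.seed(12)
  lib <- simulate_library(15, seed = 12,
                          config = sim_config(noise_sigma_mz = 0.003))
  # query = a record with RT shifted by +0.1 min: top hit, gate passed
  q <- lib$spectra[[4]]
  q$rt <- q$rt + 0.1
  q$id <- "query"
  res <- library_search(q, lib$spectra, rt_tol = 0.3)
  expect_identical(res$record_id[1], lib$spectra[[4]]$id)
  expect_true(res$passed_rt_gate[1])
  expect_equal(res$rt_delta_min[1], 0.1, tolerance = 1e-9)

  # three isomers: same precursor, near-identical spectra, distinct RTs
  base <- lib$spectra[[4]]
  isomers <- lapply(1:3, function(k) {
    s <- base
    s$id <- paste0("isomer_", k)
    s$rt <- c(6.3, 8.1, 12.4)[k]
    s
  })
  q2 <- base
  q2$id <- "q2"
  q2$rt <- 8.2
  res2 <- library_search(q2, isomers, rt_tol = 0.3)
  expect_identical(res2$record_id[1], "isomer_2")
  expect_true(res2$passed_rt_gate[1])
  expect_false(any(res2$passed_rt_gate[-1]))

  # empty candidate set after the precursor filter
  q3 <- base
  q3$precursor_mz <- base$precursor_mz + 50
  expect_identical(nrow(library_search(q3, isomers)), 0L)
  expect_error(library_search(q2, list()), "empty")
})

test_that("library self-search returns every record as its own top hit", {
  lib <- simulate_library(12, seed = 31)
  for (sp in lib$spectra) {
    res <- library_search(sp, lib$spectra)
    expect_identical(res$record_id[1], sp$id)
    expect_equal(res$cosine[1], 1, tolerance = 1e-9)
  }
})

test_that("library records check structure/precursor consistency", {
  g <- glycoside("x", aglycon(mass = 500.1234, lactone = "none"), "Xyl-Qui")
  good_mz <- precursor_mz(g)$mz
  sp <- toy_spectrum(c(100, 200), precursor = good_mz, id = "ok")
  expect_silent(library_record(sp, g))
  sp_bad <- toy_spectrum(c(100, 200), precursor = good_mz + 0.5, id = "off")
  expect_warning(library_record(sp_bad, g), "20 ppm")
})

test_that("mzML reading recovers the written centroided peak list", {
  f <- withr::local_tempfile(fileext = ".mzML")
  mz <- c(96.9601, 241.0, 987.27, 1163.45)
  it <- c(50, 30, 100, 20)
  mini_mzml(f, mz, it, precursor = 1163.45, charge = 1, rt_min = 8.4)
  sp <- read_mzml(f)
  expect_length(sp, 1)
  expect_equal(sp[[1]]$peaks$mz, mz, tolerance = 1e-6)
  expect_equal(sp[[1]]$peaks$intensity, it, tolerance = 1e-6)
  expect_equal(sp[[1]]$precursor_mz, 1163.45, tolerance = 1e-6)
  expect_equal(sp[[1]]$rt, 8.4, tolerance = 1e-3)
})
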