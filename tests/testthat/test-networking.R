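test_that("modified cosine degenerates to plain cosine at zero shift", {
  a <- toy_spectrum(c(100, 200, 300, 400), c(5, 50, 100, 20), precursor = 500)
  b <- toy_spectrum(c(100.01, 200.03, 305, 400.02), c(10, 40, 80, 30),
                    precursor = 500)
  expect_equal(modified_cosine(a, b)$score, cosine_score(a, b)$score,
               tolerance = 1e-12)
})

test_that("a uniformly shifted copy scores 1 under the modified cosine", {
  a <- toy_spectrum(c(100, 200, 300), c(10, 50, 100), precursor = 500)
  b <- toy_spectrum(c(158, 258, 358), c(10, 50, 100), precursor = 558)
  mc <- modified_cosine(a, b)
  expect_equal(mc$score, 1, tolerance = 1e-12)
  expect_identical(mc$n_matched, 3L)
  expect_equal(mc$delta_mz, 58)
})

test_that("modified cosine equals the exhaustive assignment oracle on toys", {
  set.seed(17)
  for (rep in 1:15) {
    mza <- sort(runif(4, 100, 500)); ia <- runif(4, 1, 100)
    shift <- sample(c(0, 58, 162), 1)
    mzb <- sort(c(mza[1:2] + rnorm(2, 0, 0.02),
                  mza[3:4] + shift + rnorm(2, 0, 0.02)))
    ib <- runif(4, 1, 100)
    a <- toy_spectrum(mza, ia, precursor = 600)
    b <- toy_spectrum(mzb, ib, precursor = 600 + shift)
    got <- modified_cosine(a, b, frag_tol = 0.05)$score
    ref <- ref_assignment_cosine(mza, ia, mzb, ib, 0.05, shift = shift)
    expect_lte(got, ref + 1e-12)
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("two identical spectra give a single unit edge", {
  a <- toy_spectrum(seq(100, 800, by = 100), rep(50, 8), precursor = 900,
                    id = "a")
  b <- a; b$id <- "b"
  net <- build_network(list(a, b))
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$cosine, 1, tolerance = 1e-12)
  expect_identical(net$edges$n_matched, 8L)
})

test_that("network filters match a brute-force reference on synthetic spectra", {
  lib <- simulate_library(20, seed = 11,
                          config = sim_config(noise_sigma_mz = 0.005))
  sp <- lib$spectra
  net <- build_network(sp, cosine_min = 0.5, min_matched = 5)
  ids <- sort(vapply(sp, function(s) s$id, ""))
  spo <- sp[order(vapply(sp, function(s) s$id, ""))]
  sc <- list()
  for (i in 1:19) for (j in (i + 1):20) {
    mc <- modified_cosine(spo[[i]], spo[[j]])
    sc[[length(sc) + 1]] <- data.frame(a = ids[i], b = ids[j],
                                       s = mc$score, m = mc$n_matched)
  }
  ref <- ref_filter_edges(do.call(rbind, sc), 0.5, 5, 10)
  expect_setequal(paste(net$edges$source, net$edges$target),
                  paste(ref$a, ref$b))
})

test_that("edge filters are monotone in the cosine threshold", {
  lib <- simulate_library(15, seed = 23,
                          config = sim_config(noise_sigma_mz = 0.01))
  lo <- build_network(lib$spectra, cosine_min = 0.3, min_matched = 4)
  hi <- build_network(lib$spectra, cosine_min = 0.6, min_matched = 4)
  key <- function(n) paste(n$edges$source, n$edges$target)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("the network is invariant to the input ordering", {
  lib <- simulate_library(12, seed = 29,
                          config = sim_config(noise_sigma_mz = 0.005))
  n1 <- build_network(lib$spectra, cosine_min = 0.4, min_matched = 4)
  set.seed(1)
  n2 <- build_network(sample(lib$spectra), cosine_min = 0.4, min_matched = 4)
  expect_identical(n1$edges$source, n2$edges$source)
  expect_identical(n1$edges$target, n2$edges$target)
  expect_equal(n1$edges$cosine, n2$edges$cosine, tolerance = 1e-12)
})

test_that("family-size capping keeps every component within the limit", {
  # a clique of near-identical spectra larger than the cap
  set.seed(4)
  base_mz <- seq(150, 750, by = 100)
  sp <- lapply(1:120, function(k) {
    toy_spectrum(base_mz, 50 + runif(7, -5, 5), precursor = 900,
                 id = sprintf("n%03d", k))
  })
  net <- build_network(sp, cosine_min = 0.7, min_matched = 7,
                       top_k = 10, max_family = 40)
  expect_true(all(table(net$nodes$component) <= 40))
})

test_that("edge-list export round-trips losslessly", {
  lib <- simulate_library(10, seed = 37,
                          config = sim_config(noise_sigma_mz = 0.005))
  net <- build_network(lib$spectra, cosine_min = 0.3, min_matched = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network_edges(net, f)
  back <- read_network_edges(f)
  expect_identical(back$source, net$edges$source)
  expect_identical(back$target, net$edges$target)
  expect_equal(back$cosine, net$edges$cosine, tolerance = 1e-9)
  expect_identical(back$n_matched, net$edges$n_matched)
  g <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, g)
  gg <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::gorder(gg), nrow(net$nodes))
  expect_equal(igraph::gsize(gg), nrow(net$edges))
})
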