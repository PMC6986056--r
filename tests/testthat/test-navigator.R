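test_that("catalog filters are conjunctive, idempotent and total", {
  catalog <- make_catalog(pi = c(-0.5, 1.2, 0.3), sigma = c(-0.3, 0.2, 0.7),
                          freq = c(60L, 10L, 3L),
                          smiles = c("[*]OC", "[*]C", "[*]CN"),
                          root_class = c("R-O", "R-C", "R-C"),
                          heavy = c(2L, 1L, 9L))
  q <- query_spec(root_filter = "R-O")
  expect_equal(filter_catalog(catalog, q)$smiles, "[*]OC")
  q2 <- query_spec(max_heavy = 8, sigma_range = c(-Inf, -0.2),
                   pi_range = c(-Inf, 0.5))
  hits <- filter_catalog(catalog, q2)
  brute <- catalog[catalog$heavy_atoms <= 8 & catalog$sigma <= -0.2 &
                     catalog$pi <= 0.5, ]
  expect_equal(hits$smiles, brute$smiles)
  # idempotence and subset property
  expect_equal(filter_catalog(hits, q2)$smiles, hits$smiles)
  expect_true(all(hits$smiles %in% catalog$smiles))
  # contradictory ranges: empty result, no error
  q3 <- query_spec(pi_range = c(2, 3), sigma_range = c(-1, -0.9))
  expect_equal(nrow(filter_catalog(catalog, q3)), 0L)
  expect_error(query_spec(pi_range = c(1, 0)), "lo <= hi")
})

test_that("attachment filters use profile shares", {
  catalog <- make_catalog(pi = c(0, 0), sigma = c(0, 0), freq = c(10L, 10L))
  catalog$att_c <- c(9L, 2L)
  catalog$att_Nn <- c(1L, 8L)
  modal_c <- filter_catalog(catalog, query_spec(attachment_filter = "c"))
  expect_equal(modal_c$smiles, catalog$smiles[1])
  share <- filter_catalog(catalog,
                          query_spec(attachment_filter = "N,n",
                                     attachment_min_share = 0.5))
  expect_equal(share$smiles, catalog$smiles[2])
  expect_error(filter_catalog(catalog,
                              query_spec(attachment_filter = "zz")),
               "zz")
})

test_that("nearest neighbours match brute force over random catalogs", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 50
    catalog <- make_catalog(pi = stats::rnorm(n, 0, 2),
                            sigma = stats::rnorm(n, 0, 0.5),
                            freq = sample(1:200, n, replace = TRUE))
    target <- list(pi = stats::rnorm(1), sigma = stats::rnorm(1))
    got <- nearest_bioisosteres(catalog, target, k = 5)
    sds <- c(stats::sd(catalog$pi), stats::sd(catalog$sigma))
    d <- sqrt(((catalog$pi - target$pi) / sds[1])^2 +
                ((catalog$sigma - target$sigma) / sds[2])^2)
    ord <- order(d, -catalog$molecule_frequency, catalog$smiles)
    expect_equal(got$smiles, catalog$smiles[ord[1:5]])
    expect_true(all(diff(got$distance) >= 0))
  }
})

test_that("self-match, oversized k and scaling behave as documented", {
  catalog <- make_catalog(pi = c(0, 1, 4), sigma = c(0, 0.1, 0.2),
                          smiles = canonical_smiles(c("[*]C", "[*]CC",
                                                      "[*]CCC")))
  catalog$pi[1] <- compute_pi("[*]C")
  self <- nearest_bioisosteres(catalog, "[*]C", k = 1, include_self = TRUE)
  expect_equal(self$smiles, canonical_smiles("[*]C"))
  expect_equal(self$distance, 0)
  noself <- nearest_bioisosteres(catalog, "[*]C", k = 1)
  expect_false(noself$smiles == canonical_smiles("[*]C"))
  expect_warning(all3 <- nearest_bioisosteres(catalog, list(pi = 0,
                                                            sigma = 0),
                                              k = 10),
                 "catalog size")
  expect_equal(nrow(all3), 3L)
})

test_that("raw and standardized scaling can rank differently", {
  # anisotropic: along pi the units dwarf sigma unless standardized
  catalog <- make_catalog(pi = c(0.9, 0.0), sigma = c(0.0, 0.35),
                          freq = c(1L, 1L))
  target <- list(pi = 0, sigma = 0)
  raw <- nearest_bioisosteres(catalog, target, k = 1, scaling = "raw")
  std <- nearest_bioisosteres(catalog, target, k = 1,
                              scaling = "standardize")
  expect_false(raw$smiles == std$smiles)
})

test_that("quadrants follow the sign table", {
  expect_equal(quadrant_of(0.5, 0.7), "pi+sigma+")
  expect_equal(quadrant_of(-0.3, 0.7), "pi-sigma+")
  expect_equal(quadrant_of(0.5, -0.7), "pi+sigma-")
  expect_equal(quadrant_of(-0.5, -0.7), "pi-sigma-")
  expect_equal(quadrant_of(0, 0.7), "boundary")
  expect_equal(quadrant_of(0.2, 0), "boundary")
  expect_equal(quadrant_of(c(1, 1)), "pi+sigma+")
  expect_error(quadrant_of(NA_real_, 1))
})

maxmin_objective <- function(pm, picked) {
  if (length(picked) < 2) return(Inf)
  d <- as.matrix(stats::dist(pm[picked, , drop = FALSE]))
  min(d[upper.tri(d)])
}

test_that("diverse selection is exact for small n and spans quadrants", {
  corners <- make_catalog(pi = c(2, 2, -2, -2), sigma = c(1, -1, 1, -1),
                          freq = c(4L, 3L, 2L, 1L))
  sel <- diverse_selection(corners, 4)
  expect_same_multiset(sel$smiles, corners$smiles)

  # greedy matches the exhaustive max-min optimum for n <= 3, <= 12 points
  for (seed in 1:5) {
    set.seed(seed)
    n <- 12
    catalog <- make_catalog(pi = stats::rnorm(n, 0, 2),
                            sigma = stats::rnorm(n, 0, 0.5),
                            freq = sample(1:50, n, replace = TRUE))
    pm <- cbind(catalog$pi / stats::sd(catalog$pi),
                catalog$sigma / stats::sd(catalog$sigma))
    sel3 <- diverse_selection(catalog, 3)
    got <- maxmin_objective(pm, match(sel3$smiles, catalog$smiles))
    best <- max(apply(utils::combn(n, 3), 2, maxmin_objective, pm = pm))
    expect_equal(got, best, tolerance = 1e-12)
  }

  # identity when n equals the catalog size
  expect_equal(nrow(diverse_selection(corners, 10)), 4L)

  # quadrant coverage of the first four picks
  set.seed(99)
  catalog <- make_catalog(pi = c(stats::runif(5, 0.5, 2),
                                 stats::runif(5, -2, -0.5)),
                          sigma = rep(c(0.5, -0.5), 5),
                          freq = sample(1:50, 10))
  sel4 <- diverse_selection(catalog, 4)
  quads <- mapply(quadrant_of, sel4$pi, sel4$sigma)
  expect_gte(length(unique(quads)), 3L)
})

test_that("diverse selection beats random selection in expectation", {
  set.seed(123)
  n <- 30
  catalog <- make_catalog(pi = stats::rnorm(n, 0, 2),
                          sigma = stats::rnorm(n, 0, 0.5),
                          freq = sample(1:50, n, replace = TRUE))
  pm <- cbind(catalog$pi / stats::sd(catalog$pi),
              catalog$sigma / stats::sd(catalog$sigma))
  sel <- diverse_selection(catalog, 5)
  obj_greedy <- maxmin_objective(pm, match(sel$smiles, catalog$smiles))
  obj_random <- replicate(20, maxmin_objective(pm, sample.int(n, 5)))
  expect_gt(obj_greedy, mean(obj_random))
})

test_that("craig plot data and rendering keep the point contract", {
  n <- 26
  set.seed(5)
  catalog <- make_catalog(pi = stats::rnorm(n), sigma = stats::rnorm(n),
                          freq = sample(1:500, n, replace = TRUE))
  pd <- craig_plot_data(catalog)
  expect_equal(nrow(pd), n)
  # size encoding is monotone in frequency
  ord <- order(pd$molecule_frequency)
  expect_true(all(diff(pd$size[ord]) >= 0))

  path <- withr::local_tempfile(fileext = ".png")
  res <- render_craig_plot(pd, path)
  expect_true(file.exists(res$figure))
  sidecar <- utils::read.delim(res$sidecar)
  expect_equal(nrow(sidecar), n)
  # axis ranges cover the data with margin
  expect_true(min(sidecar$pi) >= min(catalog$pi) - 1e-9)
  expect_error(render_craig_plot(pd[0, ], withr::local_tempfile(
    fileext = ".png")), "empty")
})
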