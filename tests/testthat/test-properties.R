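test_that("atom-contribution logP is additive and permutation-invariant", {
  lp <- logp_atom_contrib(c("C", "CC", "CCC", "c1ccccc1", "Cc1ccccc1"))
  expect_equal(lp[2] - lp[1], lp[3] - lp[2], tolerance = 1e-10)
  expect_gt(lp[5], lp[4])
  expect_equal(logp_atom_contrib("CC(C)O"), logp_atom_contrib("OC(C)C"),
               tolerance = 1e-12)
})

test_that("probes are the correct mono-substituted benzenes", {
  expect_equal(canonical_smiles(attr(build_probe("[*]C"), "smiles")),
               canonical_smiles("Cc1ccccc1"))
  expect_equal(canonical_smiles(attr(build_probe("[*][H]"), "smiles")),
               canonical_smiles("c1ccccc1"))
  expect_equal(canonical_smiles(attr(build_probe("[*]N(C)C"), "smiles")),
               canonical_smiles("CN(C)c1ccccc1"))
  probe <- build_probe("[*]OC")
  para <- attr(probe, "para")
  expect_equal(probe$atoms$element[para], "C")
  expect_true(probe$atoms$aromatic[para])
  expect_equal(probe$atoms$nH[para], 1L)
})

test_that("pi follows the probe-minus-benzene contract", {
  expect_identical(compute_pi("[*][H]"), 0)
  direct <- logp_atom_contrib("Cc1ccccc1") - logp_atom_contrib("c1ccccc1")
  expect_equal(compute_pi("[*]C"), direct, tolerance = 1e-12)
  alkyl <- compute_pi(c("[*]C", "[*]CC", "[*]CCC"))
  expect_true(all(diff(alkyl) > 0))
})

test_that("PEOE charges behave physically", {
  benz <- parse_smiles("c1ccccc1")
  q <- peoe_charges(benz)
  expect_equal(max(abs(q$q_heavy - q$q_heavy[1])), 0, tolerance = 1e-9)
  expect_equal(sum(q$q_heavy) + sum(q$q_h), 0, tolerance = 1e-6)
  expect_lt(q$iterations, 200L)
  # charge conservation with formal charges
  nitro <- parse_smiles("[O-][N+](=O)C")
  qn <- peoe_charges(nitro)
  expect_equal(sum(qn$q_heavy) + sum(qn$q_h), 0, tolerance = 1e-6)
  # electronegativity ordering: O pulls more than C
  meoh <- parse_smiles("CO")
  qm <- peoe_charges(meoh)
  expect_lt(qm$q_heavy[2], 0)
  expect_gt(qm$q_heavy[1], 0)
})

test_that("Huckel pi charges capture donation and withdrawal", {
  benz <- parse_smiles("c1ccccc1")
  expect_equal(huckel_pi_charges(benz), rep(0, 6), tolerance = 1e-9)
  pyr <- parse_smiles("c1ccncc1")
  qp <- huckel_pi_charges(pyr)
  n_at <- which(pyr$atoms$element == "N")
  expect_lt(qp[n_at], 0)           # ring N accumulates pi density
  ani <- build_probe("[*]N")
  qa <- huckel_pi_charges(ani)
  expect_lt(qa[attr(ani, "para")], 0)   # amino pushes density to para
  nb <- build_probe("[*][N+](=O)[O-]")
  qn <- huckel_pi_charges(nb)
  expect_gt(qn[attr(nb, "para")], 0)    # nitro drains it
})

test_that("the charge descriptor separates donors from acceptors", {
  expect_identical(charge_descriptor("[*][H]"), 0)
  expect_gt(charge_descriptor("[*][N+](=O)[O-]"), 0)
  expect_lt(charge_descriptor("[*]N(C)C"), 0)
  ladder <- c("[*][N+](=O)[O-]", "[*]C#N", "[*]Cl", "[*][H]", "[*]C",
              "[*]OC", "[*]N(C)C")
  d <- vapply(ladder, charge_descriptor, 0)
  expect_true(all(diff(d) < 0))
  # purity: bit-identical on repeated evaluation
  expect_identical(charge_descriptor("[*]C#N"), charge_descriptor("[*]C#N"))
})

test_that("sigma calibration fits, predicts and degenerates as specified", {
  x <- c(-0.03, -0.01, 0.005, 0.02, 0.05)
  exact <- data.frame(descriptor = x, sigma_exp = 2 * x + 0.1)
  m <- fit_sigma_calibration(exact)
  expect_equal(m$slope, 2, tolerance = 1e-9)
  expect_equal(m$intercept, 0.1, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)

  two <- fit_sigma_calibration(data.frame(descriptor = c(0, 1),
                                          sigma_exp = c(0.3, 1.3)))
  expect_equal(two$r_squared, 1, tolerance = 1e-9)
  expect_equal(two$slope, 1, tolerance = 1e-9)

  expect_error(fit_sigma_calibration(
    data.frame(descriptor = c(1, 1, 1), sigma_exp = 1:3)), "degenerate")
  expect_error(fit_sigma_calibration(exact[1, , drop = FALSE]), "2")
})

test_that("calibration recovers known coefficients from noisy data", {
  set.seed(42)
  n <- 40
  x <- stats::rnorm(n, 0, 0.03)
  y <- 15 * x + 0.05 + stats::rnorm(n, 0, 0.05)
  m <- fit_sigma_calibration(data.frame(descriptor = x, sigma_exp = y))
  expect_lt(abs(m$slope - 15), 3 * m$slope_se)
  expect_lt(abs(m$intercept - 0.05), 3 * m$intercept_se)
})

test_that("calibration evaluation matches the definition of r-squared", {
  x <- c(-0.02, 0, 0.01, 0.04)
  pairs <- data.frame(descriptor = x, sigma_exp = 3 * x - 0.2)
  m <- fit_sigma_calibration(pairs)
  ev <- evaluate_calibration(m, pairs)
  expect_equal(ev$r_squared, 1, tolerance = 1e-9)
  expect_equal(ev$mae, 0, tolerance = 1e-9)
  # a constant predictor at the reference mean scores exactly zero
  flat <- structure(list(slope = 0, intercept = mean(pairs$sigma_exp)),
                    class = "sigma_calibration")
  expect_equal(evaluate_calibration(flat, pairs)$r_squared, 0,
               tolerance = 1e-9)
  expect_error(evaluate_calibration(m, pairs[1, , drop = FALSE]), "2")
})

test_that("noisy synthetic r-squared tracks the analytic expectation", {
  set.seed(7)
  n <- 400
  x <- stats::rnorm(n, 0, 1)
  sd_noise <- 0.5
  y <- x + stats::rnorm(n, 0, sd_noise)
  m <- fit_sigma_calibration(data.frame(descriptor = x, sigma_exp = y))
  r2_expected <- 1 / (1 + sd_noise^2)   # var(signal) / var(total)
  expect_equal(m$r_squared, r2_expected, tolerance = 0.05)
})

test_that("sigma is an affine map of the descriptor", {
  m <- structure(list(slope = 2, intercept = 0.1),
                 class = "sigma_calibration")
  expect_equal(compute_sigma("[*][H]", m), 0.1, tolerance = 1e-12)
  d <- charge_descriptor("[*]Cl")
  expect_equal(compute_sigma("[*]Cl", m), 2 * d + 0.1, tolerance = 1e-12)
})

test_that("the packaged literature calibration is sound", {
  m <- default_calibration()
  expect_gt(m$slope, 0)
  expect_gt(m$r_squared, 0.5)
  expect_gte(m$n_train, 20L)
  # sigma span: nitro vs dimethylamino bracket the scale
  s <- compute_sigma(c("[*][N+](=O)[O-]", "[*]N(C)C"), m)
  gap <- s[1] - s[2]
  others <- compute_sigma(c("[*]Cl", "[*][H]", "[*]C", "[*]OC"), m)
  all_s <- c(s, others)
  expect_equal(gap, max(outer(all_s, all_s, "-")), tolerance = 1e-9)
})

test_that("catalog annotation fills pi and sigma consistently", {
  mols <- setNames(c("Cc1ccccc1", "COc1ccccc1", "CC(=O)c1ccccc1"),
                   c("a", "b", "c"))
  catalog <- fragment_corpus(mols, min_molecule_freq = 1L)
  ann <- annotate_catalog(catalog)
  expect_true(all(is.finite(ann$pi)))
  expect_true(all(is.finite(ann$sigma)))
  # pi additivity holds entry by entry
  for (i in seq_len(nrow(ann))) {
    probe <- attr(build_probe(ann$smiles[i]), "smiles")
    expect_equal(ann$pi[i],
                 logp_atom_contrib(probe) - logp_atom_contrib("c1ccccc1"),
                 tolerance = 1e-9)
  }
})
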