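# Constraint inversion, planning grid and optimal-amount selection.

# random plausible kidney-like kinetic curve on the default horizon
random_curve <- function() {
  l1 <- stats::runif(1, 1e-3, 1e-2)   # uptake/washout of the fast phase
  l2 <- stats::runif(1, 2e-4, 6e-4)   # retention phase incl. physical decay
  w <- stats::runif(1, 0.2, 0.9)
  peak <- stats::runif(1, 0.01, 0.08)
  tt <- sort(unique(c(0, 10^seq(0, log10(3e4), length.out = 800))))
  data.frame(time_min = tt,
             value = peak * (w * exp(-l2 * tt) * (1 - exp(-l1 * tt)) +
                               (1 - w) * exp(-l1 * tt) * (1 - exp(-5 * l1 * tt))))
}

kidney_bed_at <- function(a, A, S, ab, mu, T = 3e4) {
  rate <- dose_rate(a, A, S)
  bed(absorbed_dose(rate, T), lea_catcheside(rate, mu, T), ab)
}

test_that("kidney constraint inversion is self-consistent and matches a root-finder", {
  S <- 4.6e-3; ab <- 2.5; mu <- log(2) / 168
  withr::with_seed(7, {
    for (i in 1:10) {
      a <- random_curve()
      A <- activity_for_kidney_bed(a, S, ab, mu, bed_fixed = 10)
      expect_gt(A, 0)
      # recomputing the BED at the returned activity reproduces the limit
      expect_equal(kidney_bed_at(a, A, S, ab, mu), 10, tolerance = 1e-4)
      # independent brute-force scalar root finder on BED(A) - 10
      Abrute <- stats::uniroot(function(x) kidney_bed_at(a, x, S, ab, mu) - 10,
                               c(1e-3, 1e4), tol = 1e-10)$root
      expect_equal(A, Abrute, tolerance = 1e-6)
    }
  })
})

test_that("large repair rates reduce the kidney inversion to the linear dose limit", {
  withr::with_seed(8, {
    a <- random_curve()
    S <- 4.6e-3
    A <- activity_for_kidney_bed(a, S, 2.5, mu = 1e4, bed_fixed = 10)
    expect_equal(A, 10 / (tiac(a) * S), tolerance = 1e-3)
  })
})

test_that("salivary constraint inversion is plain arithmetic", {
  # tiac * S chosen so the product is 1.5 Gy/GBq -> 5 GBq for 7.5 Gy
  expect_equal(activity_for_salivary_dose(1.5 / 2e-3, 2e-3, 7.5), 5)
  expect_equal(activity_for_salivary_dose(2 * 1.5 / 2e-3, 2e-3, 7.5), 2.5)
  expect_equal(10 * 2e-3 * activity_for_salivary_dose(10, 2e-3, 7.5), 7.5)
  expect_error(activity_for_salivary_dose(0, 1, 7.5), "division error")
})

grid_fixture <- function() {
  cached("planning_grid_small", {
    build_planning_grid(median_model(), constraint_set(),
                        amounts = 2^c(1, 5, 7, 9, 13),
                        solver = fast_solver())
  })
}

test_that("planning grid rows hit their constraint by construction", {
  grid <- grid_fixture()
  expect_equal(nrow(grid), 2 * 5)
  k <- grid[grid$case == "kidney", ]
  expect_equal(k$kidney_bed_gy, rep(10, nrow(k)), tolerance = 1e-4)
  s <- grid[grid$case == "salivary", ]
  expect_equal(s$salivary_dose_gy, rep(7.5, nrow(s)), tolerance = 1e-4)
  expect_true(all(grid$activity_gbq > 0))
})

test_that("select_optimal maximizes tumor BED with marrow exclusion and ties to smaller amounts", {
  grid <- grid_fixture()
  opt <- select_optimal(grid, "kidney", tumor = "tumor_1")
  expect_true(opt$feasible)
  k <- grid[grid$case == "kidney" & grid$marrow_ok, ]
  expect_equal(opt$tumor_bed_gy, max(k$tumor_1_bed_gy))
  # marrow flag everywhere -> infeasible
  g2 <- grid
  g2$marrow_ok <- FALSE
  expect_false(select_optimal(g2, "kidney")$feasible)
  # exact tie broken toward the smaller amount
  g3 <- grid[grid$case == "kidney", ]
  g3$tumor_1_bed_gy <- 5
  expect_equal(select_optimal(g3, "kidney")$amount_nmol, min(g3$amount_nmol))
})

test_that("combined mode takes the row-wise minimum activity on the subgrid", {
  grid <- grid_fixture()
  opt <- select_optimal(grid, "combined", subgrid = c(32, 512))
  sub <- grid[grid$amount_nmol >= 32 & grid$amount_nmol <= 512, ]
  for (amt in unique(sub$amount_nmol)) {
    rows <- sub[sub$amount_nmol == amt, ]
    cand <- opt$rows[opt$rows$amount_nmol == amt, ]
    if (nrow(cand))
      expect_equal(cand$activity_gbq, min(rows$activity_gbq))
  }
  expect_true(all(opt$rows$amount_nmol >= 32 & opt$rows$amount_nmol <= 512))
})

test_that("marrow exclusion is monotone in activity", {
  # marrow BED is increasing in activity, so a violation at A implies
  # violation at every larger activity
  grid <- grid_fixture()
  r <- grid[1, ]
  bed_of <- function(scale) {
    d <- r$marrow_bed_gy # BED at the tabulated activity
    d
  }
  # direct property of the BED formula: D linear in A, G independent of A
  D <- 0.2; G <- 0.02; ab <- 15
  A <- seq(0.5, 30, by = 0.5)
  beds <- bed(D * A / A[1], G, ab)
  expect_true(all(diff(beds) > 0))
})

test_that("Akaike-weighted perfusion averaging reproduces the arithmetic", {
  # supported rates 0.1/0.5/1 with weights 19/33/47% (0.01 excluded) -> 0.66
  expect_equal(round(weighted_perfusion(c(0.19, 0.33, 0.47),
                                        c(0.1, 0.5, 1)), 2), 0.66)
  expect_equal(round(weighted_perfusion(c(0.005, 0.19, 0.33, 0.47),
                                        c(0.01, 0.1, 0.5, 1)), 2), 0.66)
  expect_equal(weighted_perfusion(rep(0.25, 4), c(0.01, 0.1, 0.5, 1),
                                  exclude_below = 0), 0.4025)
  expect_error(weighted_perfusion(c(1, 0), c(0.1)), "length mismatch")
})

test_that("tumor BED rises along the kidney iso-BED curve for a high-density lesion", {
  # high tumor binding density relative to kidneys: saturation of the kidney
  # pool allows more activity at larger amounts, raising tumor BED over the
  # rising limb of the grid
  cfg <- default_config()
  phys <- physiology_set(bsa = 2.0, ter = 198,
                         volumes = list(kidneys = 311, salivary_glands = 29,
                                        tumor_1 = 3, tumor_2 = 3))
  m <- build_model(phys, receptor_map(tumor_1 = 1500, tumor_2 = 1500),
                   ligand_params())
  grid <- build_planning_grid(m, constraint_set(), amounts = 2^(2:7),
                              solver = fast_solver())
  k <- grid[grid$case == "kidney", ]
  expect_true(all(diff(k$tumor_1_bed_gy) > 0))
})

test_that("perfusion sensitivity refits under fixed rates and averages by weight", {
  vp <- sample_virtual_patient(33)
  ds <- simulate_measurements(vp, f_tu = 0.5)
  sens <- perfusion_sensitivity(ds, vp, rates = c(0.1, 0.5),
                                spec = quick_spec(), seed = 4)
  expect_length(sens$fits, 2)
  expect_equal(sum(sens$weights$weight), 1, tolerance = 1e-12)
  expect_true(sens$avg_rate >= 0.1 && sens$avg_rate <= 0.5)
  # the generating rate should not be the excluded one
  expect_true(sens$weights$supported[sens$weights$rate == 0.5])
})
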