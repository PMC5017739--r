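# Whole-body model construction and simulation.

test_that("build_model validates inputs and attaches receptor pools", {
  cfg <- default_config()
  phys <- physiology_set(bsa = 2.0, ter = 198,
                         volumes = list(kidneys = 311, salivary_glands = 29,
                                        tumor_1 = 1.5, tumor_2 = 3))
  m <- build_model(phys, receptor_map(), ligand_params())
  # total kidney receptor amount = density x volume
  expect_equal(m$rtot[m$organs$name == "kidneys"], 24 * 311 / 1000)
  expect_equal(m$rtot[m$organs$name == "tumor_1"], 110 * 1.5 / 1000)
  # negative rates rejected
  expect_error(ligand_params(lambda_release = list(kidneys = -1)),
               "negative rate")
  # missing organ entry is named in the error
  broken <- cfg
  broken$physiology$spleen <- NULL
  expect_error(physiology_set(bsa = 2, ter = 198, config = broken), "spleen")
})

test_that("zero receptor densities give structurally present but empty binding pools", {
  phys <- physiology_set(bsa = 2.0, ter = 198)
  rec <- receptor_map(kidneys = 0, salivary_glands = 0, tumor_1 = 0,
                      tumor_2 = 0,
                      relative = list(liver = 0, spleen = 0, gi_tract = 0,
                                      prostate = 0))
  m <- build_model(phys, rec, ligand_params())
  expect_true(all(m$rtot == 0))
  sim <- simulate_pbpk(m, administration(100, 1), fast_solver(2000),
                       output_times = c(10, 100, 1000, 2000))
  bound <- sim$states[, m$layout$region$kidneys[3]]
  expect_true(all(bound == 0))
})

test_that("the two k_off models share topology and differ only in the rate", {
  m1 <- median_patient_model(k_off = 0.046)
  m2 <- median_patient_model(k_off = 0.46)
  expect_identical(m1$layout, m2$layout)
  expect_identical(m1$organs, m2$organs)
  expect_equal(m1$k_off, 0.046)
  expect_equal(m2$k_off, 0.46)
})

test_that("closed system conserves moles when decay, release and clearance are off", {
  m <- median_model()
  m$cl_renal <- 0
  m$cl_cat <- 0
  m$lrel <- rep(0, length(m$lrel))
  sim <- simulate_pbpk(m, administration(142, 0), fast_solver(5000),
                       output_times = c(60, 500, 2000, 5000),
                       lambda_phys_override = 0)
  total <- rowSums(sim$states)
  expect_equal(total, rep(142, 4), tolerance = 1e-6)
})

test_that("activity fractions are independent of the injected activity", {
  # Eq-1 structure: A_i(t) = A_inj * a_i(t); verified on the explicit
  # two-species system where the labeled fraction actually changes
  m <- median_model()
  tt <- c(30, 1440, 4320)
  s1 <- simulate_pbpk(m, administration(142, 2), fast_solver(4320),
                      mode = "two_species", output_times = tt)
  s2 <- simulate_pbpk(m, administration(142, 6), fast_solver(4320),
                      mode = "two_species", output_times = tt)
  for (rg in c("kidneys", "tumor_1", "total_body"))
    expect_equal(s1$activity[[rg]], s2$activity[[rg]], tolerance = 1e-6)
})

test_that("receptor saturation: bound fraction in kidneys falls with amount", {
  m <- median_model()
  frac_bound <- vapply(c(2, 512), function(amt) {
    sim <- simulate_pbpk(m, administration(amt, 0), fast_solver(1440),
                         output_times = 1440)
    idx <- m$layout$region$kidneys[3:4]
    sum(sim$states[1, idx]) / amt
  }, 0)
  expect_lt(frac_bound[2], frac_bound[1])
})

test_that("kidney time-integrated activity per unit activity is non-increasing in amount", {
  m <- median_model()
  ta <- vapply(2^seq(1, 13, by = 2), function(amt) {
    sim <- simulate_pbpk(m, administration(amt, 0), fast_solver())
    tiac(activity_fraction(sim, "kidneys"))
  }, 0)
  expect_true(all(diff(ta) < 1e-9))
})

test_that("species symmetry: fully labeled, non-decaying two-species run equals total", {
  m <- median_model()
  ad <- administration(142, 0)
  ad$labeled_fraction <- 1
  tt <- c(30, 500, 2000)
  s2 <- simulate_pbpk(m, ad, fast_solver(2000), mode = "two_species",
                      output_times = tt, lambda_phys_override = 0)
  s1 <- simulate_pbpk(m, ad, fast_solver(2000), mode = "total",
                      output_times = tt, lambda_phys_override = 0)
  expect_equal(s2$activity$kidneys, s1$activity$kidneys, tolerance = 1e-7)
  # unlabeled block stays empty
  expect_true(all(abs(s2$states[, -seq_len(m$layout$m)]) < 1e-10))
})

test_that("labeled tracer factorizes: two-species equals decay-scaled total", {
  m <- median_model()
  ad <- administration(142, 5.6)
  tt <- c(30, 1440, 10000, 30000)
  s2 <- simulate_pbpk(m, ad, fast_solver(), mode = "two_species",
                      output_times = tt)
  s1 <- simulate_pbpk(m, ad, fast_solver(), mode = "total", output_times = tt)
  for (rg in c("kidneys", "salivary_glands", "tumor_1", "total_body",
               "excreted"))
    expect_equal(s2$activity[[rg]], s1$activity[[rg]], tolerance = 1e-6)
})

test_that("activity balance: regions plus excreted follow physical decay", {
  m <- median_model()
  sim <- simulate_pbpk(m, administration(142, 5.6), fast_solver(),
                       mode = "two_species")
  pick <- sim$time >= 10 # after end of infusion
  idx <- round(seq(1, sum(pick), length.out = 20))
  tt <- sim$time[pick][idx]
  bal <- (sim$activity$total_body + sim$activity$excreted)[pick][idx]
  expect_equal(bal, exp(-lambda_phys() * tt), tolerance = 1e-6)
})

test_that("stripped one-organ model matches an independent RK4 oracle", {
  pars <- reduced_pars
  times <- c(5, 30, 120, 480, 1000)
  oracle <- reduced_oracle(pars, amount = 100, t_inf = 10, times = times,
                           h = 0.005)
  m <- reduced_package_model(pars)
  sim <- simulate_pbpk(m, administration(100, 0),
                       solver_settings(rtol = 1e-10, atol = 1e-14,
                                       t_end = 1000),
                       output_times = times, lambda_phys_override = 0)
  lay <- m$layout
  got <- cbind(sim$states[, lay$serum],
               sim$states[, lay$region$kidneys],
               sim$states[, lay$catabolite],
               sim$states[, lay$urine])
  # compare every compartment, relative to the injected amount scale
  expect_lt(max(abs(got - oracle)) / 100, 1e-8)
})

test_that("activity_fraction handles totals, remainder and bad regions", {
  sim <- median_sim()
  expect_error(activity_fraction(sim, "gallbladder"), "lookup error")
  a0 <- vapply(c("kidneys", "total_body", "remainder"), function(rg)
    activity_fraction(sim, rg)$value[1], 0)
  expect_equal(unname(a0), c(0, 0, 0)) # t = 0 pre-infusion
  rem <- sim$activity$total_body -
    rowSums(sim$activity[, c("kidneys", "salivary_glands", "tumor_1",
                             "tumor_2", "red_marrow")])
  expect_equal(sim$activity$remainder, rem, tolerance = 1e-12)
})

test_that("tiac matches closed forms", {
  tt <- sort(unique(c(0, 10^seq(-1, log10(3e4), length.out = 1200))))
  lam <- lambda_phys()
  ta <- tiac(data.frame(time_min = tt, value = exp(-lam * tt)), T = 3e4)
  expect_equal(ta, (1 - exp(-lam * 3e4)) / lam, tolerance = 1e-6)
  expect_equal(tiac(data.frame(time_min = tt, value = 0 * tt)), 0)
  # step function: 1 on [0, 100]
  ts <- c(seq(0, 100, by = 12.5), 100.001, 200, 3e4)
  vs <- c(rep(1, 9), 0, 0, 0)
  expect_equal(tiac(data.frame(time_min = ts, value = vs), T = 3e4), 100,
               tolerance = 1e-3)
  expect_error(tiac(data.frame(time_min = c(0, 5, 5), value = c(1, 1, 1))),
               "non-monotone")
})

test_that("nmol/mass conversion uses 1.66 ug per nmol", {
  expect_equal(round(nmol_to_mass(142)), 236)
  expect_equal(round(nmol_to_mass(272)), 452)
  expect_equal(nmol_to_mass(0), 0)
  expect_equal(mass_to_nmol(nmol_to_mass(57.3)), 57.3)
  expect_error(nmol_to_mass(-1), "non-negative")
})

test_that("administration derives the labeled fraction and validates", {
  ad <- administration(142, 5.6)
  expect_equal(ad$labeled_fraction, 5.6 / 0.7268 / 142, tolerance = 1e-12)
  expect_equal(ad$infusion_duration, 10)
  expect_error(administration(0, 1), "amount")
  expect_error(administration(2, 56), "labeled fraction")
})
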