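test_that("time-course generation is seeded and noise-free at cv = 0", {
  sys <- racemase_system()
  nm0 <- noise_model(cv = 0, floor = 0, seed = 1)
  tc <- generate_timecourse(sys, c(0.5, 1, 2, 3, 6, 12, 24), nm0)
  traj <- simulate(sys, times = c(0, 0.5, 1, 2, 3, 6, 12, 24))
  truth <- traj$concentrations[-1, sys$species$id]
  expect_equal(as.matrix(tc[, sys$species$id]), truth,
               ignore_attr = TRUE)
  nm <- noise_model(cv = 0.03, floor = 0.01, seed = 99)
  t1 <- generate_timecourse(sys, noise = nm)
  t2 <- generate_timecourse(sys, noise = nm)
  expect_identical(t1, t2)
  t3 <- generate_timecourse(sys, noise = noise_model(0.03, 0.01, seed = 100))
  expect_false(identical(t1, t3))
  expect_error(generate_timecourse(sys, c(2, 1), nm), "increasing")
})

test_that("empirical noise level matches the declared cv", {
  sys <- racemase_system()
  vals <- vapply(1:400, function(s) {
    tc <- generate_timecourse(sys, sample_times = 6,
                              noise = noise_model(0.03, 0, seed = s))
    tc[["S-D2"]]
  }, numeric(1))
  expect_equal(sd(vals) / mean(vals), 0.03, tolerance = 0.2)
})

test_that("replicate assays share truth but not noise, and honor limits", {
  nm <- noise_model(0.03, 0, seed = 5)
  assays <- generate_initial_rate_dataset(10, 0.01, 10, n_replicates = 3,
                                          noise = nm)
  expect_length(assays, 3)
  expect_identical(assays[[1]]$time_h, assays[[2]]$time_h)
  expect_false(identical(assays[[1]]$product_mM, assays[[2]]$product_mM))
  again <- generate_initial_rate_dataset(10, 0.01, 10, n_replicates = 3,
                                         noise = nm)
  expect_identical(assays[[1]]$product_mM, again[[1]]$product_mM)
  # explicit times breaching the 20% conversion window are refused
  expect_error(generate_initial_rate_dataset(10, 0.01, 10,
                                             noise = nm, times = c(1, 2, 30)),
               "20% conversion")
})

test_that("impure stocks split totals by the ee definition", {
  expect_equal(impure_stock(50, -99.1),
               c(S = 0.225, R = 49.775), tolerance = 1e-12)
  expect_equal(impure_stock(50, 0), c(S = 25, R = 25))
  expect_error(impure_stock(50, 120), "\\[-100, 100\\]")
  expect_error(impure_stock(0, 10), "> 0")
  set.seed(51)
  for (i in 1:25) {
    tot <- runif(1, 1, 100); x <- runif(1, -99.9, 99.9)
    st <- impure_stock(tot, x)
    expect_equal(sum(st), tot)
    expect_equal(ee_percent(st[["S"]], st[["R"]]), x)
  }
})

test_that("strictly selective OD of an impure stock plateaus the ketone
           at the impurity concentration", {
  st <- impure_stock(50, -99.1)
  sp <- rbind(species("S-D1", "amine_S", "D1"),
              species("R-D1", "amine_R", "D1"),
              species("A1", "ketone", "D1"))
  rx <- list(elemental_reaction("I^S", "S-D1", "A1", 10, 0),
             elemental_reaction("I^R", "R-D1", "A1", 0, 0))
  sys <- reaction_system(sp, rx, enzyme_total = 0.75,
                         initial_concentrations = c("S-D1" = st[["S"]],
                                                    "R-D1" = st[["R"]]))
  traj <- simulate(sys, t_end = 48)
  a1 <- traj$concentrations[, "A1"]
  expect_lt(abs(a1[length(a1)] - st[["S"]]), 1e-6)
  expect_lt(abs(max(a1) - st[["S"]]), 1e-6)
  # the disfavored enantiomer is untouched
  expect_equal(max(abs(traj$concentrations[, "R-D1"] - st[["R"]])), 0,
               tolerance = 1e-9)
})

test_that("pose generation reproduces the prescription and is frame-random", {
  fx <- generate_pose(3.1, 91, 78, 3.0, TRUE, seed = 1)
  r <- nat_report(fx$pose)
  expect_equal(r$d_NAT, 3.1, tolerance = 1e-6)
  expect_equal(r$theta_BD, 91, tolerance = 1e-6)
  expect_equal(r$theta_DH, 78, tolerance = 1e-6)
  expect_equal(r$d_Halpha_Neps, 3.0, tolerance = 1e-6)
  expect_true(r$halpha_same_face)
  # opposite-face prescription classifies nonproductive
  fx2 <- generate_pose(3.1, 79, 70, 3.0, FALSE, seed = 2)
  r2 <- nat_report(fx2$pose)
  expect_false(r2$halpha_same_face)
  expect_equal(r2$verdict, "nonproductive")
  # two seeds: different raw coordinates, identical metrics
  fxa <- generate_pose(3.1, 91, 78, 3.0, TRUE, seed = 11)
  fxb <- generate_pose(3.1, 91, 78, 3.0, TRUE, seed = 12)
  expect_false(identical(fxa$pose$coords, fxb$pose$coords))
  ra <- nat_report(fxa$pose); rb <- nat_report(fxb$pose)
  for (f in c("d_NAT", "theta_BD", "theta_DH", "d_Halpha_Neps"))
    expect_equal(ra[[f]], rb[[f]], tolerance = 1e-9)
  # infeasible prescriptions are refused
  expect_error(generate_pose(3.1, 91, 78, 1.5, FALSE, seed = 1),
               "infeasible")
  expect_error(generate_pose(3.1, 0, 78, 3, TRUE, seed = 1), "angles")
  expect_error(generate_pose(0.4, 91, 78, 3, TRUE, seed = 1), "0.5")
})

test_that("generators leave the global RNG state alone", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_timecourse(racemase_system(),
                                noise = noise_model(0.03, 0, seed = 9)))
  invisible(generate_pose(3.1, 91, 78, 3.0, TRUE, seed = 9))
  after <- runif(1)
  expect_identical(before, after)
})
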