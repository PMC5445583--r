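test_that("presets encode the study geometries", {
  u <- design_preset("unrealistic")
  expect_equal(c(u$domain$Lx, u$domain$Ly), c(100L, 100L))
  expect_equal(u$domain$x_boundary, "no_flux")
  expect_equal(u$n_replicates, 10L)
  expect_equal(u$times, c(240, 480, 720))

  s <- design_preset("realistic_small")
  expect_equal(c(s$domain$Lx, s$domain$Ly), c(23L, 23L))
  expect_equal(s$domain$x_boundary, "flux")
  expect_equal(s$n_replicates, 5L)
  expect_equal(s$replenish, 1)

  l <- design_preset("realistic_large")
  expect_equal(c(l$domain$Lx, l$domain$Ly), c(23L, 184L))
  # the large domain is exactly eight times the small one
  expect_equal(design_area(l) / design_area(s), 8)
})

test_that("scaling a design multiplies Ly and keeps column densities", {
  s <- design_realistic()
  l <- scale_design(s, 8)
  expect_equal(l$domain$Ly, 184L)
  expect_equal(l$init$densities, s$init$densities)
  expect_equal(scale_design(s, 1)$domain$Ly, s$domain$Ly)
  expect_equal(scale_design(s, 2)$domain$Ly, 46L)
  expect_error(scale_design(s, 1.5), "integer")
})

test_that("default single-sided densities ramp from a full band to the wound", {
  d <- default_column_densities(23)
  expect_equal(d[1:6], rep(1, 6))
  expect_equal(d[7:9], c(0.75, 0.5, 0.25))
  expect_equal(d[10:23], rep(0, 14))
  expect_equal(length(d), 23)
})

test_that("synthetic datasets have the declared shape and are reproducible", {
  des <- design_realistic(Lx = 10, Ly = 8,
                          column_densities = c(1, 1, 0.5, rep(0, 7)),
                          n_replicates = 3, times = c(30, 60))
  params <- abm_params(0.5, 0.25, "B")
  ds <- generate_synthetic_data(des, params, seed = 2)
  expect_s3_class(ds, "summary_dataset")
  expect_equal(sort(unique(ds$replicates$rep)), 1:3)
  expect_equal(sort(unique(ds$replicates$t)), c(30, 60))
  counts <- dplyr::count(ds$replicates, statistic, t, rep)
  expect_true(all(counts$n[counts$statistic == "density_profile"] == 10))
  expect_true(all(counts$n[counts$statistic == "pcf"] == 9))
  expect_true(all(counts$n[counts$statistic == "displacement"] == 1))
  # ensemble average equals the elementwise mean of replicates
  expect_equal(ds$ensemble, ensemble_average(ds$replicates))
  ds2 <- generate_synthetic_data(des, params, seed = 2)
  expect_equal(ds$replicates, ds2$replicates)
})

test_that("adhesion reduces and repulsion raises mean displacement", {
  des <- design_realistic(Lx = 12, Ly = 10,
                          column_densities = c(1, 1, 1, 0.5, rep(0, 8)),
                          n_replicates = 4, times = 120)
  disp <- function(alpha) {
    ds <- generate_synthetic_data(des, abm_params(0.5, alpha, "B"), seed = 6,
                                  statistics = "displacement")
    mean(ds$ensemble$value)
  }
  expect_gt(disp(-0.2), disp(0.6)) # repulsive > strongly adhesive
})

test_that("identical seeds give identical study tables", {
  des <- design_realistic(Lx = 8, Ly = 6,
                          column_densities = c(1, 0.5, rep(0, 6)),
                          n_replicates = 2, times = 20)
  params <- abm_params(0.5, 0.25, "B")
  v1 <- variance_study(list(d = des), c(2, 4), params, n_datasets = 2,
                       seed = 9)
  v2 <- variance_study(list(d = des), c(2, 4), params, n_datasets = 2,
                       seed = 9)
  expect_equal(v1, v2)
  arms <- list(a = list(design = des), b = list(design = des))
  t1 <- compare_designs(arms, params, abc_prior("B"),
                        distance_spec("pcf", times = 20),
                        n_sims = 8, n_accept = 4, seed = 3)
  t2 <- compare_designs(arms, params, abc_prior("B"),
                        distance_spec("pcf", times = 20),
                        n_sims = 8, n_accept = 4, seed = 3)
  expect_equal(t1, t2)
  expect_error(compare_designs(arms[1], params, abc_prior("B")), "two arms")
})

test_that("ensemble-average noise shrinks like one over the replicate count", {
  des <- design_realistic(Lx = 15, Ly = 12, n_replicates = 5,
                          times = 120)
  params <- abm_params(0.5, 0.25, "B")
  tab <- variance_study(list(d = des), c(5, 20, 80), params,
                        statistic = "pcf", n_datasets = 30, seed = 13)
  v <- dplyr::summarise(dplyr::group_by(tab, n_rep, r),
                        v = stats::var(ens_value), .groups = "drop")
  v <- dplyr::summarise(dplyr::group_by(v, n_rep), v = mean(v),
                        .groups = "drop")
  fit <- stats::lm(log(v) ~ log(n_rep), data = v)
  expect_lt(abs(stats::coef(fit)[2] + 1), 0.2)
})

test_that("dataset generation agrees with the record-level summariser", {
  des <- design_realistic(Lx = 10, Ly = 8,
                          column_densities = c(1, 1, 0.5, rep(0, 7)),
                          n_replicates = 1, times = c(30, 60))
  params <- abm_params(0.5, 0.25, "B")
  ds <- generate_synthetic_data(des, params, n_replicates = 1, seed = 7)
  set.seed(8) # replicate 1 uses seed + 1
  init <- initial_state(des)
  rec <- simulate_abm(des$domain, params, init, times = des$times,
                      replenish = des$replenish)
  ref <- summarise_record(rec)
  got <- dplyr::arrange(ds$replicates[c("statistic", "t", "r", "value")],
                        statistic, t, r)
  ref <- dplyr::arrange(ref, statistic, t, r)
  expect_equal(got$value, ref$value)
})
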