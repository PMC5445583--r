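two_agent_record <- function(cols_i, cols_f, Lx = 10, Ly = 4) {
  # hand-built record: agents move from cols_i to cols_f between t 0 and 1
  dom <- abm_domain(Lx, Ly)
  mk <- function(cols) occupancy_state(
    tibble::tibble(id = seq_along(cols), col = as.integer(cols),
                   row = seq_along(cols), init_col = as.integer(cols_i)),
    dom)
  structure(list(snapshots = list(`1` = mk(cols_f)), times = 1,
                 initial = mk(cols_i), domain = dom),
            class = "abm_record")
}

test_that("average horizontal displacement is the mean absolute column shift", {
  expect_equal(average_horizontal_displacement(two_agent_record(c(2, 6), c(4, 6))), 1)
  expect_equal(average_horizontal_displacement(two_agent_record(2, 5)), 3)
  expect_equal(average_horizontal_displacement(two_agent_record(c(3, 4), c(3, 4))), 0)
})

test_that("displacement only counts agents present at both times", {
  dom <- abm_domain(6, 3)
  a0 <- occupancy_state(
    tibble::tibble(id = 1:2, col = c(1L, 2L), row = c(1L, 2L),
                   init_col = c(1L, 2L)), dom)
  a1 <- occupancy_state( # agent 1 exited; agent 3 replenished
    tibble::tibble(id = c(2L, 3L), col = c(5L, 1L), row = c(2L, 1L),
                   init_col = c(2L, 1L)), dom)
  rec <- structure(list(snapshots = list(`1` = a1), times = 1, initial = a0,
                        domain = dom), class = "abm_record")
  expect_equal(average_horizontal_displacement(rec), 3) # only agent 2
  a2 <- occupancy_state(
    tibble::tibble(id = 9L, col = 1L, row = 1L, init_col = 1L), dom)
  rec$snapshots[[1]] <- a2
  expect_error(average_horizontal_displacement(rec), "no agent")
})

test_that("density profiles count per-column occupancy fractions", {
  dom <- abm_domain(3, 4)
  st <- occupancy_state(
    tibble::tibble(id = 1L, col = 2L, row = 3L, init_col = 2L), dom)
  expect_equal(density_profile(st)$density, c(0, 0.25, 0))
  empty <- occupancy_state(st$agents[0, ], dom)
  expect_equal(density_profile(empty)$density, rep(0, 3))
  full <- state_from_grid(matrix(1L, 4, 3), dom)
  expect_equal(density_profile(full)$density, rep(1, 3))
})

test_that("pair counts match brute-force enumeration on random states", {
  s2 <- occupancy_state(
    tibble::tibble(id = 1:2, col = c(1L, 3L), row = c(1L, 1L),
                   init_col = c(1L, 3L)), abm_domain(3, 1))
  expect_equal(pair_counts(s2)$count, c(0, 1))
  one <- occupancy_state(s2$agents[1, ], abm_domain(3, 1))
  expect_equal(pair_counts(one)$count, c(0, 0))
  # full lattice closed form: c(m) = Ly^2 (Lx - m)
  full <- state_from_grid(matrix(1L, 4, 6), abm_domain(6, 4))
  expect_equal(pair_counts(full)$count, 16 * (6 - 1:5))
  set.seed(20)
  for (i in 1:50) {
    st <- random_state(sample(3:9, 1), sample(1:6, 1), N = sample(2:10, 1))
    expect_equal(pair_counts(st)$count, oracle_pair_counts(st))
  }
})

test_that("pair counts plus same-column pairs exhaust all N(N-1)/2 pairs", {
  set.seed(21)
  for (i in 1:200) {
    st <- random_state(sample(3:8, 1), sample(2:6, 1), N = sample(2:12, 1))
    N <- nrow(st$agents)
    expect_equal(sum(pair_counts(st)$count) + same_column_pairs(st),
                 N * (N - 1) / 2)
  }
})

test_that("the CSR normalisation has its closed-form values", {
  # full lattice: rho = rho_hat = 1
  expect_equal(pcf_normalisation(6, 4, 24)$expected, 16 * (6 - 1:5))
  expect_equal(pcf_normalisation(3, 1, 2)$expected[2], 1 / 3)
  # strictly decreasing in m
  expect_true(all(diff(pcf_normalisation(10, 5, 7)$expected) < 0))
  expect_error(pcf_normalisation(5, 5, 1), "undefined")
})

test_that("the PCF is 1 on the full lattice and 1 on average under CSR", {
  full <- state_from_grid(matrix(1L, 5, 7), abm_domain(7, 5))
  expect_equal(pcf(full)$q, rep(1, 6))
  # worked 3x1 example
  s2 <- occupancy_state(
    tibble::tibble(id = 1:2, col = c(1L, 3L), row = c(1L, 1L),
                   init_col = c(1L, 3L)), abm_domain(3, 1))
  expect_equal(pcf(s2)$q, c(0, 3))
  # CSR: E[q(m)] = 1 by construction of the normalisation
  set.seed(31)
  qs <- replicate(1000, pcf(random_state(10, 8, 20))$q)
  z <- abs(rowMeans(qs) - 1) / (apply(qs, 1, sd) / sqrt(ncol(qs)))
  expect_true(all(z < 3))
})

test_that("the PCF depends only on column occupancy counts", {
  set.seed(40)
  st <- random_state(8, 6, 15)
  # permute agents within their columns
  shuffled <- st$agents
  for (cc in unique(shuffled$col)) {
    idx <- which(shuffled$col == cc)
    if (length(idx) > 1)
      shuffled$row[idx] <- shuffled$row[sample(idx)]
  }
  st2 <- occupancy_state(shuffled, st$domain)
  expect_equal(pcf(st2)$q, pcf(st)$q)
})

test_that("ensemble averages and variances are elementwise over replicates", {
  reps <- tibble::tibble(
    rep = rep(1:2, each = 2),
    statistic = "pcf", t = 240, r = rep(1:2, 2),
    value = c(0, 1, 2, 1))
  avg <- ensemble_average(reps)
  expect_equal(avg$value, c(1, 1))
  expect_equal(statistic_variance(reps)$variance, c(2, 0))
  one <- reps[reps$rep == 1, ]
  expect_equal(ensemble_average(one)$value, c(0, 1))
  expect_error(statistic_variance(one), "at least two")
  bad <- rbind(reps, tibble::tibble(rep = 1, statistic = "pcf", t = 480,
                                    r = 1, value = 1))
  expect_error(ensemble_average(bad), "inconsistent")
})
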