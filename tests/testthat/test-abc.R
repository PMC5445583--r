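# a small, fast design used to exercise the samplers end to end
toy_design <- function(times = c(20, 40)) {
  design_realistic(Lx = 8, Ly = 6,
                   column_densities = c(1, 1, 0.5, rep(0, 5)),
                   n_replicates = 2, times = times)
}

fake_dataset <- function(values, statistic = "pcf", t = c(240), r = NULL) {
  if (is.null(r)) r <- seq_along(values)
  tt <- rep(t, each = length(values))
  rr <- rep(r, times = length(t))
  vv <- rep(values, times = length(t))
  tibble::tibble(statistic = statistic, t = tt, r = rr, value = vv)
}

test_that("the ABC distance is a weighted sum of absolute differences", {
  obs <- fake_dataset(c(1, 2))
  spec <- distance_spec("pcf", times = 240)
  expect_equal(abc_distance(obs, obs, spec), 0)
  expect_equal(abc_distance(obs, fake_dataset(c(0, 4)), spec), 3)
  # additive over times
  obs2 <- fake_dataset(c(1, 2), t = c(240, 480))
  sim2 <- fake_dataset(c(0, 4), t = c(240, 480))
  expect_equal(abc_distance(obs2, sim2, distance_spec("pcf", c(240, 480))), 6)
  # weights scale per-statistic contributions
  expect_equal(
    abc_distance(obs, fake_dataset(c(0, 4)),
                 distance_spec("pcf", 240, weights = 2)), 6)
  # shape mismatches are reported with the offending statistic and time
  expect_error(abc_distance(obs, fake_dataset(c(0, 4, 1), r = 1:3), spec),
               "pcf at t=240")
})

test_that("rejection accepts the n smallest distances with order ties", {
  des <- toy_design()
  truth <- abm_params(0.6, 0.2, "B")
  observed <- generate_synthetic_data(des, truth, seed = 5)
  prior <- abc_prior("B")
  post <- abc_rejection(des, prior, observed,
                        distance_spec("pcf", times = des$times),
                        n_sims = 30, n_accept = 10, seed = 7)
  s <- post$samples
  expect_equal(sum(s$accepted), 10)
  expect_lte(max(s$dist[s$accepted]), min(s$dist[!s$accepted]))
  # n_accept = n_sims keeps the whole prior sample
  all_in <- abc_rejection(des, prior, observed,
                          distance_spec("pcf", times = des$times),
                          n_sims = 10, n_accept = 10, seed = 7)
  expect_true(all(all_in$samples$accepted))
  expect_error(abc_rejection(des, prior, observed, n_sims = 5, n_accept = 6),
               "exceed")
  # bit-reproducible given the seed
  post2 <- abc_rejection(des, prior, observed,
                         distance_spec("pcf", times = des$times),
                         n_sims = 30, n_accept = 10, seed = 7)
  expect_equal(post$samples, post2$samples)
})

test_that("accept_top re-ranks a stored campaign without re-simulation", {
  des <- toy_design()
  observed <- generate_synthetic_data(des, abm_params(0.6, 0.2, "B"), seed = 5)
  post <- abc_rejection(des, abc_prior("B"), observed,
                        distance_spec("pcf", times = des$times),
                        n_sims = 20, n_accept = 5, seed = 3)
  re <- accept_top(post, "displacement", 5)
  expect_equal(sum(re$samples$accepted), 5)
  expect_equal(re$samples$dist, re$samples$d_displacement)
  # re-ranking by the original statistic reproduces the original set
  expect_equal(accept_top(post, "pcf", 5)$samples$accepted,
               post$samples$accepted)
})

test_that("pilot weights put combined statistics on a common scale", {
  des <- toy_design()
  observed <- generate_synthetic_data(des, abm_params(0.6, 0.2, "B"), seed = 5)
  pilot <- abc_rejection(des, abc_prior("B"), observed,
                         distance_spec("pcf", times = des$times),
                         n_sims = 20, n_accept = 5, seed = 3)
  w <- pilot_weights(pilot)
  expect_named(w, c("pcf", "displacement", "density_profile"))
  expect_true(all(w > 0))
  # weighted median contributions are all 1 by construction
  meds <- vapply(names(w), function(s)
    stats::median(pilot$samples[[paste0("d_", s)]]), numeric(1))
  expect_equal(unname(w * meds), rep(1, 3))
  # and they plug into a combined distance spec
  spec <- distance_spec(names(w), times = des$times, weights = w)
  expect_equal(unname(spec$weights), unname(w))
})

test_that("epsilon thresholds follow the nearest-rank quantile rule", {
  expect_equal(choose_epsilon(c(1, 2, 3), 1), 3)
  expect_equal(choose_epsilon(c(1, 2, 3), 0.5), 2)
  set.seed(1)
  d <- runif(100)
  expect_equal(choose_epsilon(d, 0.01), min(d))
  expect_error(choose_epsilon(numeric(0), 0.5), "no pilot")
  expect_error(choose_epsilon(c(1, 2), 0), "quantile")
})

test_that("a zero proposal scale keeps the MCMC chain at its start", {
  des <- toy_design()
  observed <- generate_synthetic_data(des, abm_params(0.6, 0.2, "B"), seed = 5)
  post <- abc_mcmc(des, abc_prior("B"), observed,
                   distance_spec("pcf", times = des$times),
                   epsilon = Inf, chain_length = 50,
                   proposal_scales = c(0, 0), init = c(0.4, 0.3), seed = 2)
  expect_true(all(post$samples$pm == 0.4))
  expect_true(all(post$samples$alpha == 0.3))
  expect_error(abc_mcmc(des, abc_prior("B"), observed, epsilon = -1,
                        chain_length = 10), "positive")
  expect_error(abc_mcmc(des, abc_prior("B"), observed, epsilon = 1,
                        chain_length = 10, init = c(2, 0)), "outside")
})

test_that("with a vacuous threshold the chain targets the uniform prior", {
  des <- toy_design()
  observed <- generate_synthetic_data(des, abm_params(0.6, 0.2, "B"), seed = 5)
  prior <- abc_prior("B")
  post <- abc_mcmc(des, prior, observed,
                   distance_spec("pcf", times = des$times),
                   epsilon = Inf, chain_length = 10000,
                   proposal_scales = 0.5 * c(diff(prior$pm_bounds),
                                             diff(prior$alpha_bounds)),
                   seed = 11)
  u_pm <- (post$samples$pm - prior$pm_bounds[1]) / diff(prior$pm_bounds)
  u_al <- (post$samples$alpha - prior$alpha_bounds[1]) /
    diff(prior$alpha_bounds)
  ks <- function(x) max(abs(sort(x) - seq_along(x) / length(x)))
  expect_lt(ks(u_pm), 0.05)
  expect_lt(ks(u_al), 0.05)
})

test_that("tightening epsilon cannot raise the MCMC acceptance rate", {
  des <- toy_design(times = 15)
  observed <- generate_synthetic_data(des, abm_params(0.6, 0.2, "B"), seed = 5)
  spec <- distance_spec("pcf", times = 15)
  rates <- vapply(c(20, 5, 1), function(eps) {
    abc_mcmc(des, abc_prior("B"), observed, spec, epsilon = eps,
             chain_length = 150, init = c(0.6, 0.2),
             seed = 8)$acceptance_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
})
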