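#' Uniform prior box for (Pm, alpha)
#'
#' Independent uniform priors on the attempt rate and adhesion parameter.
#' The defaults are the study priors: `Pm` in \[0, 1\] for both models,
#' `alpha` in \[-0.2, 0.25\] for model A and \[-0.2, 1\] for model B —
#' strict subsets of [admissible_alpha_range()], so every prior draw yields
#' valid transition probabilities.
#'
#' @param model `"A"` or `"B"`.
#' @param pm_bounds Interval for `Pm`, within \[0, Inf).
#' @param alpha_bounds Interval for `alpha`; default depends on the model.
#' @return An object of class `abc_prior`.
#' @examples
#' abc_prior("A")
#' @export
abc_prior <- function(model = c("A", "B"), pm_bounds = c(0, 1),
                      alpha_bounds = NULL) {
  model <- match.arg(model)
  if (is.null(alpha_bounds))
    alpha_bounds <- if (model == "A") c(-0.2, 0.25) else c(-0.2, 1)
  rng <- admissible_alpha_range(model)
  if (length(pm_bounds) != 2 || pm_bounds[1] >= pm_bounds[2] ||
      pm_bounds[1] < 0 || any(!is.finite(pm_bounds)))
    abort("`pm_bounds` must be a finite interval with 0 <= lower < upper.")
  if (length(alpha_bounds) != 2 || alpha_bounds[1] >= alpha_bounds[2] ||
      alpha_bounds[1] < rng[1] || alpha_bounds[2] > rng[2])
    abort(sprintf(
      "`alpha_bounds` must be an interval inside the admissible range [%g, %g] for model %s.",
      rng[1], rng[2], model))
  structure(list(model = model, pm_bounds = as.numeric(pm_bounds),
                 alpha_bounds = as.numeric(alpha_bounds)),
            class = "abc_prior")
}

#' @export
print.abc_prior <- function(x, ...) {
  cat(sprintf("<abc_prior> model %s, Pm ~ U[%g, %g], alpha ~ U[%g, %g]\n",
              x$model, x$pm_bounds[1], x$pm_bounds[2],
              x$alpha_bounds[1], x$alpha_bounds[2]))
  invisible(x)
}

prior_draw <- function(prior, n = 1) {
  tibble(pm = runif(n, prior$pm_bounds[1], prior$pm_bounds[2]),
         alpha = runif(n, prior$alpha_bounds[1], prior$alpha_bounds[2]))
}

in_prior <- function(prior, pm, alpha) {
  pm >= prior$pm_bounds[1] & pm <= prior$pm_bounds[2] &
    alpha >= prior$alpha_bounds[1] & alpha <= prior$alpha_bounds[2]
}

#' Distance specification for ABC
#'
#' Which summary statistics enter the ABC distance, at which sampling times,
#' and with which weights. The distance is the sum over times and statistic
#' elements of the absolute difference between the two datasets' ensemble
#' averages, each statistic's contribution multiplied by its weight
#' (default 1).
#'
#' @param statistics Non-empty subset of
#'   `c("pcf", "displacement", "density_profile")`.
#' @param times Sampling times (minutes).
#' @param weights Positive weights, one per statistic (recycled).
#' @return An object of class `distance_spec`.
#' @export
distance_spec <- function(statistics = "pcf", times = c(240, 480, 720),
                          weights = 1) {
  statistics <- match.arg(statistics,
                          c("pcf", "displacement", "density_profile"),
                          several.ok = TRUE)
  if (length(times) == 0) abort("`times` must be non-empty.")
  weights <- rep_len(weights, length(statistics))
  if (any(weights <= 0)) abort("`weights` must be positive.")
  structure(list(statistics = statistics, times = as.numeric(times),
                 weights = stats::setNames(weights, statistics)),
            class = "distance_spec")
}

#' ABC distance between two summary datasets
#'
#' `d = sum_t sum_r |S(D)_{r,t} - S(D~)_{r,t}|` over the selected statistics
#' and times, applied to the ensemble-averaged statistics of each dataset,
#' with per-statistic weights.
#'
#' @param observed,simulated `summary_dataset` objects (or long ensemble
#'   tibbles with columns `statistic`, `t`, `r`, `value`).
#' @param spec A [distance_spec()].
#' @return A non-negative number; 0 iff the selected values are identical.
#' @export
abc_distance <- function(observed, simulated, spec = distance_spec()) {
  d <- abc_distance_by_statistic(observed, simulated, spec)
  sum(d * spec$weights[names(d)])
}

# per-statistic unweighted distances, named by statistic
abc_distance_by_statistic <- function(observed, simulated, spec) {
  obs <- ensemble_table(observed)
  sim <- ensemble_table(simulated)
  obs <- filter(obs, .data$statistic %in% spec$statistics,
                .data$t %in% spec$times)
  sim <- filter(sim, .data$statistic %in% spec$statistics,
                .data$t %in% spec$times)
  joined <- inner_join(obs, sim, by = c("statistic", "t", "r"),
                       suffix = c("_obs", "_sim"))
  missing <- anti_join(obs, sim, by = c("statistic", "t", "r"))
  if (nrow(missing) || nrow(joined) != nrow(sim)) {
    bad <- dplyr::distinct(
      bind_rows(missing, anti_join(sim, obs, by = c("statistic", "t", "r"))),
      .data$statistic, .data$t)
    abort(sprintf(
      "datasets do not align for: %s.",
      paste(sprintf("%s at t=%g", bad$statistic, bad$t), collapse = "; ")))
  }
  out <- joined %>%
    group_by(.data$statistic) %>%
    summarise(d = sum(abs(.data$value_obs - .data$value_sim)),
              .groups = "drop")
  stats::setNames(out$d, out$statistic)
}

ensemble_table <- function(x) {
  if (inherits(x, "summary_dataset")) return(x$ensemble)
  if (is.data.frame(x)) return(as_tibble(x))
  abort("expected a summary_dataset or a long statistic table.")
}

#' ABC rejection sampling
#'
#' Draws `n_sims` parameter vectors from the prior, simulates one dataset
#' per draw (by default with the same replicate protocol as the observed
#' data, so ensemble averages are compared like for like), computes the
#' distance of [abc_distance()], and accepts the `n_accept` draws with
#' the smallest distances (ties broken by draw order). Per-statistic
#' distances for all three summary statistics are stored alongside the
#' combined distance, so accepted sets under a different statistic can be
#' re-derived from the same run with [accept_top()].
#'
#' @param design The `experiment_design` to simulate.
#' @param prior An [abc_prior()].
#' @param observed The observed `summary_dataset`.
#' @param spec A [distance_spec()]; its statistics define the acceptance
#'   distance.
#' @param n_sims Number of prior draws / simulated datasets.
#' @param n_accept Number of accepted draws; at most `n_sims`.
#' @param seed Integer seed.
#' @param n_replicates Replicates per simulated dataset (default: the
#'   observed dataset's replicate count; set to 1 for a single model run
#'   per draw).
#' @return An object of class `abc_posterior` with elements `samples` (one
#'   row per draw: `sim`, `pm`, `alpha`, per-statistic distances, `dist`,
#'   `accepted`), `prior`, `spec`, `method = "rejection"` and provenance.
#' @export
abc_rejection <- function(design, prior, observed, spec = distance_spec(),
                          n_sims, n_accept, seed = 1,
                          n_replicates = observed$n_replicates %||% 1) {
  stopifnot(inherits(prior, "abc_prior"))
  if (n_accept > n_sims) abort("`n_accept` must not exceed `n_sims`.")
  set.seed(seed)
  theta <- prior_draw(prior, n_sims)
  sim_seeds <- sample.int(2147483000L, n_sims)
  per_stat <- purrr::map(seq_len(n_sims), function(s) {
    params <- abm_params(theta$pm[s], theta$alpha[s], prior$model)
    ds <- generate_synthetic_data(design, params, n_replicates = n_replicates,
                                  seed = sim_seeds[s])
    abc_distance_by_statistic(observed, ds,
                              distance_spec(c("pcf", "displacement",
                                              "density_profile"),
                                            times = spec$times))
  })
  samples <- mutate(theta,
    sim = seq_len(n_sims), .before = 1)
  samples$d_pcf <- purrr::map_dbl(per_stat, "pcf")
  samples$d_displacement <- purrr::map_dbl(per_stat, "displacement")
  samples$d_density_profile <- purrr::map_dbl(per_stat, "density_profile")
  samples$dist <- as.numeric(
    as.matrix(samples[paste0("d_", spec$statistics)]) %*%
      spec$weights[spec$statistics])
  samples$accepted <- rank(samples$dist, ties.method = "first") <= n_accept
  structure(
    list(samples = samples, prior = prior, spec = spec, method = "rejection",
         design = design, n_sims = as.integer(n_sims),
         n_accept = as.integer(n_accept), seed = seed,
         n_replicates = as.integer(n_replicates)),
    class = "abc_posterior"
  )
}

#' Re-derive the accepted set of a rejection run under another statistic
#'
#' A rejection run stores per-statistic distances for every simulated
#' dataset, so the accepted set under a different summary statistic (or
#' acceptance count) is a re-ranking, not a re-simulation.
#'
#' @param posterior An `abc_posterior` from [abc_rejection()].
#' @param statistics Statistic(s) to rank by.
#' @param n_accept Acceptance count (default: the original).
#' @param weights Optional weights (as in [distance_spec()]).
#' @return A new `abc_posterior`.
#' @export
accept_top <- function(posterior, statistics, n_accept = posterior$n_accept,
                       weights = 1) {
  stopifnot(inherits(posterior, "abc_posterior"),
            posterior$method == "rejection")
  spec <- distance_spec(statistics, times = posterior$spec$times,
                        weights = weights)
  s <- posterior$samples
  s$dist <- as.numeric(as.matrix(s[paste0("d_", spec$statistics)]) %*%
                         spec$weights[spec$statistics])
  s$accepted <- rank(s$dist, ties.method = "first") <= n_accept
  posterior$samples <- s
  posterior$spec <- spec
  posterior$n_accept <- as.integer(n_accept)
  posterior
}

#' ABC-MCMC sampling
#'
#' Likelihood-free MCMC with a hard distance threshold: from the current
#' parameters, propose with an independent Gaussian random walk; proposals
#' outside the prior box are rejected outright; otherwise a dataset is
#' simulated and the proposal is accepted iff its distance is at most
#' `epsilon`. With uniform priors and a symmetric kernel the Metropolis
#' ratio inside the box is 1, so the chain targets the uniform prior
#' restricted to the `{d <= epsilon}` acceptance region. On rejection the
#' chain repeats the current state.
#'
#' @inheritParams abc_rejection
#' @param epsilon Acceptance threshold; positive (may be `Inf`, in which
#'   case no simulation is needed and the chain targets the prior).
#' @param chain_length Number of iterations (including the start).
#' @param proposal_scales Standard deviations of the Gaussian proposals for
#'   `(pm, alpha)`; default 5% of each prior width.
#' @param init Optional starting value `c(pm, alpha)`; must lie inside the
#'   prior box. Default: a prior draw.
#' @return An `abc_posterior` with `method = "mcmc"`; `samples` has one row
#'   per iteration (`iter`, `pm`, `alpha`, `dist`, `accepted` = whether the
#'   proposal at that iteration was accepted), plus the acceptance rate in
#'   `acceptance_rate`.
#' @export
abc_mcmc <- function(design, prior, observed, spec = distance_spec(),
                     epsilon, chain_length, proposal_scales = NULL,
                     init = NULL, seed = 1,
                     n_replicates = observed$n_replicates %||% 1) {
  stopifnot(inherits(prior, "abc_prior"))
  if (!is.numeric(epsilon) || epsilon <= 0)
    abort("`epsilon` must be positive.")
  if (chain_length < 1) abort("`chain_length` must be at least 1.")
  if (is.null(proposal_scales))
    proposal_scales <- 0.05 * c(diff(prior$pm_bounds),
                                diff(prior$alpha_bounds))
  set.seed(seed)
  if (is.null(init)) {
    d <- prior_draw(prior, 1)
    init <- c(d$pm, d$alpha)
  }
  if (!in_prior(prior, init[1], init[2]))
    abort("`init` lies outside the prior box.")

  simulate_distance <- function(pm, alpha) {
    if (is.infinite(epsilon)) return(0)
    params <- abm_params(pm, alpha, prior$model)
    ds <- generate_synthetic_data(design, params, n_replicates = n_replicates,
                                  seed = sample.int(2147483000L, 1))
    abc_distance(observed, ds, spec)
  }

  pm <- numeric(chain_length); alpha <- numeric(chain_length)
  dist <- numeric(chain_length); acc <- logical(chain_length)
  pm[1] <- init[1]; alpha[1] <- init[2]
  dist[1] <- simulate_distance(pm[1], alpha[1])
  acc[1] <- TRUE
  for (it in seq_len(chain_length)[-1]) {
    prop_pm <- pm[it - 1] + stats::rnorm(1, 0, proposal_scales[1])
    prop_alpha <- alpha[it - 1] + stats::rnorm(1, 0, proposal_scales[2])
    ok <- in_prior(prior, prop_pm, prop_alpha)
    if (ok) {
      d_prop <- simulate_distance(prop_pm, prop_alpha)
      ok <- d_prop <= epsilon
    }
    if (ok) {
      pm[it] <- prop_pm; alpha[it] <- prop_alpha; dist[it] <- d_prop
      acc[it] <- TRUE
    } else {
      pm[it] <- pm[it - 1]; alpha[it] <- alpha[it - 1]
      dist[it] <- dist[it - 1]; acc[it] <- FALSE
    }
  }
  structure(
    list(samples = tibble(iter = seq_len(chain_length), pm = pm,
                          alpha = alpha, dist = dist, accepted = acc),
         prior = prior, spec = spec, method = "mcmc", design = design,
         epsilon = epsilon, chain_length = as.integer(chain_length),
         proposal_scales = proposal_scales, seed = seed,
         n_replicates = as.integer(n_replicates),
         acceptance_rate = mean(acc[-1])),
    class = "abc_posterior"
  )
}

#' Scale-balancing weights for combined summary statistics
#'
#' When several summary statistics are combined into one distance their
#' raw magnitudes differ (a density profile contributes `Lx` terms in
#' \[0, 1\], a PCF contributes larger fluctuating ratios). This returns
#' `1 / median(per-statistic pilot distances)` so each statistic
#' contributes on a comparable scale; pass the result as `weights` to
#' [distance_spec()].
#'
#' @param pilot An `abc_posterior` from [abc_rejection()] (its stored
#'   per-statistic distances are used).
#' @param statistics Statistics to weight.
#' @return A named numeric vector of weights.
#' @export
pilot_weights <- function(pilot, statistics = c("pcf", "displacement",
                                                "density_profile")) {
  stopifnot(inherits(pilot, "abc_posterior"), pilot$method == "rejection")
  med <- vapply(statistics, function(s)
    stats::median(pilot$samples[[paste0("d_", s)]]), numeric(1))
  if (any(med == 0)) abort("a pilot median distance is zero; cannot weight.")
  1 / med
}

#' Pick an MCMC threshold from a pilot rejection run
#'
#' Nearest-rank empirical quantile of the pilot run's distances. The default
#' workflow uses the 1% quantile of a pilot rejection run as the ABC-MCMC
#' threshold.
#'
#' @param pilot An `abc_posterior` from [abc_rejection()], or a numeric
#'   vector of distances.
#' @param quantile Quantile level in (0, 1\].
#' @return The threshold (a single number).
#' @export
choose_epsilon <- function(pilot, quantile = 0.01) {
  d <- if (inherits(pilot, "abc_posterior")) pilot$samples$dist else
    as.numeric(pilot)
  if (length(d) == 0) abort("no pilot distances available.")
  if (quantile <= 0 || quantile > 1) abort("`quantile` must be in (0, 1].")
  sort(d)[max(1L, ceiling(quantile * length(d)))]
}

#' @export
print.abc_posterior <- function(x, ...) {
  if (x$method == "rejection") {
    cat(sprintf(
      "<abc_posterior> rejection: %d sims, %d accepted (statistic: %s)\n",
      x$n_sims, x$n_accept, paste(x$spec$statistics, collapse = "+")))
  } else {
    cat(sprintf(
      "<abc_posterior> MCMC: %d iterations, epsilon = %g, acceptance rate %.2f\n",
      x$chain_length, x$epsilon, x$acceptance_rate))
  }
  print(head(accepted_samples(x)))
  invisible(x)
}

#' Accepted parameter samples of a posterior
#'
#' For a rejection run, the accepted draws; for an MCMC run, the chain
#' states (every iteration).
#'
#' @param posterior An `abc_posterior`.
#' @return A tibble with columns `pm`, `alpha` (plus distances).
#' @export
accepted_samples <- function(posterior) {
  if (posterior$method == "rejection")
    filter(posterior$samples, .data$accepted)
  else posterior$samples
}

#' @export
tidy.abc_posterior <- function(x, ...) accepted_samples(x)

#' @export
glance.abc_posterior <- function(x, ...) {
  acc <- accepted_samples(x)
  base <- tibble(method = x$method, model = x$prior$model,
                 statistic = paste(x$spec$statistics, collapse = "+"),
                 n_samples = nrow(acc),
                 mean_pm = mean(acc$pm), mean_alpha = mean(acc$alpha),
                 min_dist = min(x$samples$dist))
  if (x$method == "mcmc")
    base$acceptance_rate <- x$acceptance_rate
  base
}
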