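#' Compare experimental designs by posterior information gain
#'
#' For each arm (a design plus a replicate count), generates a synthetic
#' dataset at the true parameters, runs rejection ABC against it, and
#' scores the arm by the Kullback-Leibler divergence of the discretised
#' posterior from the uniform prior, the posterior mode, and the mode's
#' distance to the truth. Arms use independent seed streams derived from
#' the master seed, so identical arms under the same seed give identical
#' results.
#'
#' @param arms Named list; each element is a list with elements `design`
#'   (an `experiment_design`) and optionally `n_replicates` (default: the
#'   design's).
#' @param params True [abm_params()] generating the observed data.
#' @param prior An [abc_prior()] for the inference.
#' @param spec A [distance_spec()].
#' @param n_sims,n_accept Rejection-ABC budget per arm.
#' @param seed Master seed.
#' @param n_bins Discretisation bins per parameter.
#' @return A tibble with one row per arm: `arm`, `Lx`, `Ly`,
#'   `n_replicates`, `kld`, `mode_pm`, `mode_alpha`, `mode_error`
#'   (Euclidean distance of the mode from the truth).
#' @export
compare_designs <- function(arms, params, prior, spec = distance_spec(),
                            n_sims = 200, n_accept = 20, seed = 1,
                            n_bins = 64) {
  if (length(arms) < 2) abort("need at least two arms to compare.")
  if (is.null(names(arms)) || any(names(arms) == ""))
    names(arms) <- paste0("arm", seq_along(arms))
  set.seed(seed)
  arm_seeds <- sample.int(2147480000L, length(arms))
  purrr::imap(arms, function(arm, nm) {
    design <- arm$design
    n_rep <- arm$n_replicates %||% design$n_replicates
    observed <- generate_synthetic_data(design, params, n_replicates = n_rep,
                                        seed = arm_seeds[[match(nm, names(arms))]])
    post <- abc_rejection(design, prior, observed, spec,
                          n_sims = n_sims, n_accept = n_accept,
                          seed = arm_seeds[[match(nm, names(arms))]] + 1L)
    g <- discretize_posterior(post, n_bins = n_bins)
    mode <- grid_mode(g)
    tibble(arm = nm, Lx = design$domain$Lx, Ly = design$domain$Ly,
           n_replicates = as.integer(n_rep),
           kld = kld(g, prior_grid(prior, n_bins)),
           mode_pm = mode$pm, mode_alpha = mode$alpha,
           mode_error = sqrt((mode$pm - params$pm)^2 +
                               (mode$alpha - params$alpha)^2))
  }) %>% bind_rows()
}

#' Variance of summary statistics across replicates and domain sizes
#'
#' Regenerates synthetic datasets over a grid of designs and replicate
#' counts and reports, per statistic element, the unbiased sample variance
#' across replicates within each dataset (`var_within`) together with the
#' dataset's ensemble average (`ens_value`). Averaging `var_within` over
#' datasets estimates the per-replicate noise of the statistic; the
#' variance of `ens_value` across datasets estimates the noise of the
#' ensemble average, which shrinks like 1/n_replicates.
#'
#' @param designs Named list of `experiment_design`s.
#' @param rep_counts Integer vector of replicate counts to cross with the
#'   designs.
#' @param params An [abm_params()].
#' @param statistic One of `"pcf"`, `"density_profile"`, `"displacement"`.
#' @param n_datasets Independent datasets per (design, replicate) cell.
#' @param seed Master seed.
#' @return A tibble with columns `design`, `Lx`, `Ly`, `n_rep`, `dataset`,
#'   `t`, `r`, `var_within`, `ens_value`.
#' @export
variance_study <- function(designs, rep_counts, params, statistic = "pcf",
                           n_datasets = 1, seed = 1) {
  statistic <- match.arg(statistic,
                         c("pcf", "density_profile", "displacement"))
  if (is.null(names(designs)) || any(names(designs) == ""))
    names(designs) <- paste0("design", seq_along(designs))
  set.seed(seed)
  cells <- tidyr::expand_grid(design = names(designs), n_rep = rep_counts,
                              dataset = seq_len(n_datasets))
  cell_seeds <- sample.int(2147000000L, nrow(cells))
  purrr::pmap(list(cells$design, cells$n_rep, cells$dataset,
                   cell_seeds), function(nm, n_rep, dataset, s) {
    des <- designs[[nm]]
    ds <- generate_synthetic_data(des, params, n_replicates = n_rep,
                                  seed = s, statistics = statistic)
    vw <- statistic_variance(ds$replicates)
    out <- left_join(vw, ds$ensemble, by = c("statistic", "t", "r"))
    tibble(design = nm, Lx = des$domain$Lx, Ly = des$domain$Ly,
           n_rep = as.integer(n_rep), dataset = dataset,
           t = out$t, r = out$r, var_within = out$variance,
           ens_value = out$value)
  }) %>% bind_rows()
}

#' Rank summary statistics by posterior information gain
#'
#' Runs one rejection-ABC simulation campaign and scores each summary
#' statistic by the KLD (from the uniform prior) of the posterior obtained
#' when that statistic alone defines the acceptance distance. Because a
#' rejection run stores per-statistic distances for every simulated
#' dataset, the three posteriors share the same simulations.
#'
#' @inheritParams compare_designs
#' @param design The `experiment_design` to simulate.
#' @param observed The observed `summary_dataset`.
#' @param statistics Statistics to rank.
#' @return A tibble with columns `statistic`, `kld`, `mode_pm`,
#'   `mode_alpha`, plus the underlying `abc_posterior`s as an attribute
#'   `"posteriors"`.
#' @export
rank_summary_statistics <- function(design, prior, observed,
                                    statistics = c("pcf", "displacement",
                                                   "density_profile"),
                                    n_sims = 500, n_accept = 25, seed = 1,
                                    n_bins = 64) {
  base <- abc_rejection(design, prior, observed,
                        spec = distance_spec(statistics[1],
                                             times = observed$design$times),
                        n_sims = n_sims, n_accept = n_accept, seed = seed)
  posts <- purrr::map(statistics, function(s) accept_top(base, s, n_accept))
  names(posts) <- statistics
  out <- purrr::imap(posts, function(p, s) {
    g <- discretize_posterior(p, n_bins = n_bins)
    mode <- grid_mode(g)
    tibble(statistic = s, kld = kld(g, prior_grid(p$prior, n_bins)),
           mode_pm = mode$pm, mode_alpha = mode$alpha)
  }) %>% bind_rows()
  attr(out, "posteriors") <- posts
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
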