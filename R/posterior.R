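#' Uniform prior on the discretisation grid
#'
#' The analytic prior grid: `n_bins` x `n_bins` equal-width bins spanning
#' the prior box, each with mass `1 / n_bins^2`. Analytic rather than
#' sampled, since the prior is known exactly.
#'
#' @param prior An [abc_prior()].
#' @param n_bins Bins per parameter (default `2^6 = 64`).
#' @return An object of class `grid_posterior`.
#' @export
prior_grid <- function(prior, n_bins = 64) {
  stopifnot(inherits(prior, "abc_prior"))
  new_grid_posterior(
    matrix(1 / n_bins^2, n_bins, n_bins), prior, n_bins)
}

new_grid_posterior <- function(prob, prior, n_bins) {
  structure(
    list(prob = prob,
         pm_edges = seq(prior$pm_bounds[1], prior$pm_bounds[2],
                        length.out = n_bins + 1),
         alpha_edges = seq(prior$alpha_bounds[1], prior$alpha_bounds[2],
                           length.out = n_bins + 1),
         prior = prior, n_bins = as.integer(n_bins)),
    class = "grid_posterior"
  )
}

#' Discretise posterior samples onto the parameter grid
#'
#' Normalised two-dimensional histogram of parameter samples on `n_bins`
#' equally spaced bins per parameter spanning the prior box (rows index
#' `Pm`, columns `alpha`). Bins are half-open with the last bin closed. No
#' smoothing is applied by default; set `bandwidth` for a Gaussian-kernel
#' density estimate evaluated at the bin centres instead.
#'
#' @param samples An `abc_posterior` (accepted samples / chain states are
#'   used) or a data frame with columns `pm` and `alpha`.
#' @param prior An [abc_prior()] defining the box (default: the
#'   posterior's own prior).
#' @param n_bins Bins per parameter (default 64).
#' @param bandwidth Optional `c(sd_pm, sd_alpha)` for KDE smoothing.
#' @return A `grid_posterior` whose `prob` matrix sums to 1.
#' @export
discretize_posterior <- function(samples, prior = NULL, n_bins = 64,
                                 bandwidth = NULL) {
  if (inherits(samples, "abc_posterior")) {
    if (is.null(prior)) prior <- samples$prior
    samples <- accepted_samples(samples)
  }
  if (is.null(prior)) abort("`prior` is required for plain sample tables.")
  if (!is.data.frame(samples) || !all(c("pm", "alpha") %in% names(samples)))
    abort("`samples` must have columns `pm` and `alpha`.")
  if (nrow(samples) == 0) abort("no samples to discretise.")
  if (!all(in_prior(prior, samples$pm, samples$alpha)))
    abort("samples outside the prior box cannot be discretised.")

  bin_of <- function(x, lo, hi) {
    b <- floor((x - lo) / (hi - lo) * n_bins) + 1
    as.integer(pmin(b, n_bins)) # right edge closed
  }
  i <- bin_of(samples$pm, prior$pm_bounds[1], prior$pm_bounds[2])
  j <- bin_of(samples$alpha, prior$alpha_bounds[1], prior$alpha_bounds[2])
  prob <- matrix(0, n_bins, n_bins)
  if (is.null(bandwidth)) {
    for (k in seq_along(i)) prob[i[k], j[k]] <- prob[i[k], j[k]] + 1
  } else {
    centers_pm <- midpoints(prior$pm_bounds, n_bins)
    centers_a <- midpoints(prior$alpha_bounds, n_bins)
    for (k in seq_len(nrow(samples))) {
      w <- outer(stats::dnorm(centers_pm, samples$pm[k], bandwidth[1]),
                 stats::dnorm(centers_a, samples$alpha[k], bandwidth[2]))
      prob <- prob + w / sum(w)
    }
  }
  new_grid_posterior(prob / sum(prob), prior, n_bins)
}

midpoints <- function(bounds, n) {
  e <- seq(bounds[1], bounds[2], length.out = n + 1)
  (e[-1] + e[-(n + 1)]) / 2
}

#' @export
print.grid_posterior <- function(x, ...) {
  cat(sprintf("<grid_posterior> %d x %d grid on Pm [%g, %g] x alpha [%g, %g]\n",
              x$n_bins, x$n_bins, x$pm_edges[1], x$pm_edges[x$n_bins + 1],
              x$alpha_edges[1], x$alpha_edges[x$n_bins + 1]))
  invisible(x)
}

#' @export
tidy.grid_posterior <- function(x, ...) {
  tibble(
    pm = rep(midpoints(range(x$pm_edges), x$n_bins), times = x$n_bins),
    alpha = rep(midpoints(range(x$alpha_edges), x$n_bins), each = x$n_bins),
    prob = as.vector(x$prob)
  )
}

#' Mode (highest-mass bin centre) of a grid posterior
#'
#' @param x A `grid_posterior`.
#' @return A one-row tibble with `pm`, `alpha`, `prob`.
#' @export
grid_mode <- function(x) {
  idx <- which(x$prob == max(x$prob), arr.ind = TRUE)[1, ]
  tibble(pm = midpoints(range(x$pm_edges), x$n_bins)[idx[1]],
         alpha = midpoints(range(x$alpha_edges), x$n_bins)[idx[2]],
         prob = max(x$prob))
}

#' Posterior mode of an ABC posterior
#'
#' Location of the highest-density bin of the discretised posterior. For
#' the small accepted sets typical of desk-scale rejection runs (tens of
#' samples on thousands of bins) the raw histogram mode is a count-1 bin
#' chosen almost arbitrarily, so by default the density is estimated with
#' a Gaussian kernel (bandwidth 5% of each prior width, the same fraction
#' used for the MCMC proposal scales) before taking the argmax. Set
#' `smooth = FALSE` for the raw histogram mode.
#'
#' @param posterior An `abc_posterior`.
#' @param n_bins Bins per parameter (default 64).
#' @param smooth Smooth the density estimate before locating the mode?
#' @param bandwidth Optional `c(sd_pm, sd_alpha)` kernel bandwidth;
#'   default 5% of each prior width.
#' @return A one-row tibble with `pm`, `alpha`, `prob`.
#' @export
posterior_mode <- function(posterior, n_bins = 64, smooth = TRUE,
                           bandwidth = NULL) {
  prior <- posterior$prior
  if (smooth && is.null(bandwidth))
    bandwidth <- 0.05 * c(diff(prior$pm_bounds), diff(prior$alpha_bounds))
  g <- discretize_posterior(posterior, n_bins = n_bins,
                            bandwidth = if (smooth) bandwidth)
  grid_mode(g)
}

#' Kullback-Leibler divergence from the prior
#'
#' `D_KL(p | pi) = sum_l p_l log(p_l / pi_l)` over grid cells, with the
#' convention `0 log 0 = 0`. Measures the information gained moving from
#' the prior to the posterior; 0 iff the two distributions coincide. The
#' default uses natural logarithms (nats); `base = "2"` reports bits as a
#' sensitivity check.
#'
#' @param posterior A `grid_posterior`.
#' @param prior A `grid_posterior` on the same grid; default the uniform
#'   [prior_grid()] of the posterior's prior box.
#' @param base `"e"` (nats, default) or `"2"` (bits).
#' @return A non-negative number.
#' @examples
#' pr <- abc_prior("A")
#' kld(prior_grid(pr)) # 0
#' @export
kld <- function(posterior, prior = NULL, base = c("e", "2")) {
  base <- match.arg(base)
  stopifnot(inherits(posterior, "grid_posterior"))
  if (is.null(prior)) prior <- prior_grid(posterior$prior, posterior$n_bins)
  if (!identical(dim(posterior$prob), dim(prior$prob)))
    abort("posterior and prior grids have different dimensions.")
  p <- as.vector(posterior$prob)
  q <- as.vector(prior$prob)
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    abort("grids must be normalised.")
  if (any(p > 0 & q == 0))
    abort("posterior has mass where the prior is zero; KLD undefined.")
  pos <- p > 0
  val <- sum(p[pos] * log(p[pos] / q[pos]))
  if (base == "2") val / log(2) else val
}

#' KLD of an ABC posterior relative to its own uniform prior
#'
#' Convenience wrapper: discretise the accepted samples (or chain states)
#' onto the grid and compute the divergence from the analytic
#' uniform prior grid.
#'
#' @param posterior An `abc_posterior`.
#' @param n_bins Bins per parameter (default 64).
#' @param base Log base, as in [kld()].
#' @return A non-negative number.
#' @export
posterior_kld <- function(posterior, n_bins = 64, base = "e") {
  g <- discretize_posterior(posterior, n_bins = n_bins)
  kld(g, prior_grid(posterior$prior, n_bins), base = base)
}
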