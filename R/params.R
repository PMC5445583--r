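#' Motility and adhesion parameters
#'
#' The model has two parameters: the movement attempt rate `pm` (per minute)
#' and the dimensionless adhesion parameter `alpha`. Positive `alpha` models
#' cell-cell adhesion (a crowded agent moves less), negative `alpha` models
#' repulsion. Two interaction models are supported; see
#' [transition_probability()].
#'
#' @param pm Movement attempt rate per minute; non-negative.
#' @param alpha Adhesion parameter; must lie inside
#'   [admissible_alpha_range()] for the chosen model.
#' @param model `"A"` (linear in neighbour count) or `"B"` (multiplicative).
#'
#' @return An object of class `abm_params`.
#' @examples
#' abm_params(0.5, 0.1, model = "A")
#' @export
abm_params <- function(pm, alpha, model = c("A", "B")) {
  model <- match.arg(model)
  if (!is.numeric(pm) || length(pm) != 1 || is.na(pm) || pm < 0)
    abort("`pm` must be a single non-negative number.")
  rng <- admissible_alpha_range(model)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha))
    abort("`alpha` must be a single number.")
  if (alpha < rng[[1]] || alpha > rng[[2]])
    abort(sprintf(
      "`alpha` = %g violates the admissibility constraint for model %s (sum of per-direction transition probabilities must lie in [0, 1]); admissible range is [%g, %g].",
      alpha, model, rng[[1]], rng[[2]]
    ))
  structure(list(pm = as.numeric(pm), alpha = as.numeric(alpha), model = model),
            class = "abm_params")
}

#' @export
print.abm_params <- function(x, ...) {
  cat(sprintf("<abm_params> model %s, Pm = %g /min, alpha = %g\n",
              x$model, x$pm, x$alpha))
  invisible(x)
}

#' Per-direction movement transition probability
#'
#' A selected agent with `n` occupied nearest-neighbour sites assigns the
#' same transition probability to each of its target directions:
#' \deqn{T_A = (1 - n\alpha)/4, \qquad T_B = (1-\alpha)^n/4.}
#' In model A crowding reduces movement linearly; in model B multiplicatively.
#'
#' @param model `"A"` or `"B"`.
#' @param alpha Adhesion parameter, inside [admissible_alpha_range()].
#' @param n Occupied-neighbour count(s), integers in 0..4 (vectorised).
#'
#' @return Numeric vector of transition probabilities, one per element of `n`.
#' @examples
#' transition_probability("A", 0.1, 0:4)
#' transition_probability("B", 0.25, 2) # (0.75)^2 / 4
#' @export
transition_probability <- function(model = c("A", "B"), alpha, n) {
  model <- match.arg(model)
  if (!is.numeric(n) || any(is.na(n)) || any(n != round(n)) ||
      any(n < 0) || any(n > 4))
    abort("`n` must contain integers between 0 and 4.")
  rng <- admissible_alpha_range(model)
  if (alpha < rng[[1]] || alpha > rng[[2]])
    abort(sprintf(
      "`alpha` = %g outside the admissible range [%g, %g] for model %s (per-direction probabilities must sum to at most 1 over unoccupied neighbours).",
      alpha, rng[[1]], rng[[2]], model
    ))
  if (model == "A") (1 - n * alpha) / 4 else (1 - alpha)^n / 4
}

#' Admissible range of the adhesion parameter
#'
#' The transition probabilities summed over an agent's unoccupied neighbour
#' sites must lie in `[0, 1]` for every occupied-neighbour count `n` in 0..4
#' and every number of unoccupied neighbours up to `4 - n`. This bounds
#' `alpha`: model A requires `-1/3 <= alpha <= 1/4` (the lower bound binds at
#' n = 1 with three free sites, the upper at n = 4 via non-negativity);
#' model B requires `-1/3 <= alpha <= 1`.
#'
#' @param model `"A"` or `"B"`.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' admissible_alpha_range("A")
#' @export
admissible_alpha_range <- function(model = c("A", "B")) {
  model <- match.arg(model)
  if (model == "A") c(-1 / 3, 1 / 4) else c(-1 / 3, 1)
}
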