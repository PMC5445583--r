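# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: the CTMC oracle enumerates the state
# space and exponentiates the generator, the pair-count oracle enumerates
# agent pairs, and the admissibility oracle scans a fine alpha grid.

# Neighbour directions of site (i, j): x never wraps, y wraps; a direction
# mapping to the site itself (Ly == 1) is dropped, duplicated wrap
# directions (Ly == 2) are kept as distinct directions.
oracle_directions <- function(i, j, Lx, Ly) {
  dirs <- list()
  if (i < Lx) dirs <- c(dirs, list(c(i + 1, j)))
  if (i > 1) dirs <- c(dirs, list(c(i - 1, j)))
  if (Ly > 1) {
    ju <- if (j == Ly) 1 else j + 1
    jd <- if (j == 1) Ly else j - 1
    dirs <- c(dirs, list(c(i, ju)), list(c(i, jd)))
  }
  dirs
}

# Enumerate the continuous-time Markov chain over occupancy sets of k
# agents on an Lx x Ly no-flux lattice and return the exact time-t
# distribution started from `init_sites` (site index = (i-1)*Ly + j).
oracle_ctmc_distribution <- function(Lx, Ly, init_sites, t, pm, alpha,
                                     model) {
  S <- Lx * Ly
  k <- length(init_sites)
  states <- utils::combn(S, k)
  key <- apply(states, 2, paste, collapse = ",")
  nst <- ncol(states)
  site_ij <- function(s) c((s - 1) %/% Ly + 1, (s - 1) %% Ly + 1)
  trans_prob <- function(n) {
    if (model == "A") (1 - n * alpha) / 4 else (1 - alpha)^n / 4
  }
  Q <- matrix(0, nst, nst)
  for (s1 in seq_len(nst)) {
    occ <- states[, s1]
    for (v in occ) {
      ij <- site_ij(v)
      dirs <- oracle_directions(ij[1], ij[2], Lx, Ly)
      n <- sum(vapply(dirs, function(d) {
        ((d[1] - 1) * Ly + d[2]) %in% occ
      }, logical(1)))
      for (d in dirs) {
        u <- (d[1] - 1) * Ly + d[2]
        if (u %in% occ) next
        new_occ <- sort(c(setdiff(occ, v), u))
        s2 <- match(paste(new_occ, collapse = ","), key)
        Q[s1, s2] <- Q[s1, s2] + pm * trans_prob(n)
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  p0 <- numeric(nst)
  p0[match(paste(sort(init_sites), collapse = ","), key)] <- 1
  p <- as.numeric(p0 %*% as.matrix(Matrix::expm(Q * t)))
  names(p) <- key
  p
}

# Map an occupancy state to the oracle's state key.
oracle_state_key <- function(state) {
  Ly <- state$domain$Ly
  sites <- (state$agents$col - 1) * Ly + state$agents$row
  paste(sort(sites), collapse = ",")
}

# Brute-force horizontal pair counts by pair enumeration.
oracle_pair_counts <- function(state) {
  cols <- state$agents$col
  Lx <- state$domain$Lx
  if (length(cols) < 2) return(rep(0, Lx - 1))
  d <- abs(outer(cols, cols, "-"))
  d <- d[upper.tri(d)]
  tabulate(d[d > 0], nbins = Lx - 1)
}

# Brute-force admissible alpha interval: scan a fine grid and keep alphas
# for which, for every n in 0..4 and every unoccupied-neighbour count
# u <= 4 - n, the summed transition probability u * T(n) lies in [0, 1].
oracle_admissible_range <- function(model, grid = seq(-2, 2, by = 1e-4)) {
  ok <- vapply(grid, function(a) {
    for (n in 0:4) {
      T <- if (model == "A") (1 - n * a) / 4 else (1 - a)^n / 4
      for (u in 0:(4 - n)) {
        s <- u * T
        if (s < -1e-12 || s > 1 + 1e-12) return(FALSE)
      }
      if (T < -1e-12) return(FALSE)
    }
    TRUE
  }, logical(1))
  range(grid[ok])
}

# Random small occupancy state on an Lx x Ly lattice.
random_state <- function(Lx, Ly, N) {
  N <- min(N, Lx * Ly)
  sites <- sample.int(Lx * Ly, N)
  occupancy_state(
    tibble::tibble(
      id = seq_len(N),
      col = (sites - 1) %/% Ly + 1L,
      row = (sites - 1) %% Ly + 1L,
      init_col = (sites - 1) %/% Ly + 1L
    ),
    abm_domain(Lx, Ly)
  )
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
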