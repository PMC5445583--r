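#' Read and write occupancy matrices
#'
#' Occupancy states are serialised as a CSV of 0/1 integers with `Ly` rows
#' and `Lx` columns (row 1 is lattice row `j = 1`, no header) plus a JSON
#' sidecar `<path>.json` holding the domain metadata (`Lx`, `Ly`, `delta`,
#' boundary behaviour).
#'
#' @param state An [occupancy_state()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_occupancy_csv()` returns `path` invisibly;
#'   `read_occupancy_csv()` returns an [occupancy_state()].
#' @export
write_occupancy_csv <- function(state, path) {
  g <- as_grid(state)
  utils::write.table(g, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  d <- state$domain
  jsonlite::write_json(
    list(Lx = d$Lx, Ly = d$Ly, delta = d$delta, x_boundary = d$x_boundary,
         y_boundary = "periodic"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_occupancy_csv
#' @export
read_occupancy_csv <- function(path) {
  g <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(g) <- NULL
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    domain <- abm_domain(meta$Lx, meta$Ly, delta = meta$delta,
                         x_boundary = meta$x_boundary)
  } else {
    domain <- abm_domain(ncol(g), nrow(g))
  }
  state_from_grid(g, domain)
}

#' Write each snapshot of a record as an occupancy CSV
#'
#' Files are named `<prefix>_t<time>.csv` (plus JSON sidecars).
#'
#' @param record An `abm_record`.
#' @param prefix Path prefix.
#' @return The written CSV paths, invisibly.
#' @export
write_record_csv <- function(record, prefix) {
  paths <- purrr::map2_chr(record$times, record$snapshots, function(t, s) {
    p <- sprintf("%s_t%g.csv", prefix, t)
    write_occupancy_csv(s, p)
    p
  })
  invisible(paths)
}

#' Read and write summary datasets
#'
#' A dataset is serialised as `<prefix>.csv` (long table: `rep`,
#' `statistic`, `t`, `r`, `value`; the ensemble average is recomputed on
#' read) plus `<prefix>.json` with the generating parameters, design name,
#' replicate count and seed. Floating-point values keep full precision.
#'
#' @param dataset A `summary_dataset`.
#' @param prefix Path prefix (no extension).
#' @return `write_summary_dataset()` returns `prefix` invisibly;
#'   `read_summary_dataset()` returns a `summary_dataset` (with `design`
#'   reduced to its recorded metadata).
#' @export
write_summary_dataset <- function(dataset, prefix) {
  readr::write_csv(dataset$replicates, paste0(prefix, ".csv"))
  jsonlite::write_json(
    list(model = dataset$params$model, pm = dataset$params$pm,
         alpha = dataset$params$alpha, design = dataset$design$name,
         Lx = dataset$design$domain$Lx, Ly = dataset$design$domain$Ly,
         times = dataset$design$times,
         n_replicates = dataset$n_replicates, seed = dataset$seed),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_summary_dataset
#' @export
read_summary_dataset <- function(prefix) {
  reps <- readr::read_csv(paste0(prefix, ".csv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  structure(
    list(replicates = reps, ensemble = ensemble_average(reps),
         params = abm_params(meta$pm, meta$alpha, meta$model),
         design = meta, n_replicates = meta$n_replicates, seed = meta$seed),
    class = "summary_dataset")
}

#' Write an ABC posterior (samples + metadata)
#'
#' Samples go to `<prefix>.csv`; the prior box, method, distance spec and
#' provenance go to `<prefix>.json`.
#'
#' @param posterior An `abc_posterior`.
#' @param prefix Path prefix (no extension).
#' @return `write_posterior()` returns `prefix` invisibly;
#'   `read_posterior()` returns an `abc_posterior` (design not restored).
#' @export
write_posterior <- function(posterior, prefix) {
  readr::write_csv(posterior$samples, paste0(prefix, ".csv"))
  meta <- list(method = posterior$method, model = posterior$prior$model,
               pm_bounds = posterior$prior$pm_bounds,
               alpha_bounds = posterior$prior$alpha_bounds,
               statistics = posterior$spec$statistics,
               times = posterior$spec$times, seed = posterior$seed,
               n_replicates = posterior$n_replicates)
  if (posterior$method == "rejection") {
    meta$n_sims <- posterior$n_sims
    meta$n_accept <- posterior$n_accept
  } else {
    meta$epsilon <- posterior$epsilon
    meta$chain_length <- posterior$chain_length
    meta$acceptance_rate <- posterior$acceptance_rate
  }
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(prefix) {
  samples <- readr::read_csv(paste0(prefix, ".csv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  prior <- abc_prior(meta$model, meta$pm_bounds, meta$alpha_bounds)
  out <- list(samples = samples, prior = prior,
              spec = distance_spec(meta$statistics, meta$times),
              method = meta$method, design = NULL, seed = meta$seed,
              n_replicates = meta$n_replicates)
  if (meta$method == "rejection") {
    out$n_sims <- meta$n_sims; out$n_accept <- meta$n_accept
  } else {
    out$epsilon <- meta$epsilon; out$chain_length <- meta$chain_length
    out$acceptance_rate <- meta$acceptance_rate
  }
  structure(out, class = "abc_posterior")
}
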