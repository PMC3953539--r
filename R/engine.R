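#' Run one simulation
#'
#' Initializes a world from the configuration and advances it `n_steps`
#' time steps. Within each step every agent -- signalers, receivers, food
#' items and display items -- acts exactly once, in one uniformly random
#' permutation drawn for that step. Display flags are cleared at the start
#' of each step; a display spans the whole step, so receivers that observed
#' during a step register every signaler that displayed in it.
#'
#' Identical `(config, seed)` pairs give bit-identical results across
#' processes.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed for the run (defaults to `config$seed`).
#' @param n_steps Number of steps to advance (defaults to `config$n_steps`);
#'   `0` returns the freshly initialized world.
#' @param record Logical; keep per-step history (display flags, energies,
#'   item populations, scheduler audit counts). Intended for small runs.
#' @return An object of class `run_result` with components
#'   `true_efforts` (integer vector, one per signaler), `estimates`
#'   (receivers x signalers matrix), `lost_opportunities` (count of steps
#'   in which a signaler had the energy to display but could not find a
#'   display item), `state` (final world snapshot), `config`, `seed` and,
#'   if `record = TRUE`, `history`.
#' @examples
#' res <- run_sim(sim_config(n_steps = 100, n_food_init = 500), seed = 42)
#' res
#' @export
run_sim <- function(config, seed = config$seed, n_steps = config$n_steps,
                    record = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  validate_config(config)
  cfg <- unclass(config)
  cfg$n_steps <- as.integer(n_steps)
  cfg$record <- isTRUE(record)
  set.seed(as.integer(seed))
  raw <- cpp_simulate(cfg)

  n_s <- config$n_signalers
  n_r <- config$n_receivers
  sig_ids <- sprintf("signaler_%02d", seq_len(n_s) - 1L)
  rec_ids <- sprintf("receiver_%02d", seq_len(n_r) - 1L)
  efforts <- stats::setNames(raw$true_efforts, sig_ids)
  est <- raw$estimates
  dimnames(est) <- list(rec_ids, sig_ids)

  structure(list(
    true_efforts = efforts,
    estimates = est,
    lost_opportunities = as.numeric(raw$lost_opportunities),
    state = raw[c("signalers", "receivers", "food", "display_items", "pop_max")],
    history = raw$history,
    config = config,
    seed = as.integer(seed),
    n_steps = as.integer(n_steps)
  ), class = "run_result")
}

#' Initialize a world without stepping it
#'
#' Convenience wrapper around [run_sim()] with `n_steps = 0`: returns the
#' state of a freshly initialized world (agent positions and integer
#' energies, item positions and ages, shuffled receiver tours).
#'
#' @inheritParams run_sim
#' @return A `run_result` whose `state` is the initial world; efforts and
#'   estimates are all zero.
#' @export
init_world <- function(config, seed = config$seed) {
  run_sim(config, seed = seed, n_steps = 0)
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result> build ", format(x$config$flags),
      ", ", x$n_steps, " steps, seed ", x$seed, "\n", sep = "")
  cat(sprintf("  true display effort: min %d, median %g, max %d\n",
              min(x$true_efforts), stats::median(x$true_efforts),
              max(x$true_efforts)))
  cat(sprintf("  Kendall's W = %.4f; lost opportunities = %g\n",
              run_concordance(x), x$lost_opportunities))
  invisible(x)
}

#' Assemble the judges-by-signalers rating table of a run
#'
#' Row 1 holds the true display efforts; the remaining rows hold each
#' receiver's estimate vector. With the default 20 receivers this is the
#' 21-judge table (equivalently, a 20 x 21 table with signalers as rows)
#' summarizing one run.
#'
#' @param result A `run_result`.
#' @return A numeric matrix with `n_receivers + 1` rows and one column per
#'   signaler.
#' @export
rating_table <- function(result) {
  stopifnot(inherits(result, "run_result"))
  rbind(true_effort = result$true_efforts, result$estimates)
}

#' Write a run to disk
#'
#' Writes the per-signaler rating table as CSV (signalers as rows; columns
#' `true_effort`, `receiver_00`, ..., one per receiver) plus a JSON sidecar
#' echoing the configuration, seed and lost-opportunity count.
#'
#' @param result A `run_result`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the two files.
#' @return Invisibly, the paths written.
#' @export
write_run_result <- function(result, dir, name = "run") {
  stopifnot(inherits(result, "run_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- t(rating_table(result))
  df <- data.frame(signaler = rownames(tab), tab, check.names = FALSE,
                   row.names = NULL)
  csv <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(df, csv, row.names = FALSE)
  meta <- file.path(dir, paste0(name, ".json"))
  cfg <- unclass(result$config)
  cfg$flags <- unclass(cfg$flags)
  jsonlite::write_json(
    list(config = cfg, seed = result$seed, n_steps = result$n_steps,
         lost_opportunities = result$lost_opportunities),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, meta))
}
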