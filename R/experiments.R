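#' Specify a full-factorial sweep
#'
#' A sweep crosses model builds with food abundances (and display-item
#' abundances where display items exist) and replicate seeds. The default
#' grid spans the 250--25000 item range with roughly logarithmic spacing.
#'
#' @param food_levels Integer vector of initial food counts.
#' @param display_levels Integer vector of initial display-item counts;
#'   varied only in builds with `items_needed = TRUE`.
#' @param builds List of [build_flags()] (default: all eight).
#' @param replicates Replicate runs per design cell.
#' @param base_config [sim_config()] supplying all other parameters.
#' @param master_seed Integer; per-run seeds are derived deterministically
#'   from it, so runs may be executed in any order (or in parallel) with
#'   identical results.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(food_levels = c(250, 1000, 2500, 5000, 10000, 25000),
                       display_levels = c(250, 2500, 25000),
                       builds = all_builds(), replicates = 10,
                       base_config = sim_config(), master_seed = 1L) {
  stopifnot(length(food_levels) >= 1, all(food_levels > 0),
            length(display_levels) >= 1, all(display_levels > 0),
            replicates >= 1, length(builds) >= 1,
            all(vapply(builds, inherits, logical(1), "build_flags")),
            inherits(base_config, "sim_config"))
  structure(list(food_levels = sort(unique(as.integer(food_levels))),
                 display_levels = sort(unique(as.integer(display_levels))),
                 builds = builds, replicates = as.integer(replicates),
                 base_config = base_config,
                 master_seed = as.integer(master_seed)),
            class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat("<sweep_spec> ", length(x$builds), " builds x ",
      length(x$food_levels), " food levels (display levels: ",
      paste(x$display_levels, collapse = ", "), ") x ",
      x$replicates, " replicates = ", nrow(sweep_design(x)), " runs\n",
      sep = "")
  invisible(x)
}

# tidy design table of a sweep: one row per run, with its derived seed
sweep_design <- function(spec) {
  rows <- list()
  for (b in seq_along(spec$builds)) {
    fl <- spec$builds[[b]]
    disp <- if (fl$items_needed) spec$display_levels else NA_integer_
    g <- expand.grid(replicate = seq_len(spec$replicates),
                     display_level = disp, food_level = spec$food_levels)
    g$build <- b
    rows[[b]] <- g
  }
  d <- do.call(rbind, rows)
  d$items_needed <- vapply(spec$builds, `[[`, logical(1), "items_needed")[d$build]
  d$sequential <- vapply(spec$builds, `[[`, logical(1), "sequential")[d$build]
  d$realtime <- vapply(spec$builds, `[[`, logical(1), "realtime")[d$build]
  # unique reproducible per-run seeds, a pure function of the master seed
  set.seed(spec$master_seed)
  d$seed <- sample.int(.Machine$integer.max, nrow(d))
  d[c("build", "items_needed", "sequential", "realtime",
      "food_level", "display_level", "replicate", "seed")]
}

#' Execute a full-factorial sweep
#'
#' Runs every design cell and replicate, computing the run's Kendall's W
#' and lost-opportunity count. Runs are independent: each uses its own
#' derived seed, so execution order does not affect results.
#'
#' @param spec A [sweep_spec()].
#' @param verbose Print a progress line per run.
#' @return A data.frame (class `sweep_table`) with one row per run:
#'   `items_needed`, `sequential`, `realtime` (0/1), `food_level`,
#'   `display_level` (`NA` where display items do not exist), `replicate`,
#'   `seed`, `W`, `lost_opportunities`.
#' @examples
#' \donttest{
#' sp <- sweep_spec(food_levels = c(250, 2500), display_levels = 2500,
#'                  replicates = 2,
#'                  base_config = sim_config(n_steps = 200))
#' tab <- factorial_sweep(sp)
#' }
#' @export
factorial_sweep <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  d <- sweep_design(spec)
  d$W <- NA_real_
  d$lost_opportunities <- NA_real_
  for (i in seq_len(nrow(d))) {
    cfg <- spec$base_config
    cfg$flags <- spec$builds[[d$build[i]]]
    cfg$n_food_init <- cfg$food_capacity <- d$food_level[i]
    if (cfg$flags$items_needed)
      cfg$n_display_init <- cfg$display_capacity <- d$display_level[i]
    res <- tryCatch(run_sim(cfg, seed = d$seed[i]), error = function(e)
      stop(sprintf("run failed in cell build=%s food=%d display=%s replicate=%d: %s",
                   format(cfg$flags), d$food_level[i],
                   format(d$display_level[i]), d$replicate[i],
                   conditionMessage(e)), call. = FALSE))
    d$W[i] <- run_concordance(res)
    d$lost_opportunities[i] <- res$lost_opportunities
    if (verbose)
      message(sprintf("[%d/%d] %s food=%d display=%s W=%.3f",
                      i, nrow(d), format(cfg$flags), d$food_level[i],
                      format(d$display_level[i]), d$W[i]))
  }
  d$items_needed <- as.integer(d$items_needed)
  d$sequential <- as.integer(d$sequential)
  d$realtime <- as.integer(d$realtime)
  out <- d[c("items_needed", "sequential", "realtime", "food_level",
             "display_level", "replicate", "seed", "W",
             "lost_opportunities")]
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Lost signaling opportunities by resource abundance
#'
#' Mean and standard error of the per-run lost-opportunity count -- steps
#' in which a signaler had the energy to display but could not locate a
#' display item -- grouped by food and display abundance. Only meaningful
#' where signalers need items, so rows with `items_needed = 0` are
#' excluded.
#'
#' @param table A `sweep_table` from [factorial_sweep()].
#' @return A data.frame with `food_level`, `display_level`, `mean_lost`,
#'   `sem` (0 for single-run cells) and `n`. If the table has no
#'   `items_needed = 1` rows, a zero-row data.frame is returned with a
#'   warning.
#' @export
lost_opportunity_summary <- function(table) {
  stopifnot(is.data.frame(table))
  sel <- table[table$items_needed == 1, , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no items_needed = 1 runs: lost opportunities are undefined",
            call. = FALSE)
    return(data.frame(food_level = integer(0), display_level = integer(0),
                      mean_lost = numeric(0), sem = numeric(0),
                      n = integer(0)))
  }
  agg <- group_mean_sem(sel$lost_opportunities,
                        sel[c("food_level", "display_level")])
  names(agg)[names(agg) == "mean"] <- "mean_lost"
  agg
}

# mean +/- s.e.m. of x within groups; sem = 0 when n = 1
group_mean_sem <- function(x, groups) {
  key <- interaction(groups, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_along(x), key)
  out <- unique(cbind(groups, key = key))
  out <- out[match(names(idx), out$key), , drop = FALSE]
  out$key <- NULL
  out$mean <- vapply(idx, function(i) mean(x[i]), numeric(1))
  out$sem <- vapply(idx, function(i)
    if (length(i) > 1) stats::sd(x[i]) / sqrt(length(i)) else 0, numeric(1))
  out$n <- lengths(idx)
  rownames(out) <- NULL
  out
}

#' Write a sweep table and its manifest
#'
#' @param table A `sweep_table`.
#' @param dir Output directory (created if needed).
#' @param spec Optional [sweep_spec()] echoed into a JSON manifest.
#' @param name Basename for the files.
#' @return Invisibly, the paths written.
#' @export
write_sweep <- function(table, dir, spec = NULL, name = "sweep") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(table), csv, row.names = FALSE)
  paths <- csv
  if (!is.null(spec)) {
    manifest <- file.path(dir, paste0(name, "_manifest.json"))
    cfg <- unclass(spec$base_config)
    cfg$flags <- NULL
    jsonlite::write_json(
      list(food_levels = spec$food_levels,
           display_levels = spec$display_levels,
           builds = lapply(spec$builds, function(b) unclass(b)),
           replicates = spec$replicates, master_seed = spec$master_seed,
           base_config = cfg),
      manifest, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, manifest)
  }
  invisible(paths)
}
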