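#' Build flags for the factorial model design
#'
#' The three dichotomies that define the eight model builds:
#' whether signalers must secure an external display item before displaying,
#' whether receivers assess signalers sequentially (one territory per time
#' step) rather than all at once as on a lek, and whether receivers can only
#' witness displays in real time rather than reading a cumulative record of
#' effort (a structure such as a nest or bower).
#'
#' @param items_needed Logical; must a display item be found before display?
#' @param sequential Logical; sequential territory visits (`TRUE`) vs. lek
#'   observation of all displaying signalers at once (`FALSE`).
#' @param realtime Logical; count displays as they happen (`TRUE`) vs. read
#'   the signaler's cumulative display effort at each observation (`FALSE`).
#' @return An object of class `build_flags`.
#' @seealso [all_builds()]
#' @export
build_flags <- function(items_needed = FALSE, sequential = FALSE, realtime = FALSE) {
  for (nm in c("items_needed", "sequential", "realtime")) {
    v <- get(nm)
    if (!is.logical(v) || length(v) != 1L || is.na(v))
      stop("'", nm, "' must be TRUE or FALSE", call. = FALSE)
  }
  structure(list(items_needed = items_needed, sequential = sequential,
                 realtime = realtime),
            class = "build_flags")
}

#' All eight builds of the factorial design
#'
#' @return A list of eight [build_flags()] objects covering every
#'   combination of the three dichotomies.
#' @export
all_builds <- function() {
  g <- expand.grid(realtime = c(FALSE, TRUE), sequential = c(FALSE, TRUE),
                   items_needed = c(FALSE, TRUE))
  lapply(seq_len(nrow(g)), function(i)
    build_flags(g$items_needed[i], g$sequential[i], g$realtime[i]))
}

#' @export
format.build_flags <- function(x, ...) {
  paste0(if (x$items_needed) "items" else "no-items", "/",
         if (x$sequential) "sequential" else "lek", "/",
         if (x$realtime) "realtime" else "cumulative")
}

#' @export
print.build_flags <- function(x, ...) {
  cat("<build_flags> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Configuration of a single simulation run
#'
#' Collects every tunable parameter of one run. Defaults are the study
#' conditions: 20 signalers and 20 receivers on a 500 x 500 continuous
#' torus, 1440 time steps, perception neighbourhood 10, energy threshold
#' 500, initial energies drawn as integers on 0--1000, 10% item
#' reproduction below carrying capacity, item ages drawn on 0--100 with
#' maximum age 100.
#'
#' The three energy-flow parameters are not part of the published design
#' and are exposed here: `step_cost` (energy spent per time step, display
#' steps included), `food_energy` (mean energy yield per food item) and
#' `move_step` (displacement of a random move, coupled by default to the
#' perception radius). See the package vignette for how their defaults
#' were fixed.
#'
#' @param n_signalers,n_receivers Agent counts.
#' @param arena_side Side of the square toroidal arena.
#' @param n_steps Number of discrete time steps per run.
#' @param neighborhood Perception radius for food and display items.
#' @param energy_threshold Energy below which an agent must forage.
#' @param init_energy_min,init_energy_max Bounds of the uniform integer
#'   draw for initial energy reserves.
#' @param n_food_init,n_display_init Initial item counts (display items are
#'   only instantiated in builds with `items_needed = TRUE`).
#' @param reproduce_prob Per-item, per-step reproduction probability while
#'   the item population is under its carrying capacity.
#' @param max_age Item age at which an item dies.
#' @param step_cost Energy consumed by every agent in every time step.
#' @param food_energy Mean energy yield of a food item; realized yields are
#'   exponentially distributed with this mean, so bout lengths stay
#'   aperiodic across agents.
#' @param move_step Length of a random-heading move.
#' @param food_capacity,display_capacity Item carrying capacities; default
#'   (`NULL`) is the corresponding initial count.
#' @param flags A [build_flags()] object selecting the model build.
#' @param seed Default RNG seed used by [run_sim()] when none is given.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_food_init = 1000, flags = build_flags(sequential = TRUE))
#' cfg
#' @export
sim_config <- function(n_signalers = 20, n_receivers = 20, arena_side = 500,
                       n_steps = 1440, neighborhood = 10,
                       energy_threshold = 500,
                       init_energy_min = 0, init_energy_max = 1000,
                       n_food_init = 2500, n_display_init = 2500,
                       reproduce_prob = 0.1, max_age = 100,
                       step_cost = 1, food_energy = 1.15, move_step = 10,
                       food_capacity = NULL, display_capacity = NULL,
                       flags = build_flags(), seed = 1L) {
  cfg <- list(n_signalers = n_signalers, n_receivers = n_receivers,
              arena_side = arena_side, n_steps = n_steps,
              neighborhood = neighborhood,
              energy_threshold = energy_threshold,
              init_energy_min = init_energy_min,
              init_energy_max = init_energy_max,
              n_food_init = n_food_init, n_display_init = n_display_init,
              reproduce_prob = reproduce_prob, max_age = max_age,
              step_cost = step_cost, food_energy = food_energy,
              move_step = move_step,
              food_capacity = if (is.null(food_capacity)) n_food_init else food_capacity,
              display_capacity = if (is.null(display_capacity)) n_display_init else display_capacity,
              flags = flags, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_config <- function(cfg) {
  chk <- function(cond, field, what) {
    if (!cond) stop("invalid '", field, "': must be ", what, call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  count_fields <- c("n_signalers", "n_receivers", "n_steps", "n_food_init",
                    "n_display_init", "max_age", "food_capacity",
                    "display_capacity")
  for (f in count_fields)
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] == round(cfg[[f]]),
        f, "a non-negative integer")
  chk(cfg$n_steps >= 0, "n_steps", "non-negative")
  for (f in c("arena_side", "neighborhood", "energy_threshold",
              "init_energy_min", "init_energy_max", "step_cost",
              "food_energy", "move_step"))
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0, f, "a non-negative number")
  chk(cfg$arena_side > 0, "arena_side", "positive")
  chk(num1(cfg$reproduce_prob) && cfg$reproduce_prob >= 0 && cfg$reproduce_prob <= 1,
      "reproduce_prob", "a probability in [0, 1]")
  chk(cfg$init_energy_max >= cfg$init_energy_min, "init_energy_max",
      ">= init_energy_min")
  chk(inherits(cfg$flags, "build_flags"), "flags", "a build_flags object")
  chk(num1(cfg$seed), "seed", "a single number")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> build ", format(x$flags), "\n", sep = "")
  cat(sprintf("  %d signalers, %d receivers on %g x %g torus, %d steps\n",
              x$n_signalers, x$n_receivers, x$arena_side, x$arena_side,
              x$n_steps))
  cat(sprintf("  food %d (cap %d), display %s, neighbourhood %g, threshold %g\n",
              x$n_food_init, x$food_capacity,
              if (x$flags$items_needed)
                sprintf("%d (cap %d)", x$n_display_init, x$display_capacity)
              else "-", x$neighborhood, x$energy_threshold))
  cat(sprintf("  step_cost %g, food_energy %g, move_step %g, seed %s\n",
              x$step_cost, x$food_energy, x$move_step, format(x$seed)))
  invisible(x)
}
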