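#' One step of resource-item population dynamics
#'
#' Reference implementation of the item life cycle used for both food and
#' display items (the compiled engine applies the identical rule within
#' the per-step agent permutation). Each item ages by one step; items
#' reaching `max_age` die; each surviving item reproduces with probability
#' `reproduce_prob` while the population is below `capacity`. Offspring
#' have age 0 and a uniform random location, so the population can never
#' exceed the carrying capacity.
#'
#' Items act in row order; births within the step count towards the
#' capacity check for later items.
#'
#' @param items Data frame with columns `x`, `y`, `age`.
#' @param capacity Carrying capacity (`>= 0`).
#' @param reproduce_prob Per-item reproduction probability.
#' @param max_age Age at which an item dies.
#' @param side Arena side for offspring placement.
#' @return Updated items data frame (survivors first, then births).
#' @examples
#' it <- data.frame(x = runif(5, 0, 500), y = runif(5, 0, 500), age = 99)
#' item_population_step(it, capacity = 10, max_age = 100) # all die at 100
#' @export
item_population_step <- function(items, capacity, reproduce_prob = 0.1,
                                 max_age = 100, side = 500) {
  stopifnot(is.data.frame(items), all(c("x", "y", "age") %in% names(items)),
            capacity >= 0, reproduce_prob >= 0, reproduce_prob <= 1)
  n0 <- nrow(items)
  age <- items$age + 1L
  keep <- age < max_age
  pop <- sum(keep)
  births <- list()
  for (i in which(keep)) {
    if (pop < capacity && stats::runif(1) < reproduce_prob) {
      births[[length(births) + 1L]] <-
        data.frame(x = stats::runif(1, 0, side), y = stats::runif(1, 0, side),
                   age = 0L)
      pop <- pop + 1L
    }
  }
  out <- items[keep, , drop = FALSE]
  out$age <- age[keep]
  if (length(births)) out <- rbind(out, do.call(rbind, births))
  rownames(out) <- NULL
  out
}
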