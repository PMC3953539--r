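#' Partial eta-squared from sums of squares
#'
#' `SS_factor / (SS_factor + SS_error)`: the share of the variation not
#' explained by the other terms that this factor accounts for.
#'
#' @param ss_factor,ss_error Sums of squares.
#' @return Partial eta-squared in `[0, 1]` (`NaN` if both are zero).
#' @examples
#' partial_eta_squared(1, 3) # 0.25
#' @export
partial_eta_squared <- function(ss_factor, ss_error) {
  ss_factor / (ss_factor + ss_error)
}

#' General linear model of concordance on the design factors
#'
#' Ordinary least squares of per-run Kendall's W on food abundance and the
#' three binary build factors, with an intercept:
#' `W ~ food + items_needed + sequential + realtime`.
#'
#' Food enters by default as a fraction of the largest food level in the
#' table (`food_coding = "fraction"`), keeping its coefficient on a scale
#' commensurate with W; `"raw"` uses the item count itself. The binary
#' factor coefficients do not depend on this choice in a (near-)balanced
#' design. Partial eta-squared per term uses sequential (Type-I) sums of
#' squares in the model's term order by default; `ss_type = "marginal"`
#' uses each term's SS adjusted for all others ([stats::drop1()]).
#'
#' @param table A `sweep_table` from [factorial_sweep()] (or any data.frame
#'   with columns `W`, `food_level`, `items_needed`, `sequential`,
#'   `realtime`).
#' @param food_coding `"fraction"` or `"raw"`.
#' @param ss_type `"sequential"` or `"marginal"`.
#' @return An object of class `signal_glm`: a list with `table` (one row
#'   per term: `term`, `estimate`, `std_error`, `t_value`, `eta_sq_partial`,
#'   `p_value`), `model` (the underlying `lm` fit), `residual_df`,
#'   `food_coding` and `ss_type`.
#' @export
fit_glm <- function(table, food_coding = c("fraction", "raw"),
                    ss_type = c("sequential", "marginal")) {
  food_coding <- match.arg(food_coding)
  ss_type <- match.arg(ss_type)
  stopifnot(is.data.frame(table),
            all(c("W", "food_level", "items_needed", "sequential",
                  "realtime") %in% names(table)))
  d <- data.frame(
    W = table$W,
    food = if (food_coding == "fraction")
      table$food_level / max(table$food_level) else table$food_level,
    items_needed = as.numeric(table$items_needed),
    sequential = as.numeric(table$sequential),
    realtime = as.numeric(table$realtime))
  preds <- c("food", "items_needed", "sequential", "realtime")
  n_lev <- vapply(d[preds], function(x) length(unique(x)), integer(1))
  if (any(n_lev < 2))
    stop("predictor(s) without variation: ",
         paste(preds[n_lev < 2], collapse = ", "), call. = FALSE)
  fit <- stats::lm(W ~ food + items_needed + sequential + realtime, data = d)
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    al <- stats::alias(fit)$Complete
    stop("rank-deficient design; collinear terms: ",
         paste(rownames(al), collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  ss_err <- sum(stats::residuals(fit)^2)
  if (ss_type == "sequential") {
    av <- stats::anova(fit)
    ss <- av[preds, "Sum Sq"]
  } else {
    d1 <- stats::drop1(fit, test = "F")
    ss <- d1[preds, "Sum of Sq"]
  }
  eta <- partial_eta_squared(ss, ss_err)
  tab <- data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    t_value = sm[, "t value"],
    eta_sq_partial = c(NA_real_, eta),
    p_value = sm[, "Pr(>|t|)"],
    row.names = NULL)
  structure(list(table = tab, model = fit,
                 residual_df = fit$df.residual,
                 food_coding = food_coding, ss_type = ss_type),
            class = "signal_glm")
}

#' @export
print.signal_glm <- function(x, digits = 3, ...) {
  cat("General linear model of Kendall's W on the design factors\n")
  cat("  food coding: ", x$food_coding, "; eta^2 from ", x$ss_type,
      " SS; residual df ", x$residual_df, "\n\n", sep = "")
  tab <- x$table
  tab$p_value <- format.pval(tab$p_value, digits = digits)
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.signal_glm <- function(object, ...) stats::coef(object$model)

#' Write a fitted model as CSV
#'
#' One row per term with coefficient, standard error, t-value, partial
#' eta-squared and p-value.
#'
#' @param fit A `signal_glm`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_glm <- function(fit, path) {
  stopifnot(inherits(fit, "signal_glm"))
  utils::write.csv(fit$table, path, row.names = FALSE)
  invisible(path)
}

#' Condition means of Kendall's W for the figure summaries
#'
#' Mean W (+/- one standard error of the mean) by food level, split in
#' turn by each design factor: items needed, sequential assessment,
#' real-time observation, and -- within item-needed runs -- display-item
#' abundance.
#'
#' @param table A `sweep_table`.
#' @return A data.frame with columns `factor`, `level`, `food_level`,
#'   `mean_W`, `sem`, `n`; one block of rows per split factor.
#' @export
condition_summaries <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0)
  one <- function(fac) {
    g <- group_mean_sem(table$W,
                        data.frame(level = table[[fac]],
                                   food_level = table$food_level))
    data.frame(factor = fac, g)
  }
  out <- rbind(one("items_needed"), one("sequential"), one("realtime"))
  it <- table[table$items_needed == 1, , drop = FALSE]
  if (nrow(it) > 0) {
    g <- group_mean_sem(it$W, data.frame(level = it$display_level,
                                         food_level = it$food_level))
    out <- rbind(out, data.frame(factor = "display_level", g))
  }
  names(out)[names(out) == "mean"] <- "mean_W"
  out
}

#' Plot mean concordance against food abundance
#'
#' Base-graphics rendering of one block of [condition_summaries()]: one
#' line per level of the chosen factor, points at condition means with
#' +/- 1 s.e.m. bars, food level on a log axis.
#'
#' @param summaries Output of [condition_summaries()].
#' @param factor Which split to draw.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the subset drawn.
#' @export
plot_w_by_food <- function(summaries, factor = "items_needed", ...) {
  s <- summaries[summaries$factor == factor, , drop = FALSE]
  if (nrow(s) == 0L) stop("no rows for factor '", factor, "'", call. = FALSE)
  lev <- sort(unique(s$level))
  graphics::plot(range(s$food_level), range(c(s$mean_W - s$sem, s$mean_W + s$sem)),
                 type = "n", log = "x", xlab = "food items",
                 ylab = "Kendall's W", ...)
  for (i in seq_along(lev)) {
    si <- s[s$level == lev[i], , drop = FALSE]
    si <- si[order(si$food_level), , drop = FALSE]
    graphics::lines(si$food_level, si$mean_W, lty = i)
    graphics::points(si$food_level, si$mean_W, pch = c(1, 15, 17)[i])
    graphics::arrows(si$food_level, si$mean_W - si$sem,
                     si$food_level, si$mean_W + si$sem,
                     angle = 90, code = 3, length = 0.03)
  }
  graphics::legend("bottomright", legend = paste(factor, "=", lev),
                   lty = seq_along(lev), pch = c(1, 15, 17)[seq_along(lev)],
                   bty = "n")
  invisible(s)
}
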