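## Interaction-deducted effect-size decomposition: centered partial
## dependence, Friedman's H, sum-of-squares effects in per-mil and
## percent-of-total form, and the cumulative climate vs demography
## comparison.

model_predict <- function(model, newdata) {
  if (is.function(model)) as.numeric(model(newdata))
  else as.numeric(stats::predict(model, newdata))
}

#' Centered partial-dependence profile
#'
#' For data rows i and grid values v_k of variable j, predictions
#' yhat_{i,k} are made with row i's variable j replaced by v_k. The partial
#' dependence PD_j(v_k) is the mean over rows, centered across the grid; the
#' complement PD_{-j}(i) is the mean over grid values, centered across rows.
#'
#' @param model A [fit_forest] model, or any object with a `predict` method,
#'   or a prediction function of a data frame.
#' @param data Data frame of covariate rows.
#' @param variable Variable name (must be a model predictor).
#' @param grid Numeric grid of values for `variable`.
#' @return List (`pd_profile`): `variable`, `grid`, `pd` (centered, length
#'   m), `pd_complement` (centered, length n), `predictions` (n x m matrix).
#' @export
pd_profile <- function(model, data, variable, grid) {
  if (!length(grid)) stop("grid must be non-empty")
  if (!nrow(data)) stop("data must be non-empty")
  if (!variable %in% names(data))
    stop(sprintf("variable '%s' not in model data", variable))
  n <- nrow(data)
  m <- length(grid)
  nd <- data[rep(seq_len(n), times = m), , drop = FALSE]
  nd[[variable]] <- rep(grid, each = n)
  f <- matrix(model_predict(model, nd), nrow = n, ncol = m)
  pd <- colMeans(f)
  pdc <- rowMeans(f)
  structure(list(variable = variable, grid = grid,
                 pd = pd - mean(pd), pd_complement = pdc - mean(pdc),
                 predictions = f),
            class = "pd_profile")
}

#' Friedman's H interaction statistic
#'
#' The proportion of a variable's predictive effect attributable to its
#' interactions with the remaining variables: with f the grid-centered
#' prediction matrix, h = sum((f - pd_j - pd_{-j})^2) / sum(f^2), clipped to
#' [0, 1]. h = 0 for an additive (interaction-free) prediction surface and
#' approaches 1 when the effect is carried entirely by interactions.
#'
#' @param profile A [pd_profile].
#' @return Proportion in [0, 1].
#' @export
friedman_h <- function(profile) {
  f <- profile$predictions - mean(profile$predictions)
  den <- sum(f^2)
  if (den <= .Machine$double.eps * length(f)) {
    warning("predictions have (near) zero variance: H reported as 0")
    return(0)
  }
  resid <- sweep(sweep(f, 2L, profile$pd, "-"), 1L,
                 profile$pd_complement, "-")
  min(max(sum(resid^2) / den, 0), 1)
}

## Summary statistics of one iteration's profile.
effect_stats <- function(profile) {
  h <- suppressWarnings(friedman_h(profile))
  ss_raw <- sum(profile$pd^2)
  f <- profile$predictions - mean(profile$predictions)
  list(h = h, ss_raw = ss_raw, ss_deducted = ss_raw * (1 - h),
       ss_total = sum(f^2) / nrow(profile$predictions))
}

#' Interaction-deducted effect size of one variable
#'
#' Monte-Carlo estimate of a variable's independent effect: per iteration, m
#' values of the variable are resampled with replacement from its observed
#' values in the zone, the centered partial-dependence profile and
#' prediction matrix are built on that grid, and the explained sum of
#' squares ss_raw = sum_k pd_j(v_k)^2, Friedman's H, the deducted sum of
#' squares ss_raw * (1 - h), and the total sum of squares
#' (1/n) * sum_{i,k} f_{i,k}^2 are recorded. Quantities are averaged over
#' iterations; the per-mil effect is sqrt(mean deducted SS) and the percent
#' of total variability is 100 * sqrt(mean deducted SS) / sqrt(mean total
#' SS). With `deduction = "h2"` the deduction uses (1 - h^2) instead.
#'
#' @param model A [fit_forest] model (or prediction function).
#' @param data Covariate rows for the zone being decomposed.
#' @param variable Variable name.
#' @param n_iter Number of iterations (study default 100).
#' @param m Sampled grid values per iteration (study default 100).
#' @param seed Integer seed.
#' @param deduction `"h"` (default) or `"h2"`.
#' @param max_rows Optional cap on the number of data rows entering each
#'   iteration's partial-dependence averages (a seeded subsample, the usual
#'   cost control for partial-dependence estimation); `NULL` uses all rows.
#' @return One-row data frame: `variable`, `h`, `ss_raw`, `ss_deducted`,
#'   `ss_total`, `effect_permil`, `percent_of_total`, `n_iterations`.
#' @export
effect_size <- function(model, data, variable, n_iter = 100, m = 100,
                        seed = 1, deduction = c("h", "h2"),
                        max_rows = NULL) {
  deduction <- match.arg(deduction)
  if (m < 2) stop("m must be at least 2")
  if (nrow(data) < m / 2)
    stop("zone has too few rows for the requested grid size")
  obs <- data[[variable]]
  set.seed(seed)
  if (!is.null(max_rows) && nrow(data) > max_rows)
    data <- data[sample.int(nrow(data), max_rows), , drop = FALSE]
  grids <- matrix(sample(obs, n_iter * m, replace = TRUE), n_iter, m)
  n <- nrow(data)
  ## chunk iterations so the replicated prediction frame stays bounded
  chunk <- max(1L, floor(2e6 / (n * m)))
  stats_list <- vector("list", n_iter)
  it <- 1L
  while (it <= n_iter) {
    span <- it:min(it + chunk - 1L, n_iter)
    grid_all <- as.numeric(t(grids[span, , drop = FALSE]))
    nd <- data[rep(seq_len(n), times = length(grid_all)), , drop = FALSE]
    nd[[variable]] <- rep(grid_all, each = n)
    preds <- matrix(model_predict(model, nd), nrow = n)
    for (ci in seq_along(span)) {
      f <- preds[, (ci - 1L) * m + seq_len(m), drop = FALSE]
      g <- grids[span[ci], ]
      pd <- colMeans(f)
      pdc <- rowMeans(f)
      prof <- structure(list(variable = variable, grid = g,
                             pd = pd - mean(pd),
                             pd_complement = pdc - mean(pdc),
                             predictions = f),
                        class = "pd_profile")
      st <- effect_stats(prof)
      if (deduction == "h2")
        st$ss_deducted <- st$ss_raw * (1 - st$h^2)
      stats_list[[span[ci]]] <- st
    }
    it <- span[length(span)] + 1L
  }
  h <- mean(vapply(stats_list, `[[`, numeric(1), "h"))
  ss_raw <- mean(vapply(stats_list, `[[`, numeric(1), "ss_raw"))
  ss_ded <- mean(vapply(stats_list, `[[`, numeric(1), "ss_deducted"))
  ss_tot <- mean(vapply(stats_list, `[[`, numeric(1), "ss_total"))
  data.frame(variable = variable, h = h, ss_raw = ss_raw,
             ss_deducted = ss_ded, ss_total = ss_tot,
             effect_permil = sqrt(ss_ded),
             percent_of_total = 100 * sqrt(ss_ded) / sqrt(ss_tot),
             n_iterations = n_iter, stringsAsFactors = FALSE)
}

#' Decompose all covariate effects per zone
#'
#' Runs [effect_size] for every model predictor within every elevation zone
#' present in `data`.
#'
#' @param model A [fit_forest] model.
#' @param data Covariate rows including a `zone` column.
#' @param variables Predictors to decompose (default: the model's).
#' @param n_iter,m,seed,deduction,max_rows Passed to [effect_size] (seeds
#'   derived per zone x variable).
#' @return Data frame with one row per zone x variable.
#' @export
decompose_effects <- function(model, data, variables = NULL, n_iter = 100,
                              m = 100, seed = 1, deduction = "h",
                              max_rows = NULL) {
  if (is.null(variables)) variables <- model$predictors
  zones_here <- intersect(ZONES, unique(data$zone))
  out <- list()
  for (z in zones_here) {
    zdata <- data[data$zone == z, , drop = FALSE]
    for (v in variables) {
      row <- effect_size(model, zdata, v, n_iter = n_iter, m = m,
                         seed = stage_seed(seed, paste0(z, "_", v)),
                         deduction = deduction, max_rows = max_rows)
      row <- cbind(zone = z, row, stringsAsFactors = FALSE)
      out[[paste(z, v)]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cumulative climate vs demography comparison
#'
#' Sums the four climate variables' per-mil effects and percentages per zone
#' and pairs them against the population effect, the summary used to judge
#' whether climate or demography dominates dietary variation.
#'
#' @param effects Data frame from [decompose_effects] (optionally carrying
#'   `isotope` and `kde_variant` columns, preserved in the output).
#' @return Data frame with per-zone cumulative climate and demography
#'   effects (per mil and percent) and their ratio.
#' @export
cumulative_comparison <- function(effects) {
  extra <- intersect(c("isotope", "kde_variant"), names(effects))
  key_cols <- c("zone", extra)
  keys <- unique(effects[, key_cols, drop = FALSE])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- rep(TRUE, nrow(effects))
    for (kc in key_cols) sel <- sel & effects[[kc]] == keys[[kc]][i]
    e <- effects[sel, , drop = FALSE]
    if (!all(c(CLIMATE_VARS, "population") %in% e$variable))
      stop("all five variables must be decomposed per zone")
    clim <- e[e$variable %in% CLIMATE_VARS, , drop = FALSE]
    pop <- e[e$variable == "population", , drop = FALSE]
    cbind(keys[i, , drop = FALSE],
          data.frame(climate_permil = sum(clim$effect_permil),
                     climate_percent = sum(clim$percent_of_total),
                     demography_permil = pop$effect_permil,
                     demography_percent = pop$percent_of_total,
                     ratio = sum(clim$effect_permil) /
                       max(pop$effect_permil, .Machine$double.eps)))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
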