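## Force-pCa contractility analysis.
##
## Steady-state forces of permeabilized single myofibres, measured across
## activating solutions of decreasing pCa (= -log10 molar free Ca2+), are
## normalized to the maximal force at pCa 4.5 and fitted to the Hill
## equation in pCa space,
##
##     F(pCa) = 1 / (1 + 10^(nH * (pCa - pCa50))),
##
## with unit plateau (no offset), giving the half-activation point pCa50 and
## the cooperativity index nH. pCa10/pCa20 and calcium concentrations at any
## activation fraction follow in closed form.

#' Hill force-pCa relation
#'
#' @param pca pCa values.
#' @param pca50 Half-activation pCa.
#' @param nh Hill coefficient (> 0).
#' @return Normalized force in `[0, 1]`.
#' @export
hill_force <- function(pca, pca50, nh) {
  1 / (1 + 10^(nh * (pca - pca50)))
}

#' Elliptical fibre cross-sectional area
#'
#' Width and depth are measured at points along the fibre; each point
#' contributes an elliptical area `pi * (width/2) * (depth/2)` and the CSA
#' is their mean.
#'
#' @param widths,depths Positive values (um), same length (typically 3).
#' @return CSA in um^2.
#' @export
elliptical_csa <- function(widths, depths) {
  assert_that(length(widths) == length(depths) && length(widths) >= 1L,
              "widths and depths must have equal, positive length")
  assert_that(all(widths > 0) && all(depths > 0),
              "fibre dimensions must be positive")
  mean(pi * (widths / 2) * (depths / 2))
}

#' Normalize a force-pCa curve to the maximal force at pCa 4.5
#'
#' Every force is divided by the force measured at pCa 4.5 (the saturating
#' solution); the relaxing-solution point (pCa 9.0) is retained as data, not
#' subtracted as a baseline.
#'
#' @param curve Data frame with columns `pCa` and `force`.
#' @return The curve with `force` rescaled so force(pCa 4.5) is 1.
#' @export
normalize_curve <- function(curve) {
  stopifnot(all(c("pCa", "force") %in% names(curve)))
  ref <- curve$force[curve$pCa == 4.5]
  assert_that(length(ref) >= 1L,
              "no measurement at pCa 4.5; cannot normalize")
  curve$force <- curve$force / mean(ref)
  curve
}

#' Fit the Hill equation to a normalized force-pCa curve
#'
#' Bounded Levenberg-Marquardt least squares
#' ([minpack.lm::nlsLM()]) of `F = 1 / (1 + 10^(nH (pCa - pCa50)))`.
#' Initialization: pCa50 starts at the measured pCa whose force is nearest
#' 0.5, nH at 2; bounds pCa50 in [4.5, 7.5], nH in [0.1, 10].
#'
#' @param curve Data frame with `pCa` and normalized `force`; at least 4
#'   distinct pCa values spanning the transition.
#' @return Object of class `hill_fit` with components `pca50`, `nh`,
#'   `residual` (sum of squared residuals), `pca10`, `pca20`, per-fraction
#'   calcium concentrations, and the underlying `nls` fit.
#' @export
fit_hill <- function(curve) {
  stopifnot(all(c("pCa", "force") %in% names(curve)))
  assert_that(length(unique(curve$pCa)) >= 4L,
              "need at least 4 distinct pCa points to fit")
  start <- list(pca50 = curve$pCa[which.min(abs(curve$force - 0.5))],
                nh = 2)
  lower <- c(pca50 = 4.5, nh = 0.1)
  upper <- c(pca50 = 7.5, nh = 10)
  fit <- tryCatch(
    minpack.lm::nlsLM(force ~ 1 / (1 + 10^(nh * (pCa - pca50))),
                      data = curve, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("Hill fit did not converge (start pCa50=", start$pca50,
           ", nH=", start$nh, "; bounds pCa50 [4.5, 7.5], nH [0.1, 10]): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  est <- coef(fit)
  obj <- structure(list(
    pca50 = unname(est["pca50"]),
    nh = unname(est["nh"]),
    residual = sum(residuals(fit)^2),
    fit = fit,
    data = curve
  ), class = "hill_fit")
  d10 <- pca_at_fraction(obj, 0.1)
  d20 <- pca_at_fraction(obj, 0.2)
  d50 <- pca_at_fraction(obj, 0.5)
  obj$pca10 <- d10$pCa
  obj$pca20 <- d20$pCa
  obj$ca50_mM <- d50$calcium_mM
  obj$ca20_mM <- d20$calcium_mM
  obj$ca10_mM <- d10$calcium_mM
  obj
}

#' @export
print.hill_fit <- function(x, digits = 4, ...) {
  cat("Hill force-pCa fit\n")
  cat("  pCa50 = ", round(x$pca50, digits), ", nH = ", round(x$nh, digits),
      " (RSS = ", signif(x$residual, 3), ")\n", sep = "")
  cat("  pCa20 = ", round(x$pca20, digits), ", pCa10 = ",
      round(x$pca10, digits), "\n", sep = "")
  cat("  [Ca2+] at 50% max force = ", signif(x$ca50_mM, 4), " mM\n",
      sep = "")
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(pCa50 = object$pca50, nH = object$nh)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  pca <- if (is.null(newdata)) object$data$pCa else newdata$pCa
  hill_force(pca, object$pca50, object$nh)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$data$force - predict(object)
}

#' @export
summary.hill_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  grid <- seq(max(x$data$pCa), min(x$data$pCa), length.out = 200)
  plot(x$data$pCa, x$data$force, xlim = rev(range(x$data$pCa)),
       xlab = "pCa", ylab = "normalized force", ...)
  graphics::lines(grid, hill_force(grid, x$pca50, x$nh))
  invisible(x)
}

#' pCa and calcium concentration at a given activation fraction
#'
#' Closed form from the Hill fit:
#' `pCa_x = pCa50 + log10((1 - x) / x) / nH`, and the molar concentration
#' back-transformed to mM. Fractions below one half give larger pCa values
#' (less calcium), so pCa10 >= pCa20 >= pCa50.
#'
#' @param fit A `hill_fit`, or any list with `pca50` and `nh`.
#' @param fraction Activation fraction(s), strictly between 0 and 1.
#' @return Data frame: `fraction`, `pCa`, `calcium_mM`.
#' @export
pca_at_fraction <- function(fit, fraction) {
  assert_that(all(fraction > 0 & fraction < 1),
              "fraction must lie strictly between 0 and 1")
  pca <- fit$pca50 + log10((1 - fraction) / fraction) / fit$nh
  data.frame(fraction = fraction, pCa = pca,
             calcium_mM = 10^(-pca) * 1000)
}

#' Fit Hill curves per fibre (or pooled per group)
#'
#' @param data Long table with `fibre_id`, `group`, `pCa`, `force`
#'   (normalized).
#' @param pooled Fit one curve per group over all of its fibres' points
#'   instead of per fibre.
#' @return Data frame of per-fibre (or per-group) estimates: `pca50`, `nh`,
#'   `pca20`, `pca10`, `ca50_mM`, `ca20_mM`, `ca10_mM`, `residual`.
#' @export
fit_hill_groups <- function(data, pooled = FALSE) {
  stopifnot(all(c("fibre_id", "group", "pCa", "force") %in% names(data)))
  key <- if (pooled) data$group else data$fibre_id
  pieces <- lapply(split(data, key), function(d) {
    f <- fit_hill(d)
    data.frame(fibre_id = if (pooled) NA_character_ else d$fibre_id[1L],
               group = d$group[1L],
               pca50 = f$pca50, nh = f$nh,
               pca20 = f$pca20, pca10 = f$pca10,
               ca50_mM = f$ca50_mM, ca20_mM = f$ca20_mM,
               ca10_mM = f$ca10_mM, residual = f$residual,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Compare per-fibre metrics between two groups
#'
#' Two-tailed unpaired t-test per metric (equal-variance by default,
#' Welch optionally), with group means and SDs.
#'
#' @param stats Per-fibre table with a `group` column (two groups) and the
#'   metric columns.
#' @param metrics Column names to compare.
#' @param welch Use the Welch (unequal-variance) t-test.
#' @return Data frame: one row per metric with group means, SDs, `t`, `df`
#'   and two-tailed `p`.
#' @export
compare_groups <- function(stats,
                           metrics = c("pca50", "nh", "pca20", "pca10",
                                       "ca50_mM", "ca20_mM", "ca10_mM"),
                           welch = FALSE) {
  groups <- unique(stats$group)
  assert_that(length(groups) == 2L,
              paste0("exactly two groups required (got ",
                     length(groups), ")"))
  for (g in groups) {
    assert_that(sum(stats$group == g) >= 2L,
                paste0("group '", g, "' has fewer than 2 observations"))
  }
  rows <- lapply(metrics, function(m) {
    x <- stats[[m]][stats$group == groups[1L]]
    y <- stats[[m]][stats$group == groups[2L]]
    tt <- t.test(x, y, var.equal = !welch)
    data.frame(metric = m,
               group_1 = groups[1L], mean_1 = mean(x), sd_1 = sd(x),
               group_2 = groups[2L], mean_2 = mean(y), sd_2 = sd(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## --- simulation -----------------------------------------------------------

#' Configuration for simulated force-pCa experiments
#'
#' Defaults are the study's generative conditions: 10 fibres per group on a
#' 10-point pCa grid from 9.0 (relaxing) to 4.5 (saturating), wild-type
#' pCa50 5.804, affected pCa50 6.056, nH 2.0, Gaussian noise with SD 0.02
#' of maximal force.
#'
#' @param n_fibres_per_group Fibres per group.
#' @param pca_grid Measurement pCa values; must cover 4.5 and 9.0.
#' @param pca50_true Named numeric: generative pCa50 per group.
#' @param nh_true Generative Hill coefficient.
#' @param noise_sd Gaussian noise SD (fraction of maximal force).
#' @param seed Integer seed.
#' @return A list of class `fibre_sim_config`.
#' @export
fibre_sim_config <- function(n_fibres_per_group = 10L,
                             pca_grid = c(9.0, 6.4, 6.2, 6.0, 5.8, 5.6,
                                          5.4, 5.2, 5.0, 4.5),
                             pca50_true = c(wild_type = 5.804,
                                            affected = 6.056),
                             nh_true = 2.0,
                             noise_sd = 0.02,
                             seed = 1L) {
  cfg <- list(n_fibres_per_group = as.integer(n_fibres_per_group),
              pca_grid = pca_grid,
              pca50_true = pca50_true,
              nh_true = nh_true,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  assert_that(min(pca_grid) <= 4.5 && max(pca_grid) >= 9.0,
              "pca_grid must span at least [4.5, 9.0]")
  assert_that(any(pca_grid == 4.5),
              "pca_grid must include the pCa 4.5 normalization point")
  assert_that(cfg$noise_sd >= 0, "noise_sd must be non-negative")
  assert_that(cfg$nh_true > 0, "nh_true must be positive")
  class(cfg) <- "fibre_sim_config"
  cfg
}

#' Simulate force-pCa curves from the Hill model
#'
#' Per fibre, the normalized force at each grid pCa is the Hill relation at
#' the group's generative parameters plus Gaussian noise (SD `noise_sd`),
#' truncated at zero; the curve is then re-normalized so the pCa 4.5 force
#' is exactly 1.
#'
#' @param config A [fibre_sim_config()].
#' @return Long data frame: `fibre_id`, `group`, `pCa`, `force`; attribute
#'   `truth` records the generative parameters.
#' @export
simulate_force_pca <- function(config = fibre_sim_config()) {
  with_seed(config$seed, {
    rows <- list()
    for (g in names(config$pca50_true)) {
      for (i in seq_len(config$n_fibres_per_group)) {
        f <- hill_force(config$pca_grid, config$pca50_true[[g]],
                        config$nh_true)
        f <- pmax(f + rnorm(length(f), 0, config$noise_sd), 0)
        f <- f / f[config$pca_grid == 4.5][1L]
        rows[[length(rows) + 1L]] <- data.frame(
          fibre_id = sprintf("%s_f%02d", g, i),
          group = g,
          pCa = config$pca_grid,
          force = f,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- config[c("pca50_true", "nh_true", "noise_sd")]
    out
  })
}
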