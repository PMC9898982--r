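# Perturbation stage: per-CpG pyrosequencing deltas with two-way ANOVA,
# delta-delta-Ct qPCR fold changes, and 4-parameter log-logistic IC50 fits
# of viability dose-response curves.

#' Per-CpG pyrosequencing deltas
#'
#' Means per condition and the treated-minus-control delta per CpG site.
#'
#' @param table Long pyro assay tibble (`condition`, `replicate`, `key`,
#'   `value` with value = percent methylation).
#' @param control,treated Condition labels.
#' @return Tibble `cpg` (key), `mean_control`, `mean_treated`, `delta`,
#'   `n_control`, `n_treated`.
#' @export
pyro_deltas <- function(table, control, treated) {
  tab <- dplyr::filter(table, .data$condition %in% c(control, treated))
  present <- tab |>
    dplyr::distinct(.data$key, .data$condition) |>
    dplyr::count(.data$key)
  missing <- present$key[present$n < 2]
  missing <- union(missing, setdiff(unique(table$key), present$key))
  if (length(missing) > 0) {
    rlang::abort(sprintf("CpG site(s) missing in one condition: %s",
                         paste(sort(missing), collapse = ", ")))
  }
  tab |>
    dplyr::group_by(.data$key, .data$condition) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = c("mean", "n")) |>
    dplyr::rename(
      cpg = "key",
      mean_control = paste0("mean_", control),
      mean_treated = paste0("mean_", treated),
      n_control = paste0("n_", control),
      n_treated = paste0("n_", treated)
    ) |>
    dplyr::mutate(delta = .data$mean_treated - .data$mean_control) |>
    dplyr::select("cpg", "mean_control", "mean_treated", "delta",
                  "n_control", "n_treated")
}

#' Two-way ANOVA on per-CpG methylation
#'
#' Fits `value ~ condition * cpg` over the replicate observations (factors:
#' condition, CpG site, and their interaction) and tests, per CpG, the
#' condition contrast within that CpG against the pooled residual error.
#' With zero residual variance the contrast p-value degenerates to 0 for a
#' nonzero delta (and 1 otherwise).
#'
#' @param table Long pyro assay tibble restricted to two conditions.
#' @param control,treated Condition labels.
#' @param alpha Significance level (default 0.001).
#' @return [pyro_deltas()] columns plus `p_value` and `significant`.
#' @export
pyro_anova <- function(table, control, treated, alpha = 0.001) {
  deltas <- pyro_deltas(table, control, treated)
  tab <- dplyr::filter(table, .data$condition %in% c(control, treated))
  cell_n <- dplyr::count(tab, .data$condition, .data$key)
  if (any(cell_n$n < 2)) {
    rlang::abort("two-way ANOVA needs >= 2 replicates per condition x CpG cell")
  }
  fit <- stats::lm(value ~ condition * cpg,
                   data = dplyr::mutate(tab, condition = factor(.data$condition),
                                        cpg = factor(.data$key)))
  mse <- sum(resid(fit)^2) / fit$df.residual
  out <- deltas |>
    dplyr::mutate(
      se = sqrt(mse * (1 / .data$n_control + 1 / .data$n_treated)),
      p_value = dplyr::case_when(
        .data$se > 0 ~ 2 * stats::pt(-abs(.data$delta / .data$se), fit$df.residual),
        .data$delta != 0 ~ 0,
        TRUE ~ 1
      ),
      significant = .data$p_value < alpha
    ) |>
    dplyr::select(-"se")
  out
}

#' Delta-delta-Ct qPCR fold change
#'
#' dCt = mean Ct(target) - mean Ct(reference) per condition;
#' ddCt = dCt(treated) - dCt(control); fold = 2^-ddCt. The p-value is a
#' two-tailed Mann-Whitney test on the replicate dCt values (replicates
#' paired by index within condition).
#'
#' @param table Long qPCR tibble (`condition`, `replicate`, `key` = gene,
#'   `value` = Ct cycles).
#' @param target Target gene (e.g. `"ITGB7"`).
#' @param reference Reference gene (default `"GAPDH"`).
#' @param control,treated Condition labels.
#' @return One-row tibble `target`, `reference`, `control`, `treated`,
#'   `ddct`, `fold`, `p_value`.
#' @export
ddct_fold_change <- function(table, target, reference = "GAPDH",
                             control, treated) {
  need <- tidyr::expand_grid(condition = c(control, treated),
                             key = c(target, reference))
  have <- dplyr::distinct(table, .data$condition, .data$key)
  miss <- dplyr::anti_join(need, have, by = c("condition", "key"))
  if (nrow(miss) > 0) {
    rlang::abort(sprintf(
      "missing qPCR measurements: %s",
      paste(sprintf("%s/%s", miss$condition, miss$key), collapse = ", ")
    ))
  }
  dct <- table |>
    dplyr::filter(.data$condition %in% c(control, treated),
                  .data$key %in% c(target, reference)) |>
    tidyr::pivot_wider(names_from = "key", values_from = "value") |>
    dplyr::mutate(dct = .data[[target]] - .data[[reference]])
  if (any(is.na(dct$dct))) rlang::abort("unpaired target/reference replicates")
  dct_c <- dct$dct[dct$condition == control]
  dct_t <- dct$dct[dct$condition == treated]
  if (length(dct_c) < 3 || length(dct_t) < 3) {
    rlang::abort("ddCt fold change needs >= 3 replicates per condition")
  }
  ddct <- mean(dct_t) - mean(dct_c)
  tibble::tibble(
    target = target, reference = reference,
    control = control, treated = treated,
    ddct = ddct, fold = 2^(-ddct),
    p_value = mann_whitney_p(dct_t, dct_c)
  )
}

#' Fit a 4-parameter log-logistic dose-response curve
#'
#' Least-squares fit of `v(c) = bottom + (top - bottom) / (1 +
#' (c / ic50)^hill)` to viability versus concentration, initialised from
#' the data (top = max mean, bottom = min mean, ic50 = concentration whose
#' mean response is nearest the half range, hill = 1) with ic50 bounded
#' positive. Luminescence viability error is proportional to signal
#' (constant CV), so residuals are minimised on the log scale, which is the
#' correctly weighted least-squares fit under that error model; when
#' non-positive viability values are present the fit falls back to the
#' linear scale. The fit is refused when the mean response increases with
#' dose or is flat.
#'
#' @param table Long viability tibble (`condition`, `replicate`, `key` =
#'   concentration in uM, `value` = viability fraction), or any tibble with
#'   numeric `key`/`value` after filtering to one time point.
#' @param condition Optional condition label (e.g. `"JQ1_48h"`) to filter
#'   on; `NULL` uses all rows.
#' @return Object of class `ren_ic50_fit`: list with `ic50`, `hill`, `top`,
#'   `bottom`, `rss`, `n`, `extrapolated`, `data`, and the underlying `nls`
#'   fit. Use [tidy()]/[glance()]/[autoplot()] on it.
#' @export
fit_ic50 <- function(table, condition = NULL) {
  tab <- if (!is.null(condition)) {
    dplyr::filter(table, .data$condition == !!condition)
  } else {
    table
  }
  dat <- tibble::tibble(conc = as.numeric(tab$key), viability = tab$value)
  if (any(is.na(dat$conc))) rlang::abort("non-numeric concentration key")
  if (length(unique(dat$conc)) < 5) {
    rlang::abort("IC50 fit needs >= 5 distinct concentrations")
  }
  means <- dat |>
    dplyr::group_by(.data$conc) |>
    dplyr::summarise(mean = mean(.data$viability), .groups = "drop") |>
    dplyr::arrange(.data$conc)
  trend <- stats::coef(stats::lm(mean ~ log(conc), data = means))[2]
  if (diff(range(means$mean)) < 1e-8 || trend >= 0) {
    rlang::abort("non-monotone or flat mean response: dose-response fit refused")
  }

  top0 <- max(means$mean)
  bottom0 <- min(means$mean)
  half <- (top0 + bottom0) / 2
  ic50_0 <- means$conc[which.min(abs(means$mean - half))]
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  fit <- if (all(dat$viability > 0)) {
    minpack.lm::nlsLM(
      log(viability) ~ log(bottom + (top - bottom) / (1 + (conc / ic50)^hill)),
      data = dat,
      start = list(top = top0, bottom = max(bottom0, 1e-4), ic50 = ic50_0,
                   hill = 1),
      lower = c(top = 1e-6, bottom = 1e-6, ic50 = 1e-9, hill = 1e-3),
      control = ctrl
    )
  } else {
    minpack.lm::nlsLM(
      viability ~ bottom + (top - bottom) / (1 + (conc / ic50)^hill),
      data = dat,
      start = list(top = top0, bottom = bottom0, ic50 = ic50_0, hill = 1),
      lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-9, hill = 1e-3),
      control = ctrl
    )
  }
  est <- as.list(coef(fit))
  structure(
    list(
      ic50 = est$ic50, hill = est$hill, top = est$top, bottom = est$bottom,
      rss = sum(resid(fit)^2), n = nrow(dat),
      extrapolated = est$ic50 < min(dat$conc) || est$ic50 > max(dat$conc),
      condition = condition, data = dat, fit = fit
    ),
    class = "ren_ic50_fit"
  )
}

#' @export
print.ren_ic50_fit <- function(x, ...) {
  cat(sprintf(
    "4PL dose-response fit%s: IC50 = %.4g uM (hill %.3g, top %.3g, bottom %.3g)%s\n",
    if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
    x$ic50, x$hill, x$top, x$bottom,
    if (x$extrapolated) " [extrapolated]" else ""
  ))
  invisible(x)
}

#' @rdname fit_ic50
#' @param x A `ren_ic50_fit` object.
#' @param ... Unused.
#' @export
tidy.ren_ic50_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"]
  )
}

#' @rdname fit_ic50
#' @export
glance.ren_ic50_fit <- function(x, ...) {
  tibble::tibble(
    ic50 = x$ic50, hill = x$hill, top = x$top, bottom = x$bottom,
    rss = x$rss, n = x$n, extrapolated = x$extrapolated
  )
}
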