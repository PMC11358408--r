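#' Ordinary least-squares line fit
#'
#' Fits `y = a + b * x` by unweighted OLS and reports the coefficient of
#' determination `r2 = 1 - SSres/SStot`. When the response is constant
#' (`SStot = 0`, hence also `SSres = 0` for the OLS fit) `r2` is defined
#' as 1: the line reproduces the data exactly.
#'
#' @param x,y Numeric vectors of equal length, at least 2 distinct `x`.
#' @return A list with elements `a` (intercept), `b` (slope), `r2`, `n`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("need at least 2 complete points", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("degenerate fit: all x values identical", call. = FALSE)
  cf <- stats::.lm.fit(cbind(1, x), y)
  a <- cf$coefficients[1L]; b <- cf$coefficients[2L]
  ss_res <- sum(cf$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(a = a, b = b, r2 = r2, n = n)
}

#' Mean absolute deviation from a line fit
#'
#' The scatter statistic of the reliability framework:
#' `(1/n) * sum |y_i - (a + b * x_i)|`, the mean absolute residual of the
#' observed values around the fitted line.
#'
#' @param x,y The points the fit was computed from.
#' @param fit A fit as returned by [fit_linear()] (elements `a`, `b`).
#' @return The mean absolute residual, >= 0.
#' @export
mean_abs_deviation <- function(x, y, fit) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  mean(abs(y[keep] - (fit$a + fit$b * x[keep])))
}

#' Restrict a parameter series to an RWC window
#'
#' Keeps the points whose RWC lies in the closed interval `[lo, hi]`,
#' preserving order. The default 50-100% window reflects the fact that
#' RWC below ~50% usually means lethal leaf damage, so method comparison
#' is most meaningful during milder desiccation.
#'
#' @param rwc RWC values, percent.
#' @param value Parameter values, same length.
#' @param lo,hi Window bounds, percent (inclusive).
#' @return A list with windowed `rwc` and `value` vectors.
#' @export
select_window <- function(rwc, value, lo = 50, hi = 100) {
  stopifnot(is.numeric(rwc), is.numeric(value), length(rwc) == length(value),
            lo < hi)
  keep <- !is.na(rwc) & rwc >= lo & rwc <= hi
  list(rwc = rwc[keep], value = value[keep])
}

#' Reliability, sensitivity and inaccuracy coefficients of one parameter
#'
#' The core statistic of the package. A monitored parameter, observed as
#' `(RWC, value)` points across leaf samples, is fitted linearly against
#' RWC over the evaluation window (default 100-50%). With slope `b`, mean
#' value `ybar` and mean absolute residual `dy_bar`, the coefficients
#' are:
#' * coefficient of reliability `CR = |b| * delta_s / dy_bar` — the
#'   change the parameter shows over a `delta_s` step of RWC, in units of
#'   its own scatter;
#' * coefficient of sensitivity `CS = 100 * |b| / |ybar|` — relative
#'   slope per percent RWC;
#' * coefficient of inaccuracy `CI = 100 * dy_bar / |ybar|` — relative
#'   scatter.
#'
#' The identity `CR = delta_s * CS / CI` holds algebraically for every
#' finite result. Absolute values are used so parameters that rise and
#' parameters that fall with RWC rank on the same magnitude scale. A
#' perfect fit (`dy_bar = 0`) gives `CR = Inf` and sets `perfect_fit`;
#' `ybar = 0` leaves CS and CI undefined (`NaN`, flagged).
#'
#' @param rwc RWC values, percent.
#' @param value Parameter values.
#' @param delta_s RWC step over which a detectable change is required,
#'   percentage points (default 10, i.e. a 0.1 step on the fractional
#'   scale).
#' @param window Evaluation window `c(lo, hi)` in percent RWC,
#'   inclusive on both ends.
#' @param threshold Reliability threshold on CR (default 0.4).
#' @param parameter,group,species Metadata carried into the result.
#' @return An object of class `reliability_result`: a list with
#'   `parameter`, `group`, `species`, `n`, `a`, `b`, `y_bar`, `dy_bar`,
#'   `r2`, `CR`, `CS`, `CI`, `reliable`, `perfect_fit`,
#'   `mean_undefined`, `window`, `delta_s`.
#' @export
compute_coefficients <- function(rwc, value, delta_s = 10,
                                 window = c(50, 100), threshold = 0.4,
                                 parameter = NA_character_,
                                 group = NA_character_,
                                 species = NA_character_) {
  stopifnot(is.numeric(delta_s), delta_s > 0, length(window) == 2L,
            threshold >= 0)
  w <- select_window(rwc, value, lo = window[1L], hi = window[2L])
  keep <- is.finite(w$rwc) & is.finite(w$value)
  x <- w$rwc[keep]; y <- w$value[keep]
  if (length(x) < 3L)
    stop(sprintf("insufficient data: %d point(s) in the RWC window [%g, %g]",
                 length(x), window[1L], window[2L]), call. = FALSE)
  fit <- fit_linear(x, y)
  dy_bar <- mean_abs_deviation(x, y, fit)
  y_bar <- mean(y)

  # a perfect fit leaves only rounding-level residuals; treat scatter at
  # double precision relative to the data scale as exactly zero
  perfect <- dy_bar <= 1e-12 * max(mean(abs(y)), .Machine$double.xmin)
  if (perfect) dy_bar <- 0
  CR <- if (perfect) Inf else abs(fit$b) * delta_s / dy_bar
  mean_undefined <- y_bar == 0
  CS <- if (mean_undefined) NaN else 100 * abs(fit$b) / abs(y_bar)
  CI <- if (mean_undefined) NaN else 100 * dy_bar / abs(y_bar)

  structure(
    list(parameter = parameter, group = group, species = species,
         n = fit$n, a = fit$a, b = fit$b, y_bar = y_bar, dy_bar = dy_bar,
         r2 = fit$r2, CR = CR, CS = CS, CI = CI,
         reliable = is.finite(CR) && CR >= threshold || is.infinite(CR),
         perfect_fit = dy_bar == 0, mean_undefined = mean_undefined,
         window = as.numeric(window), delta_s = delta_s,
         threshold = threshold),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("reliability_result '%s' (n = %d, RWC %g-%g%%, delta_s = %g)\n",
              x$parameter, x$n, x$window[1L], x$window[2L], x$delta_s))
  cat(sprintf("  fit: y = %.5g %+.5g * RWC   R2 = %.4f\n", x$a, x$b, x$r2))
  cat(sprintf("  CR = %.4f  CS = %.4f  CI = %.4f  reliable: %s\n",
              x$CR, x$CS, x$CI, x$reliable))
  invisible(x)
}

#' @export
as.data.frame.reliability_result <- function(x, ...) {
  data.frame(parameter = x$parameter, group = x$group, species = x$species,
             n = x$n, a = x$a, b = x$b, y_bar = x$y_bar, dy_bar = x$dy_bar,
             r2 = x$r2, CR = x$CR, CS = x$CS, CI = x$CI,
             reliable = x$reliable, perfect_fit = x$perfect_fit,
             stringsAsFactors = FALSE)
}

#' Reliability coefficients for every parameter in a tidy series table
#'
#' Applies [compute_coefficients()] to each `(species, parameter)` group
#' of a tidy long table of observations.
#'
#' @param series A data.frame with columns `parameter`, `rwc`, `value`
#'   and optionally `species` and `group`.
#' @param ... Passed to [compute_coefficients()] (`delta_s`, `window`,
#'   `threshold`).
#' @return A data.frame with one row per (species, parameter), the
#'   columns of [as.data.frame.reliability_result()].
#' @export
reliability_table <- function(series, ...) {
  stopifnot(is.data.frame(series),
            all(c("parameter", "rwc", "value") %in% names(series)))
  if (!"species" %in% names(series)) series$species <- NA_character_
  if (!"group" %in% names(series)) series$group <- NA_character_
  pieces <- split(series, list(series$species, series$parameter), drop = TRUE)
  rows <- lapply(pieces, function(d) {
    as.data.frame(compute_coefficients(
      d$rwc, d$value, ...,
      parameter = d$parameter[1L], group = d$group[1L],
      species = d$species[1L]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank parameters by a reliability coefficient
#'
#' Sorts a reliability table in descending order of the chosen
#' coefficient (rank 1 = largest; `Inf`, from perfect fits, sorts
#' first). Ties are broken lexicographically by parameter name and
#' flagged. The `reliable` flag marks `CR >= threshold`.
#'
#' @param results A data.frame from [reliability_table()] (or rbind-ed
#'   [as.data.frame.reliability_result()] rows).
#' @param by Coefficient to rank by: `"CR"`, `"CS"` or `"CI"`.
#' @return The input with added columns `rank` and `tie`, sorted.
#' @export
rank_parameters <- function(results, by = c("CR", "CS", "CI")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            by %in% names(results))
  v <- results[[by]]
  ord <- order(-v, results$parameter)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tie <- duplicated(out[[by]]) | duplicated(out[[by]], fromLast = TRUE)
  if (any(out$tie, na.rm = TRUE))
    warning(sprintf("ties in %s broken by parameter name", by), call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-group rank sums and mean coefficients
#'
#' Parameters are assigned to groups by the leaf characteristic they
#' reflect (water potential, water indices, leaf structure, chlorophyll
#' content, chlorophyll fluorescence). For each group and each
#' coefficient this sums the within-species ranks (lower sum = the group
#' ranks better on that coefficient) and averages the coefficient
#' values.
#'
#' @param results A reliability table with a non-missing `group` column.
#' @param coefficients Coefficients to summarize (default CR, CS, CI).
#' @return A data.frame with one row per (species, group, coefficient):
#'   `rank_sum`, `mean_value`, `n_parameters`.
#' @export
group_rank_sums <- function(results, coefficients = c("CR", "CS", "CI")) {
  stopifnot(is.data.frame(results), "group" %in% names(results))
  if (any(is.na(results$group)))
    stop(sprintf("parameter(s) without a group assignment: %s",
                 paste(results$parameter[is.na(results$group)], collapse = ", ")),
         call. = FALSE)
  per_species <- split(results, results$species, drop = TRUE)
  rows <- list()
  for (sp in names(per_species)) {
    res <- per_species[[sp]]
    for (coef in coefficients) {
      ranked <- rank_parameters(res, by = coef)
      agg_rank <- tapply(ranked$rank, ranked$group, sum)
      finite_mean <- function(v) mean(v[is.finite(v)])
      agg_mean <- tapply(ranked[[coef]], ranked$group, finite_mean)
      agg_n <- tapply(ranked$rank, ranked$group, length)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, group = names(agg_rank), coefficient = coef,
        rank_sum = as.numeric(agg_rank), mean_value = as.numeric(agg_mean),
        n_parameters = as.integer(agg_n), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Squared correlation between two reliability coefficients
#'
#' Regresses one coefficient on another across parameters (OLS) and
#' returns the r-squared — e.g. CR on CS to ask whether reliability is
#' driven by sensitivity. Non-finite pairs (perfect fits with infinite
#' CR, undefined CS/CI) are excluded with a message. A constant response
#' has no variance to explain and yields `r2 = 0`.
#'
#' @param results A reliability table.
#' @param x,y Names of the predictor and response coefficients.
#' @return The r-squared of the OLS fit of `y` on `x`.
#' @export
correlate_coefficients <- function(results, x = "CR", y = "CS") {
  stopifnot(is.data.frame(results), x %in% names(results),
            y %in% names(results))
  xv <- results[[x]]; yv <- results[[y]]
  keep <- is.finite(xv) & is.finite(yv)
  if (sum(!keep) > 0)
    message(sprintf("%d non-finite coefficient pair(s) excluded", sum(!keep)))
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3L)
    stop("insufficient data: fewer than 3 finite coefficient pairs",
         call. = FALSE)
  if (stats::var(yv) == 0) return(0)
  fit_linear(xv, yv)$r2
}
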