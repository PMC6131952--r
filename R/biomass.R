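#' Fit a qPCR standard curve
#'
#' Least-squares fit of `Ct ~ log10(copies per reaction)` over the nonzero
#' standards. Zero-copy wells are excluded from the fit (log undefined)
#' and serve only as no-template contamination checks. Amplification
#' efficiency is `10^(-1/slope) - 1` (1 = 100%: perfect doubling per
#' cycle).
#'
#' @param standards data.frame with `copies_per_reaction` and `ct`
#'   (NA = undetermined); replicate wells are individual rows.
#' @return object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `standards_used`.
#' @export
fit_standard_curve <- function(standards) {
  ok <- standards$copies_per_reaction > 0 & !is.na(standards$ct)
  df <- standards[ok, , drop = FALSE]
  if (length(unique(df$copies_per_reaction)) < 3L)
    stop("need at least 3 distinct nonzero standards")
  fit <- stats::lm(ct ~ log10(copies_per_reaction), data = df)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) stop("invalid standard curve: nonnegative slope")
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 efficiency = 10^(-1 / slope) - 1,
                 standards_used = sort(unique(df$copies_per_reaction))),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve: Ct = %.4f %+.4f*log10(copies); R2 = %.4f, efficiency = %.1f%%\n",
    x$intercept, x$slope, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Absolute quantification from Ct values
#'
#' Inverts the standard curve: copies per reaction
#' `= 10^((Ct - intercept)/slope)` using the mean Ct over a sample's
#' determined replicate wells, then divides by the template volume to get
#' copies/uL. Samples whose wells are all undetermined get 0 copies and a
#' flag.
#'
#' @param ct_values data.frame with `sample_id` and `ct` (one row per
#'   well; NA = undetermined).
#' @param curve a [fit_standard_curve()] result.
#' @param template_volume_ul template volume per reaction (default 5 uL).
#' @return data.frame per sample: `sample_id`, `mean_ct`,
#'   `copies_per_reaction`, `copies_per_ul`, `undetermined`.
#' @export
quantify <- function(ct_values, curve, template_volume_ul = 5) {
  stopifnot(inherits(curve, "standard_curve"), template_volume_ul > 0)
  sp <- split(ct_values$ct, ct_values$sample_id)
  rows <- lapply(names(sp), function(id) {
    ct <- sp[[id]][!is.na(sp[[id]])]
    if (!length(ct))
      return(data.frame(sample_id = id, mean_ct = NA_real_,
                        copies_per_reaction = 0, copies_per_ul = 0,
                        undetermined = TRUE))
    mct <- mean(ct)
    cp <- 10^((mct - curve$intercept) / curve$slope)
    data.frame(sample_id = id, mean_ct = mct, copies_per_reaction = cp,
               copies_per_ul = cp / template_volume_ul,
               undetermined = FALSE)
  })
  out <- do.call(rbind, rows)
  out[match(unique(ct_values$sample_id), out$sample_id), , drop = FALSE]
}

#' Expected copy numbers along a dilution series
#'
#' Two calibrations of the expected concentration at each level: the naive
#' expectation `stock / factor`, and a sequential recalibration that
#' propagates the measured concentration of the parent tube — each
#' dilution is prepared from the previous one, so
#' `expected(k) = measured(k-1) * factor(k-1) / factor(k)`.
#'
#' @param stock_measured measured copies/uL of the undiluted stock
#'   (factor 1).
#' @param factors dilution factors, ascending, starting at 1.
#' @param measured measured copies/uL per level (same order as
#'   `factors`).
#' @return data.frame per level: `dilution_factor`, `naive_expected`,
#'   `sequential_expected`, `measured`; attribute `log10_correlation`
#'   holds the Pearson correlation of log10 naive expectation with log10
#'   measurement.
#' @export
expected_copies <- function(stock_measured, factors, measured) {
  stopifnot(length(factors) == length(measured),
            all(diff(factors) > 0), factors[1L] == 1)
  naive <- stock_measured / factors
  seqexp <- numeric(length(factors))
  seqexp[1L] <- stock_measured
  for (k in seq_along(factors)[-1L]) {
    parent <- measured[k - 1L]
    seqexp[k] <- if (is.na(parent)) NA_real_ else
      parent * factors[k - 1L] / factors[k]
  }
  out <- data.frame(dilution_factor = factors, naive_expected = naive,
                    sequential_expected = seqexp, measured = measured)
  ok <- !is.na(measured) & measured > 0
  attr(out, "log10_correlation") <- if (sum(ok) >= 3L)
    stats::cor(log10(naive[ok]), log10(measured[ok])) else NA_real_
  out
}

#' Assemble the CV-versus-biomass dataset
#'
#' One row per taxon x dilution level: the CV and mean relative abundance
#' across the level's replicates, and the level's biomass as the mean
#' qPCR-measured copies/uL. Rows are kept only when the taxon's mean
#' relative abundance reaches `min_mean_ra`, it was detected in at least
#' `min_detected` replicates, and the CV is defined and positive (all
#' three quantities are logged downstream).
#'
#' @param relabund relative-abundance [feature_table()] of the dilution
#'   samples.
#' @param metadata sample metadata; rows with a `dilution_factor` define
#'   the series.
#' @param qpcr data.frame with `sample_id` and `copies_per_ul`.
#' @param taxon_rank rank to collapse to (default genus).
#' @param min_mean_ra minimum mean relative abundance, as a fraction
#'   (default 0.001 = 0.1%).
#' @param min_detected minimum replicates with detection (default 3).
#' @return data.frame: `taxon`, `dilution_factor`, `mean_ra`, `cv`, `sd`,
#'   `copies_per_ul`, `n_detected`, `n_replicates`.
#' @export
build_cv_dataset <- function(relabund, metadata, qpcr,
                             taxon_rank = "genus", min_mean_ra = 0.001,
                             min_detected = 3) {
  metadata <- match_metadata(relabund, metadata)
  sel <- !is.na(metadata$dilution_factor)
  if (!any(sel)) stop("metadata contains no dilution samples")
  tab <- collapse_rank(subset_table(relabund,
                                    samples = sample_ids(relabund)[sel]),
                       taxon_rank)
  md <- metadata[sel, , drop = FALSE]
  copies <- qpcr$copies_per_ul[match(md$sample_id, qpcr$sample_id)]
  rows <- list()
  for (d in sort(unique(md$dilution_factor))) {
    idx <- which(md$dilution_factor == d)
    if (length(idx) < 2L) next
    m <- tab$counts[, idx, drop = FALSE]
    mu <- rowMeans(m)
    sd_ <- apply(m, 1L, stats::sd)
    cv <- ifelse(mu > 0, 100 * sd_ / mu, NA_real_)
    nd <- rowSums(m > 0)
    keep <- mu >= min_mean_ra & nd >= min_detected & !is.na(cv) & cv > 0
    if (!any(keep)) next
    rows[[as.character(d)]] <- data.frame(
      taxon = rownames(m)[keep], dilution_factor = d, mean_ra = mu[keep],
      cv = cv[keep], sd = sd_[keep],
      copies_per_ul = mean(copies[idx], na.rm = TRUE),
      n_detected = nd[keep], n_replicates = length(idx), row.names = NULL)
  }
  if (!length(rows)) stop("no rows pass the inclusion filters")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the biomass-abundance variation model
#'
#' Ordinary least squares of
#' `log10(CV) ~ log10(copies/uL) + log10(mean relative abundance)` on a
#' [build_cv_dataset()] table. Mean relative abundance enters in percent
#' by default; the unit convention is stored on the model so prediction
#' applies the same convention. `response = "sd"` swaps the CV for the
#' raw standard deviation of relative abundances.
#'
#' @param ds a [build_cv_dataset()] data.frame.
#' @param response `"cv"` (percent) or `"sd"`.
#' @param ra_unit `"percent"` or `"fraction"`.
#' @return object of class `variation_model`: `coefficients` (data.frame
#'   with estimate / std_error / t_value / p_value), `sigma`,
#'   `r_squared`, `adj_r_squared`, `f_statistic`, `df`, `n`, `ra_unit`,
#'   `response`.
#' @export
fit_variation_model <- function(ds, response = c("cv", "sd"),
                                ra_unit = c("percent", "fraction")) {
  response <- match.arg(response)
  ra_unit <- match.arg(ra_unit)
  if (nrow(ds) < 4L) stop("need at least 4 rows")
  y <- if (response == "cv") ds$cv else ds$sd
  ra <- if (ra_unit == "percent") 100 * ds$mean_ra else ds$mean_ra
  df <- data.frame(ly = log10(y), lc = log10(ds$copies_per_ul),
                   lm_ = log10(ra))
  if (any(!is.finite(as.matrix(df))))
    stop("all logged quantities must be positive and finite")
  if (stats::sd(df$lc) == 0 || stats::sd(df$lm_) == 0 ||
      abs(stats::cor(df$lc, df$lm_)) > 0.999)
    stop("collinear or constant predictors")
  if (stats::sd(df$ly) == 0) {
    co <- data.frame(estimate = c(df$ly[1L], 0, 0), std_error = 0,
                     t_value = NA_real_, p_value = NA_real_,
                     row.names = c("intercept", "log10_copies_per_ul",
                                   "log10_mean_ra"))
    return(structure(list(coefficients = co, sigma = 0, r_squared = 0,
                          adj_r_squared = 0, f_statistic = NA_real_,
                          df = c(2L, nrow(df) - 3L), n = nrow(ds),
                          ra_unit = ra_unit, response = response),
                     class = "variation_model"))
  }
  fit <- stats::lm(ly ~ lc + lm_, data = df)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "std_error", "t_value", "p_value")
  rownames(co) <- c("intercept", "log10_copies_per_ul", "log10_mean_ra")
  structure(list(coefficients = co, sigma = sm$sigma,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 f_statistic = unname(sm$fstatistic[1L]),
                 df = unname(sm$fstatistic[2:3]), n = nrow(ds),
                 ra_unit = ra_unit, response = response),
            class = "variation_model")
}

#' @export
print.variation_model <- function(x, ...) {
  cat(sprintf(
    "variation_model: log10(%s) = %.4f %+.4f*log10(copies/uL) %+.4f*log10(mean RA [%s])\n",
    x$response, x$coefficients$estimate[1L], x$coefficients$estimate[2L],
    x$coefficients$estimate[3L], x$ra_unit))
  cat(sprintf("  n = %d, R2 = %.4f (adj %.4f), F = %.2f on df (%d, %d)\n",
              x$n, x$r_squared, x$adj_r_squared, x$f_statistic,
              x$df[1L], x$df[2L]))
  invisible(x)
}

#' Predict variation from biomass and abundance
#'
#' Back-transforms the fitted log-log model:
#' `10^(b0 + b1 log10(copies) + b2 log10(mean_ra))`. `mean_ra` must be
#' given in the model's stored unit (percent by default).
#'
#' @param model a [fit_variation_model()] result.
#' @param copies_per_ul positive biomass value(s).
#' @param mean_ra positive mean relative abundance value(s), in
#'   `model$ra_unit`.
#' @return predicted CV (percent) or SD, recycled over the inputs.
#' @export
predict_variation <- function(model, copies_per_ul, mean_ra) {
  stopifnot(inherits(model, "variation_model"))
  if (any(copies_per_ul <= 0) || any(mean_ra <= 0))
    stop("copies_per_ul and mean_ra must be positive")
  b <- model$coefficients$estimate
  10^(b[1L] + b[2L] * log10(copies_per_ul) + b[3L] * log10(mean_ra))
}

#' Prediction grid over biomass and abundance
#'
#' Evaluates [predict_variation()] over the cross-product of biomass and
#' abundance values. The default grid spans low (10), medium (1000) and
#' high (100,000) copies/uL against 1-50% mean relative abundance.
#'
#' @param model a [fit_variation_model()] result (percent units assumed
#'   for the default grid).
#' @param copies_per_ul grid rows.
#' @param mean_ra grid columns, in `model$ra_unit`.
#' @return numeric matrix, rows named by copies/uL, columns by abundance.
#' @export
prediction_grid <- function(model, copies_per_ul = c(10, 1e3, 1e5),
                            mean_ra = c(1, 5, 10, 25, 50)) {
  out <- outer(copies_per_ul, mean_ra,
               function(c, m) predict_variation(model, c, m))
  dimnames(out) <- list(format(copies_per_ul, scientific = FALSE,
                               trim = TRUE),
                        format(mean_ra, trim = TRUE))
  out
}
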