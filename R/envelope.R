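#' Fit a Gaussian envelope over a charge-state series
#'
#' ESI spectra of a folded species show a smooth, roughly Gaussian
#' distribution of ion intensity across consecutive charge states. This
#' fits `height ~ A * exp(-(mz - mu)^2 / (2 sigma^2))` by least squares over
#' the matched peak heights of one species at one voltage step. The apex
#' intensity `A` and apex m/z `mu` are the quantities propagated to the
#' survival-curve analysis; the intensity-weighted mean charge
#' `sum(z * h) / sum(h)` is reported alongside.
#'
#' With fewer than three non-zero heights the fit degrades to
#' apex = maximum height at its m/z with `sigma = NA` (`degenerate = TRUE`).
#' With no signal at all a flagged absent result is returned (apex 0),
#' never an error: species absence is data.
#'
#' @param assignments Data frame from [assign_charge_series()].
#' @return An object of class `envelope_fit`: list with `species`,
#'   `apex_intensity`, `apex_mz`, `sigma`, `mean_charge`, `points_used`,
#'   `degenerate`, `absent`.
#' @export
fit_envelope <- function(assignments) {
  stopifnot(is.data.frame(assignments),
            all(c("charge", "expected_mz", "matched_mz", "height") %in% names(assignments)))
  sp <- if ("species" %in% names(assignments)) assignments$species[1] else NA_character_
  nz <- which(assignments$height > 0)
  if (length(nz) == 0L) {
    return(structure(list(species = sp, apex_intensity = 0, apex_mz = NA_real_,
                          sigma = NA_real_, mean_charge = NA_real_,
                          points_used = 0L, degenerate = TRUE, absent = TRUE),
                     class = "envelope_fit"))
  }
  h <- assignments$height[nz]
  mz <- ifelse(is.na(assignments$matched_mz[nz]),
               assignments$expected_mz[nz], assignments$matched_mz[nz])
  z <- assignments$charge[nz]
  mean_charge <- sum(z * h) / sum(h)
  if (length(nz) < 3L) {
    i <- which.max(h)
    return(structure(list(species = sp, apex_intensity = h[i], apex_mz = mz[i],
                          sigma = NA_real_, mean_charge = mean_charge,
                          points_used = length(nz), degenerate = TRUE, absent = FALSE),
                     class = "envelope_fit"))
  }
  i0 <- which.max(h)
  span <- diff(range(mz))
  start <- list(A = h[i0], mu = mz[i0], s = max(span / 2, 1e-6))
  fit <- try(minpack.lm::nlsLM(
    h ~ A * exp(-(mz - mu)^2 / (2 * s^2)),
    start = start,
    lower = c(A = 0, mu = min(mz) - span, s = 1e-9),
    upper = c(A = Inf, mu = max(mz) + span, s = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    i <- which.max(h)
    return(structure(list(species = sp, apex_intensity = h[i], apex_mz = mz[i],
                          sigma = NA_real_, mean_charge = mean_charge,
                          points_used = length(nz), degenerate = TRUE, absent = FALSE),
                     class = "envelope_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(species = sp, apex_intensity = unname(cf["A"]),
                 apex_mz = unname(cf["mu"]), sigma = unname(abs(cf["s"])),
                 mean_charge = mean_charge, points_used = length(nz),
                 degenerate = FALSE, absent = FALSE),
            class = "envelope_fit")
}

#' @export
print.envelope_fit <- function(x, ...) {
  cat(sprintf("<envelope_fit> %s: apex %.4g at m/z %.2f, mean charge %.3f (%d points%s)\n",
              x$species, x$apex_intensity,
              if (is.na(x$apex_mz)) NA else x$apex_mz,
              x$mean_charge, x$points_used,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Normalized educt/product fractions at one voltage step
#'
#' Converts the fitted apex intensities of the educt (intact complex) and
#' its dissociation products into normalized fractions. The default
#' `pairs-mean` convention averages the product apex intensities: one educt
#' dissociation yields one of each product, so the two product signals are
#' two measurements of the same dissociation extent, and
#' `norm_ed = I_ed / (I_ed + mean(I_products))`. The `sum` convention
#' (alias `educt-vs-total`) pools the products instead.
#'
#' @param educt `envelope_fit` of the educt species.
#' @param products List of `envelope_fit`s of product species.
#' @param mode Normalization convention.
#' @param delta_cv Voltage step (volts), carried through.
#' @param replicate_id Replicate index, carried through.
#' @return Data frame row: `delta_cv`, `norm_ed`, `norm_prod`, `replicate_id`.
#' @export
normalize_step <- function(educt, products,
                           mode = c("pairs-mean", "sum", "educt-vs-total"),
                           delta_cv = NA_real_, replicate_id = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(educt, "envelope_fit"))
  ip <- vapply(products, function(p) p$apex_intensity, 0)
  ie <- educt$apex_intensity
  pool <- switch(mode,
                 "pairs-mean" = mean(ip),
                 "sum" = ,
                 "educt-vs-total" = sum(ip))
  if (ie + pool <= 0)
    stop("undefined point: total signal is zero at this step", call. = FALSE)
  norm_ed <- ie / (ie + pool)
  data.frame(delta_cv = delta_cv, norm_ed = norm_ed,
             norm_prod = 1 - norm_ed, replicate_id = replicate_id)
}

#' Aggregate replicate fractions per voltage step
#'
#' Groups normalized points by identical `delta_cv` and reports the mean and
#' sample standard deviation of `norm_ed`. Steps observed in a single
#' replicate get `sd = 0` with `single_replicate = TRUE`.
#'
#' @param points Data frame of rows from [normalize_step()].
#' @return Data frame: `delta_cv`, `mean_norm_ed`, `sd_norm_ed`, `n`,
#'   `single_replicate`, sorted by `delta_cv`.
#' @export
aggregate_replicates <- function(points) {
  stopifnot(is.data.frame(points), all(c("delta_cv", "norm_ed") %in% names(points)))
  sp <- split(points$norm_ed, points$delta_cv)
  out <- data.frame(
    delta_cv = as.numeric(names(sp)),
    mean_norm_ed = vapply(sp, mean, 0),
    sd_norm_ed = vapply(sp, function(v) if (length(v) > 1L) stats::sd(v) else 0, 0),
    n = vapply(sp, length, 0L)
  )
  out$single_replicate <- out$n == 1L
  out <- out[order(out$delta_cv), , drop = FALSE]
  rownames(out) <- NULL
  out
}
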