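#' Construct dose-response data
#'
#' @param compound Compound name.
#' @param sample_id Cell line / sample identifier.
#' @param dose Concentrations in uM (0 = vehicle), one per measurement.
#' @param response Viability fractions (>= 0), aligned with `dose`.
#' @param replicate Optional replicate labels.
#' @return An object of class `DoseResponseData`.
#' @export
dose_response_data <- function(compound, sample_id, dose, response,
                               replicate = NULL) {
  stopifnot(length(dose) == length(response))
  if (any(dose < 0)) stop("negative dose")
  if (any(response < 0)) stop("negative response")
  if (length(unique(dose[dose > 0])) < 4) {
    stop("need >= 4 distinct non-zero doses")
  }
  if (is.null(replicate)) replicate <- rep(1L, length(dose))
  structure(
    list(compound = compound, sample_id = sample_id,
         data = data.frame(dose = dose, response = response,
                           replicate = replicate)),
    class = "DoseResponseData"
  )
}

#' Read a dose-response TSV
#'
#' Layout: `compound  sample_id  dose_uM  viability  replicate`.
#'
#' @param path Path to the TSV.
#' @return List of [dose_response_data()] objects, one per
#'   compound/sample combination.
#' @export
read_dose_response <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("compound", "sample_id", "dose_uM", "viability", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("dose-response table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  keys <- unique(df[c("compound", "sample_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$compound == keys$compound[i] &
                df$sample_id == keys$sample_id[i], ]
    dose_response_data(keys$compound[i], keys$sample_id[i],
                       sub$dose_uM, sub$viability, sub$replicate)
  })
}

.fourpl <- function(d, top, bottom, hill, ic50) {
  bottom + (top - bottom) / (1 + (d / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Model: `response(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)`,
#' fitted by nonlinear least squares in log10-dose space with multi-start
#' initialization (hill in 0.5/1/2, ic50 over a geometric grid spanning
#' the dose range; best residual sum of squares wins). Vehicle (dose 0)
#' measurements are excluded from the fit. `top`/`bottom` are
#' unconstrained, initialized at the max/min mean response.
#'
#' The fit is censored (`converged = FALSE`) when the optimizer fails or
#' the fitted IC50 falls outside `[min dose / 10, max dose * 10]`; the
#' IC50 is then reported as a directional bound (`censored = "greater"`
#' with `ic50 = max dose` for no observable inhibition, `"less"` with
#' `ic50 = min dose / 10` for complete inhibition at all doses).
#'
#' @param data A [dose_response_data()].
#' @return A `FourPLFit`: `top`, `bottom`, `hill`, `ic50` (uM), `rss`,
#'   `converged`, `censored` (`"none"`, `"greater"`, `"less"`),
#'   `compound`, `sample_id`.
#' @export
fit_4pl <- function(data) {
  stopifnot(inherits(data, "DoseResponseData"))
  df <- data$data[data$data$dose > 0, , drop = FALSE]
  d <- df$dose
  y <- df$response
  dmin <- min(d)
  dmax <- max(d)
  mk <- function(top, bottom, hill, ic50, rss, converged, censored) {
    structure(list(top = top, bottom = bottom, hill = hill, ic50 = ic50,
                   rss = rss, converged = converged, censored = censored,
                   compound = data$compound, sample_id = data$sample_id),
              class = "FourPLFit")
  }
  ud <- sort(unique(d))
  means <- vapply(ud, function(dd) mean(y[d == dd]), numeric(1))
  top0 <- max(means)
  bottom0 <- min(means)
  if (diff(range(y)) < 1e-12) {
    return(mk(top0, bottom0, NA_real_, dmax, 0, FALSE, "greater"))
  }
  best <- NULL
  ld <- log10(d)
  grid_ic50 <- 10^seq(log10(dmin), log10(dmax), length.out = 7)
  for (hill0 in c(0.5, 1, 2)) {
    for (ic0 in grid_ic50) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + 10^(hill * (ld - lic50))),
          start = list(top = top0, bottom = bottom0, hill = hill0,
                       lic50 = log10(ic0)),
          control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) {
        co <- stats::coef(fit)
        best <- list(top = unname(co["top"]), bottom = unname(co["bottom"]),
                     hill = unname(co["hill"]),
                     ic50 = 10^unname(co["lic50"]), rss = rss)
      }
    }
  }
  no_inhibition <- unname(means[length(means)] >= means[1])
  if (is.null(best)) {
    return(mk(top0, bottom0, NA_real_,
              if (no_inhibition) dmax else dmin / 10, Inf, FALSE,
              if (no_inhibition) "greater" else "less"))
  }
  if (best$ic50 > dmax * 10 || best$hill <= 0) {
    return(mk(best$top, best$bottom, best$hill, dmax, best$rss, FALSE,
              "greater"))
  }
  if (best$ic50 < dmin / 10) {
    return(mk(best$top, best$bottom, best$hill, dmin / 10, best$rss, FALSE,
              "less"))
  }
  mk(best$top, best$bottom, best$hill, best$ic50, best$rss, TRUE, "none")
}

#' @export
print.FourPLFit <- function(x, ...) {
  ic <- switch(x$censored, none = sprintf("%.4g", x$ic50),
               greater = sprintf(">%.4g", x$ic50),
               less = sprintf("<%.4g", x$ic50))
  cat(sprintf("FourPLFit %s/%s: IC50 %s uM (top %.3f, bottom %.3f, hill %.3f)%s\n",
              x$compound, x$sample_id, ic, x$top, x$bottom, x$hill,
              if (x$converged) "" else " [censored]"))
  invisible(x)
}

#' Resistance index from a pair of dose-response fits
#'
#' `RI = IC50(resistant) / IC50(parental)` for the same compound. A
#' censored IC50 propagates as a directional bound on the ratio
#' (e.g. `>100 / 0.04 -> > 2500`); bounds in conflicting or identical
#' directions on both sides are indeterminate.
#'
#' @param fit_r,fit_p `FourPLFit`s for the resistant and parental lines
#'   (same compound), or bare numeric IC50 values for the worked-example
#'   path where fitting is bypassed.
#' @param compound Compound name when bare numerics are given.
#' @return A `ResistanceIndex`: `ri`, `censored` (`"none"`, `"greater"`,
#'   `"less"`, `"indeterminate"`), `resistant_id`, `parental_id`,
#'   `compound`.
#' @export
resistance_index <- function(fit_r, fit_p, compound = NULL) {
  as_fit <- function(x, id) {
    if (inherits(x, "FourPLFit")) return(x)
    stopifnot(is.numeric(x), length(x) == 1, x > 0)
    structure(list(ic50 = x, censored = "none", compound = compound,
                   sample_id = id, converged = TRUE),
              class = "FourPLFit")
  }
  fit_r <- as_fit(fit_r, "resistant")
  fit_p <- as_fit(fit_p, "parental")
  if (!identical(fit_r$compound, fit_p$compound)) {
    stop("resistance index requires the same compound on both fits")
  }
  ratio <- fit_r$ic50 / fit_p$ic50
  cr <- fit_r$censored
  cp <- fit_p$censored
  censored <- if (cr == "none" && cp == "none") "none"
  else if (cr == "greater" && cp == "none") "greater"
  else if (cr == "less" && cp == "none") "less"
  else if (cr == "none" && cp == "greater") "less"
  else if (cr == "none" && cp == "less") "greater"
  else if (cr == "greater" && cp == "less") "greater"
  else if (cr == "less" && cp == "greater") "less"
  else "indeterminate"
  structure(
    list(ri = if (censored == "indeterminate") NA_real_ else ratio,
         censored = censored, resistant_id = fit_r$sample_id,
         parental_id = fit_p$sample_id, compound = fit_r$compound),
    class = "ResistanceIndex"
  )
}

#' @export
print.ResistanceIndex <- function(x, ...) {
  ri <- switch(x$censored, none = sprintf("%.4g", x$ri),
               greater = sprintf(">%.4g", x$ri),
               less = sprintf("<%.4g", x$ri),
               indeterminate = "indeterminate")
  cat(sprintf("ResistanceIndex %s: %s (%s / %s)\n",
              if (is.null(x$compound)) "" else x$compound, ri,
              x$resistant_id, x$parental_id))
  invisible(x)
}
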