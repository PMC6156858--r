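# Dose-response confirmation: four-parameter logistic (4PL) fits and
# cross-cell-line IC50 selectivity summaries.

#' Fit a four-parameter logistic dose-response curve
#'
#' Unweighted least-squares fit of
#' `v(d) = bottom + (top - bottom) / (1 + (d/ic50)^hill)` on the viability
#' scale, with multi-start initialization: an IC50 grid spanning the tested
#' positive doses crossed with Hill slopes {1, 2, -1, -2}; the best
#' converged start by residual sum of squares wins.
#'
#' @param doses doses in micromolar; at least 5 distinct values including 0
#'   (the confirmation assays spanned 0-15 micromolar).
#' @param viability viability percent, same length as `doses`.
#' @return An object of class `dose_response_fit`: list with `top`, `bottom`,
#'   `ic50`, `hill`, `rss`, `converged` and `extrapolated` (`TRUE`, with a
#'   warning, when the fitted IC50 falls outside the positive tested dose
#'   range).
#' @export
fit_4pl <- function(doses, viability) {
  if (length(doses) != length(viability)) stop("length mismatch")
  ok <- is.finite(doses) & is.finite(viability)
  doses <- doses[ok]; viability <- viability[ok]
  if (length(unique(doses)) < 5L || !any(doses == 0)) {
    stop("need >= 5 distinct doses including 0")
  }
  if (stats::sd(viability) == 0) {
    stop("no-response: all viabilities equal, IC50 undefined")
  }
  dpos <- sort(unique(doses[doses > 0]))
  ic50_grid <- exp(seq(log(min(dpos)), log(max(dpos)), length.out = 5L))
  lo <- min(doses); hi <- max(doses)
  top0 <- mean(viability[doses == lo])
  bot0 <- mean(viability[doses == hi])
  df <- data.frame(d = doses, v = viability)

  best <- NULL
  for (ic in ic50_grid) {
    for (h in c(1, 2, -1, -2)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          v ~ bottom + (top - bottom) / (1 + (d / ic50)^hill),
          data = df,
          start = list(top = top0, bottom = bot0, ic50 = ic, hill = h),
          lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-9, hill = -Inf),
          control = minpack.lm::nls.lm.control(
            maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) next
      rss <- stats::deviance(fit)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(top = NA_real_, bottom = NA_real_,
                          ic50 = NA_real_, hill = NA_real_, rss = NA_real_,
                          converged = FALSE, extrapolated = NA),
                     class = "dose_response_fit"))
  }
  cf <- as.list(stats::coef(best$fit))
  # canonical orientation: report the curve with top >= bottom
  if (cf$top < cf$bottom) {
    cf <- list(top = cf$bottom, bottom = cf$top, ic50 = cf$ic50,
               hill = -cf$hill)
  }
  extrapolated <- cf$ic50 < min(dpos) || cf$ic50 > max(dpos)
  if (extrapolated) {
    warning(sprintf("fitted IC50 (%.3g) lies outside the tested dose range",
                    cf$ic50))
  }
  structure(list(top = cf$top, bottom = cf$bottom, ic50 = cf$ic50,
                 hill = cf$hill, rss = best$rss,
                 converged = isTRUE(best$fit$convInfo$isConv),
                 extrapolated = extrapolated),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<4PL fit> top %.3g bottom %.3g IC50 %.4g uM hill %.3g (rss %.3g%s)\n",
    x$top, x$bottom, x$ic50, x$hill, x$rss,
    if (isTRUE(x$converged)) "" else ", NOT converged"))
  invisible(x)
}

#' Fit 4PL curves for every compound and cell line in a dose table
#'
#' @param doses data.frame with columns `compound_id`, `cell_line`,
#'   `dose_uM`, `viability` (the dose-response CSV layout).
#' @return data.frame, one row per compound x cell line: the fitted
#'   parameters plus `rss`, `converged`, `extrapolated`.
#' @export
fit_dose_table <- function(doses) {
  need <- c("compound_id", "cell_line", "dose_uM", "viability")
  if (!all(need %in% names(doses))) {
    stop("dose table must have columns: ", paste(need, collapse = ", "))
  }
  groups <- split(doses, list(doses$compound_id, doses$cell_line),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    f <- suppressWarnings(fit_4pl(g$dose_uM, g$viability))
    data.frame(compound_id = g$compound_id[1], cell_line = g$cell_line[1],
               top = f$top, bottom = f$bottom, ic50_uM = f$ic50,
               hill = f$hill, rss = f$rss, converged = f$converged,
               extrapolated = f$extrapolated)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound_id, out$cell_line), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-cell-line IC50 selectivity profile
#'
#' Compares converged 4PL fits across cell lines by pairwise IC50 ratios and
#' flags a compound as preferential for the acid-adapted line when
#' IC50(adapted) < IC50(parental) and both fall below IC50(normal).
#'
#' @param fits_by_cell_line named list of [fit_4pl()] results, one per cell
#'   line (>= 2 converged fits required).
#' @param adapted,parental,normal names of the corresponding entries; the
#'   preferential flag is only evaluated when all three are present and
#'   converged (otherwise `NA`).
#' @return list with `ratios` (data.frame `numerator`, `denominator`,
#'   `ic50_ratio`, sorted ascending) and `preferential_for_adapted`.
#' @export
selectivity_profile <- function(fits_by_cell_line,
                                adapted = "adapted",
                                parental = "parental",
                                normal = "normal") {
  if (length(fits_by_cell_line) < 2L) {
    stop("need fits for at least 2 cell lines")
  }
  conv <- vapply(fits_by_cell_line, function(f) isTRUE(f$converged),
                 logical(1))
  if (any(!conv)) {
    warning("excluding unconverged fits: ",
            paste(names(fits_by_cell_line)[!conv], collapse = ", "))
  }
  fits <- fits_by_cell_line[conv]
  if (length(fits) < 2L) stop("fewer than 2 converged fits")
  ic50 <- vapply(fits, `[[`, numeric(1), "ic50")
  pairs <- expand.grid(numerator = names(ic50), denominator = names(ic50),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$numerator != pairs$denominator, , drop = FALSE]
  pairs$ic50_ratio <- ic50[pairs$numerator] / ic50[pairs$denominator]
  pairs <- pairs[order(pairs$ic50_ratio), , drop = FALSE]
  rownames(pairs) <- NULL
  flag <- NA
  if (all(c(adapted, parental, normal) %in% names(ic50))) {
    flag <- ic50[[adapted]] < ic50[[parental]] &&
      ic50[[adapted]] < ic50[[normal]] &&
      ic50[[parental]] < ic50[[normal]]
  }
  list(ratios = pairs, preferential_for_adapted = flag)
}
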