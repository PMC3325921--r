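#' Relative quantification fold change (2^-ddCt)
#'
#' Comparative-Ct qPCR quantification: the target gene's Ct is first
#' referenced to a housekeeping gene within each sample (dCt = Ct_target -
#' Ct_reference), then the treated sample's dCt is referenced to the control
#' sample's, and the fold change is `2^-ddCt`. Adding a common offset to
#' both dCt values leaves the fold unchanged. Vectorized.
#'
#' @param target_treated,ref_treated,target_control,ref_control Ct values
#'   (cycles, > 0 and finite).
#' @return fold change(s) relative to control (> 0; 1 = no change).
#' @export
ddct_fold_change <- function(target_treated, ref_treated,
                             target_control, ref_control) {
  cts <- cbind(target_treated, ref_treated, target_control, ref_control)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    stop("all four Ct values must be finite and positive")
  }
  ddct <- (target_treated - ref_treated) - (target_control - ref_control)
  2^(-ddct)
}

#' Olive tail moment of a comet-assay cell
#'
#' `OTM = tail length x fraction of DNA in the tail`. The DNA fraction is
#' stored on the 0-1 scale; image-analysis exports that report percent can
#' pass `units = "percent"` to divide by 100. Vectorized; per-slide means
#' are plain means over the measured cells.
#'
#' @param tail_length tail length in micrometres (>= 0).
#' @param dna_in_tail fraction of DNA in the tail, in \[0, 1\] (or percent
#'   in \[0, 100\] with `units = "percent"`).
#' @param units `"fraction"` (default) or `"percent"`.
#' @return olive tail moment(s), micrometres.
#' @export
olive_tail_moment <- function(tail_length, dna_in_tail,
                              units = c("fraction", "percent")) {
  units <- match.arg(units)
  if (units == "percent") dna_in_tail <- dna_in_tail / 100
  if (any(tail_length < 0)) stop("tail_length must be >= 0")
  if (any(dna_in_tail < 0 | dna_in_tail > 1)) {
    stop("dna_in_tail must be within [0, 1] (fraction) or [0, 100] (percent)")
  }
  tail_length * dna_in_tail
}

#' Linear dose-response regression between expression and DNA damage
#'
#' Ordinary least-squares fit of mean DNA damage (e.g. olive tail moment)
#' on mean expression fold change across dose groups, with the squared
#' Pearson correlation as goodness of fit. `r_squared` is invariant under
#' affine rescaling of either axis.
#'
#' @param x numeric, mean expression fold change per dose group.
#' @param y numeric, mean damage per dose group (same length).
#' @return list of class `dose_response_fit`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
dose_response_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 dose groups")
  if (stats::sd(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)^2
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n = length(x)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("dose-response OLS: y = %.4g + %.4g x  (r^2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Micronucleus frequency
#'
#' Fraction of micronucleated cells among the scored cells, and the
#' conventional per-1000-cells rate.
#'
#' @param mn_cells number of micronucleated cells (0 <= mn <= total).
#' @param total_cells number of cells scored (>= 1; conventionally 1000).
#' @return list with `fraction` and `per_1000`.
#' @export
micronucleus_frequency <- function(mn_cells, total_cells) {
  if (any(total_cells < 1)) stop("total_cells must be >= 1")
  if (any(mn_cells < 0 | mn_cells > total_cells)) {
    stop("mn_cells must be between 0 and total_cells")
  }
  frac <- mn_cells / total_cells
  list(fraction = frac, per_1000 = 1000 * frac)
}

#' Normalize raw expression to folds of control
#'
#' @param values raw per-sample measurements.
#' @param control the control-group value (> 0), e.g. its mean.
#' @return values divided by `control`.
#' @export
fold_of_control <- function(values, control) {
  if (!is.finite(control) || control <= 0) stop("control value must be > 0")
  values / control
}
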