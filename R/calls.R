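#' Intensity-dependent regulation-calling criteria
#'
#' A step-wise rule set: the control-side intensity of a gene picks an
#' intensity band, and the band sets the fold-change cut-off that the
#' treated/control ratio must exceed (up) or fall below (down). Low-intensity
#' bands use stricter cut-offs because ratios of dim signals are noisier.
#'
#' `up_rules` and `down_rules` are data frames with columns `intensity_floor`
#' (lower edge of the band; bands run from one floor to the next, the last
#' to infinity) and `min_ratio` / `max_ratio`. Floors must be distinct and
#' include the full intensity range from 0.
#'
#' @param up_rules,down_rules band tables as described above.
#' @return A `call_criteria` object.
#' @export
call_criteria <- function(up_rules, down_rules) {
  check_rules <- function(rules, col, up) {
    if (!all(c("intensity_floor", col) %in% names(rules))) {
      stop("rules need columns intensity_floor and ", col)
    }
    if (anyDuplicated(rules$intensity_floor)) {
      stop("overlapping bands: duplicated intensity_floor")
    }
    rules <- rules[order(rules$intensity_floor), , drop = FALSE]
    if (rules$intensity_floor[1L] > 0) {
      stop("bands must cover intensities down to 0")
    }
    if (up && any(rules[[col]] <= 1)) stop("up-call min_ratio must be > 1")
    if (!up && any(rules[[col]] >= 1)) stop("down-call max_ratio must be < 1")
    rules
  }
  structure(
    list(up_rules = check_rules(as.data.frame(up_rules), "min_ratio", TRUE),
         down_rules = check_rules(as.data.frame(down_rules), "max_ratio", FALSE)),
    class = "call_criteria"
  )
}

#' Default step-wise calling criteria
#'
#' Two bands on the per-chip-normalized control intensity: dim genes
#' (control intensity below 0.5, i.e. below half the chip median) need a
#' 3-fold change, brighter genes a 2-fold change; down-calls mirror the
#' up-calls reciprocally.
#'
#' @return A `call_criteria` object.
#' @export
default_call_criteria <- function() {
  call_criteria(
    up_rules = data.frame(intensity_floor = c(0, 0.5), min_ratio = c(3, 2)),
    down_rules = data.frame(intensity_floor = c(0, 0.5), max_ratio = c(1 / 3, 0.5))
  )
}

#' Assign up/down/none regulation calls
#'
#' Each gene x condition cell is assigned `up` when its ratio meets the
#' band's `min_ratio`, `down` when it falls to the band's `max_ratio`, else
#' `none`; the band is chosen by the cell's control-side intensity. The
#' assignment is deterministic and idempotent.
#'
#' @param calls a `call_matrix` from [compute_ratios()].
#' @param criteria a [call_criteria()]; default [default_call_criteria()].
#' @return The `call_matrix` with its `call` entries filled in.
#' @export
call_regulation <- function(calls, criteria = default_call_criteria()) {
  if (!inherits(criteria, "call_criteria")) stop("`criteria` must be call_criteria")
  band_cut <- function(rules, thr_col) {
    floors <- rules$intensity_floor
    idx <- findInterval(calls$control_intensity, floors)
    matrix(rules[[thr_col]][idx], nrow(calls$ratio), ncol(calls$ratio))
  }
  up_thr <- band_cut(criteria$up_rules, "min_ratio")
  dn_thr <- band_cut(criteria$down_rules, "max_ratio")
  out <- matrix("none", nrow(calls$ratio), ncol(calls$ratio),
                dimnames = dimnames(calls$ratio))
  out[calls$ratio >= up_thr] <- "up"
  out[calls$ratio <= dn_thr] <- "down"
  calls$call <- out
  calls
}

#' Read / write calling criteria as YAML
#'
#' @param criteria a `call_criteria` object.
#' @param path file path.
#' @return `write_call_criteria` returns `path` invisibly;
#'   `read_call_criteria` returns a `call_criteria`.
#' @export
write_call_criteria <- function(criteria, path) {
  yaml::write_yaml(list(up_rules = as.list(criteria$up_rules),
                        down_rules = as.list(criteria$down_rules)), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname write_call_criteria
#' @export
read_call_criteria <- function(path) {
  y <- yaml::read_yaml(path)
  call_criteria(up_rules = as.data.frame(y$up_rules),
                down_rules = as.data.frame(y$down_rules))
}
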