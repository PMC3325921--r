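#' Infer monotone score-bin tables from (value, score) examples
#'
#' The published top-20 table prints, for each parameter, both the raw value
#' and the 0-5 score it was binned into, but not the bin boundaries
#' themselves. This function reconstructs, per parameter, a piecewise-constant
#' monotone step function consistent with every supplied (value, score) pair:
#' interval boundaries are placed at the midpoint between the closest
#' observed values carrying different scores, the two outer intervals extend
#' to +/-Inf, and score levels never observed for a parameter simply have no
#' interval. The direction (whether larger values score higher or lower) is
#' inferred from the pairs.
#'
#' @param pairs data frame with columns `parameter`, `value`, `score`.
#' @return A named list of `score_bin_table` data frames (columns `score`,
#'   `lower`, `upper`; intervals are `[lower, upper)`), with the inferred
#'   `direction` (`"higher"`, `"lower"` or `"flat"`) as an attribute.
#'   Errors with an infeasibility report naming the offending pairs when no
#'   monotone step function fits.
#' @export
infer_bin_tables <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("parameter", "value", "score") %in% names(pairs)))
  if (any(pairs$score < 0 | pairs$score > 5 | pairs$score != round(pairs$score))) {
    stop("scores must be integers in 0..5")
  }
  out <- lapply(split(pairs, pairs$parameter), infer_one_bin_table)
  out[unique(pairs$parameter)]
}

infer_one_bin_table <- function(p) {
  param <- p$parameter[1L]
  agg <- unique(p[, c("value", "score")])
  clash <- agg$value[duplicated(agg$value)]
  if (length(clash) > 0L) {
    bad <- agg[agg$value %in% clash, ]
    stop("infeasible bin table for '", param, "': same value, different score: ",
         paste(sprintf("(%g -> %d)", bad$value, bad$score), collapse = ", "))
  }
  agg <- agg[order(agg$value), , drop = FALSE]
  d <- diff(agg$score)
  if (all(d >= 0)) {
    direction <- if (any(d > 0)) "higher" else "flat"
  } else if (all(d <= 0)) {
    direction <- "lower"
  } else {
    i <- which(sign(d) != sign(d[which(d != 0)[1L]]) & d != 0)[1L]
    stop("infeasible bin table for '", param, "': scores are not monotone in ",
         "the value (e.g. ", sprintf("%g -> %d but %g -> %d", agg$value[i],
         agg$score[i], agg$value[i + 1L], agg$score[i + 1L]), ")")
  }
  change <- which(d != 0)
  cuts <- (agg$value[change] + agg$value[change + 1L]) / 2
  runs_score <- agg$score[c(change, nrow(agg))]
  tab <- data.frame(score = as.integer(runs_score),
                    lower = c(-Inf, cuts), upper = c(cuts, Inf))
  structure(tab, class = c("score_bin_table", "data.frame"),
            parameter = param, direction = direction)
}

#' Bin a raw parameter value into its 0-5 component score
#'
#' Piecewise-constant lookup in a `score_bin_table`: the score of the
#' `[lower, upper)` interval containing the value. Vectorized over `value`.
#'
#' @param value numeric value(s) of the parameter.
#' @param table a `score_bin_table` (one element of [infer_bin_tables()] /
#'   [default_bin_tables()]).
#' @return integer score(s) in 0..5.
#' @export
bin_score <- function(value, table) {
  if (any(!is.finite(value))) stop("value outside the bin table's domain")
  idx <- findInterval(value, c(table$lower[1L], table$upper))
  if (any(idx < 1L | idx > nrow(table))) {
    stop("value outside the bin table's domain")
  }
  as.integer(table$score[idx])
}

# memoized defaults inferred from the packaged fixture
.gtxscore_cache <- new.env(parent = emptyenv())

#' Default score-bin tables
#'
#' Inferred once per session from the packaged top-20 fixture via
#' [infer_bin_tables()]; they reproduce every printed (value, score)
#' assignment of that table. Override by supplying your own tables (e.g.
#' from [read_bin_tables()]) wherever a `bin_tables` argument is accepted.
#'
#' @return Named list of eight `score_bin_table` objects, one per parameter
#'   of [score_parameters()].
#' @export
default_bin_tables <- function() {
  if (is.null(.gtxscore_cache$bins)) {
    .gtxscore_cache$bins <- infer_bin_tables(fixture_score_pairs(table2_fixture()))
  }
  .gtxscore_cache$bins
}

#' Long (parameter, value, score) pairs from a fixture-style score table
#'
#' @param fixture a data frame in the layout of [table2_fixture()].
#' @return data frame with columns `parameter`, `value`, `score` (8 rows per
#'   input gene).
#' @export
fixture_score_pairs <- function(fixture) {
  do.call(rbind, lapply(score_parameters(), function(par) {
    data.frame(parameter = par, value = fixture[[par]],
               score = fixture[[paste0(par, "_score")]],
               stringsAsFactors = FALSE)
  }))
}

#' Read / write score-bin tables as YAML
#'
#' @param bins named list of `score_bin_table`s.
#' @param path file path.
#' @return `write_bin_tables` returns `path` invisibly; `read_bin_tables`
#'   returns the named list.
#' @export
write_bin_tables <- function(bins, path) {
  yaml::write_yaml(lapply(bins, function(b) {
    list(direction = attr(b, "direction"),
         intervals = lapply(seq_len(nrow(b)), function(i) {
           list(score = b$score[i], lower = b$lower[i], upper = b$upper[i])
         }))
  }), path, precision = 15L)
  invisible(path)
}

#' @rdname write_bin_tables
#' @export
read_bin_tables <- function(path) {
  y <- yaml::read_yaml(path)
  out <- lapply(names(y), function(nm) {
    iv <- y[[nm]]$intervals
    tab <- data.frame(score = as.integer(vapply(iv, `[[`, numeric(1), "score")),
                      lower = vapply(iv, function(r) as.numeric(r$lower), numeric(1)),
                      upper = vapply(iv, function(r) as.numeric(r$upper), numeric(1)))
    structure(tab, class = c("score_bin_table", "data.frame"),
              parameter = nm, direction = y[[nm]]$direction)
  })
  names(out) <- names(y)
  out
}
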