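# Independent brute-force oracles and small random-instance generators.
# Everything here is deliberately written as plain loops over cells so it
# shares no code path with the vectorized package implementation.

# random per-gene call row over a design-like condition table
random_call_row <- function(n_gtx = 6L, n_ngtx = 3L, n_dup = 2L) {
  n <- n_gtx + n_ngtx
  class <- c(rep("GTX", n_gtx), rep("NGTX", n_ngtx))
  chemical <- c(paste0("G", c(seq_len(n_gtx - n_dup), rep("dup", n_dup))),
                paste0("N", seq_len(n_ngtx)))
  weight <- ifelse(chemical == "Gdup", 0.5, 1)
  call <- sample(c("up", "down", "none"), n, replace = TRUE,
                 prob = c(0.35, 0.25, 0.4))
  ratio <- exp(stats::rnorm(n, 0, 1))
  ratio[call == "up"] <- 1 + exp(stats::rnorm(sum(call == "up"), 0.5, 0.5))
  ratio[call == "down"] <- 1 / (1 + exp(stats::rnorm(sum(call == "down"), 0.5, 0.5)))
  list(call = call, ratio = ratio, class = class, chemical = chemical,
       weight = weight)
}

# loop-based reference values for the call-derived parameters of one row
oracle_row_parameters <- function(row) {
  up_gtx <- 0L; up_all <- 0L; ratio_sum <- 0; wsum <- 0
  dn_gtx <- 0L; dn_ngtx <- 0L
  chems <- character(0)
  for (i in seq_along(row$call)) {
    if (row$call[i] == "up") {
      up_all <- up_all + 1L
      if (row$class[i] == "GTX") {
        up_gtx <- up_gtx + 1L
        ratio_sum <- ratio_sum + row$ratio[i]
        wsum <- wsum + row$weight[i]
        chems <- union(chems, row$chemical[i])
      }
    }
    if (row$call[i] == "down") {
      if (row$class[i] == "GTX") dn_gtx <- dn_gtx + 1L
      if (row$class[i] == "NGTX") dn_ngtx <- dn_ngtx + 1L
    }
  }
  list(
    specificity = if (up_all == 0) NA_real_ else up_gtx / up_all,
    ave_ratio = if (up_gtx == 0) NA_real_ else ratio_sum / up_gtx,
    positive_condition = wsum,
    positive_chemical = length(chems),
    reverse_change = dn_ngtx - dn_gtx
  )
}

# textbook Welch formula, scalar arithmetic only
oracle_welch_p <- function(a, b) {
  m1 <- sum(a) / length(a); m2 <- sum(b) / length(b)
  v1 <- sum((a - m1)^2) / (length(a) - 1)
  v2 <- sum((b - m2)^2) / (length(b) - 1)
  se2 <- v1 / length(a) + v2 / length(b)
  if (se2 == 0) return(if (m1 == m2) 1 else 0)
  df <- se2^2 / ((v1 / length(a))^2 / (length(a) - 1) +
                   (v2 / length(b))^2 / (length(b) - 1))
  2 * stats::pt(-abs((m1 - m2) / sqrt(se2)), df)
}

# brute-force UPGMA: cluster distances recomputed each step as the plain
# mean over all cross leaf pairs of the ORIGINAL distance matrix; returns
# the cophenetic matrix implied by the merges
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        s <- 0; cnt <- 0
        for (a in clusters[[i]]) for (b in clusters[[j]]) {
          s <- s + d[a, b]; cnt <- cnt + 1
        }
        dij <- s / cnt
        lo <- min(min(clusters[[i]]), min(clusters[[j]]))
        hi <- max(min(clusters[[i]]), min(clusters[[j]]))
        if (dij < best_d ||
            (dij == best_d && (lo < best$lo || (lo == best$lo && hi < best$hi)))) {
          best_d <- dij; best <- list(i = i, j = j, lo = lo, hi = hi)
        }
      }
    }
    for (a in clusters[[best$i]]) for (b in clusters[[best$j]]) {
      coph[a, b] <- best_d; coph[b, a] <- best_d
    }
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  coph
}

# cophenetic distances indexed in the original leaf order
cophenetic_matrix <- function(tree) {
  m <- as.matrix(stats::cophenetic(tree))
  ord <- if (is.null(tree$labels)) as.character(seq_len(nrow(m))) else tree$labels
  m[ord, ord]
}

# tiny dataset builder for hand-computed normalization checks
make_dataset <- function(intensities, samples) {
  structure(list(intensities = intensities, samples = samples, truth = NULL),
            class = "gtx_dataset")
}

small_design <- function(n_genes = 300L, n_control_animals = 4L) {
  study_design(n_genes = n_genes, n_control_animals = n_control_animals)
}
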