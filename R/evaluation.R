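#' Normalized absolute difference between two non-negative maps
#'
#' `sum(|projected - truth|) / sum(truth)`; lower is better. Normalizing by
#' the ground-truth mass makes structures of different sizes comparable.
#'
#' @param projected,truth equal-length non-negative vectors.
#' @return a scalar, >= 0.
#' @export
nad <- function(projected, truth) {
  if (length(projected) != length(truth))
    stop("maps must have equal length")
  s <- sum(truth)
  if (s <= 0) stop("undefined normalization: ground-truth map sums to 0")
  sum(abs(projected - truth)) / s
}

#' Dice coefficient of one label's support in two parcellations
#'
#' `2 |A intersect B| / (|A| + |B|)` for the voxel/vertex support sets of
#' `label`. A label absent from both parcellations has no defined overlap
#' and raises an error (never silently 1 or 0).
#'
#' @param a,b [Parcellation-class] objects (or plain integer label
#'   vectors) of equal length.
#' @param label the label id to compare.
#' @return a scalar in `[0, 1]`.
#' @export
dice <- function(a, b, label) {
  la <- if (is(a, "Parcellation")) a@labels else as.integer(a)
  lb <- if (is(b, "Parcellation")) b@labels else as.integer(b)
  if (length(la) != length(lb)) stop("parcellations must have equal length")
  A <- la == label
  B <- lb == label
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0L)
    stop("label ", label, " is absent from both parcellations; ",
         "Dice is undefined")
  2 * sum(A & B) / (na + nb)
}

#' Paired t-test on per-structure differences
#'
#' One-sample t-test of the differences against zero (equivalent to the
#' paired two-sample test), two-sided.
#'
#' @param diffs numeric vector of per-structure value differences, n >= 2.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
pairedT <- function(diffs) {
  if (length(diffs) < 2L) stop("need at least two differences")
  if (sd(diffs) == 0)
    stop("differences have zero variance; the paired t-test is undefined")
  ht <- t.test(diffs, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg step-up rejections
#'
#' Rejects the hypotheses whose BH-adjusted p-value is at most `q`
#' (equivalently: sort ascending, find the largest k with
#' `p_(k) <= k q / m`, reject ranks 1..k).
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q target false-discovery rate.
#' @return sorted integer indices (into `pvals`) of rejected hypotheses.
#' @export
bhFdr <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(integer(0))
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  sort(which(p.adjust(pvals, method = "BH") <= q))
}

#' Metric table over structures, approaches and replicates
#'
#' Plain data.frame with columns `structure`, `approach`, `replicate`,
#' `value`, carrying the metric name and cohort size as attributes.
#'
#' @param structure,approach,replicate,value column vectors.
#' @param metric metric name.
#' @param n cohort size (or other problem-size annotation).
#' @return data.frame of class `c("metricTable", "data.frame")`.
#' @export
metricTable <- function(structure, approach, replicate, value,
                        metric = "metric", n = NA_integer_) {
  stopifnot(all(is.finite(value)))
  out <- data.frame(structure = structure, approach = approach,
                    replicate = replicate, value = value,
                    stringsAsFactors = FALSE)
  attr(out, "metric") <- metric
  attr(out, "n") <- n
  class(out) <- c("metricTable", "data.frame")
  out
}

# Replicate-averaged per-structure values for one approach.
replicateAverage <- function(tbl, approach) {
  sub <- tbl[tbl$approach == approach, , drop = FALSE]
  tapply(sub$value, sub$structure, mean)
}

#' Compare mapping approaches on a metric table
#'
#' Per-structure values are averaged across replicates (the two phantom
#' hemispheres play the role of the replicate), then every pair of
#' approaches is submitted to a paired t-test across structures and the
#' pair set is corrected with Benjamini-Hochberg FDR.
#'
#' A self-comparison (all differences zero) is flagged `degenerate` and
#' never significant.
#'
#' @param tbl a [metricTable()] data.frame.
#' @param q false-discovery rate for the pairwise tests.
#' @param higherBetter direction of the metric (TRUE for Dice, FALSE for
#'   normalized absolute difference).
#' @return list with `means` (named mean metric per approach), `tests`
#'   (one row per approach pair: t, df, p, adjusted significance flag,
#'   winner), and `q`.
#' @export
compareApproaches <- function(tbl, q = 0.05, higherBetter = FALSE) {
  apps <- unique(tbl$approach)
  if (length(apps) < 2L) stop("need at least two approaches")
  perStruct <- lapply(apps, function(a) replicateAverage(tbl, a))
  names(perStruct) <- apps
  structs <- Reduce(intersect, lapply(perStruct, names))
  if (length(structs) < 2L) stop("need at least two common structures")
  means <- vapply(perStruct, function(v) mean(v[structs]), numeric(1))
  pairs <- t(combn(apps, 2))
  tests <- data.frame(a = pairs[, 1], b = pairs[, 2], t = NA_real_,
                      df = NA_real_, p = NA_real_, degenerate = FALSE,
                      winner = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tests))) {
    d <- perStruct[[tests$a[i]]][structs] - perStruct[[tests$b[i]]][structs]
    if (sd(d) == 0) {
      tests$degenerate[i] <- TRUE
      tests$p[i] <- 1
      next
    }
    ht <- pairedT(d)
    tests$t[i] <- ht$t; tests$df[i] <- ht$df; tests$p[i] <- ht$p
    better <- if (higherBetter) mean(d) > 0 else mean(d) < 0
    tests$winner[i] <- if (better) tests$a[i] else tests$b[i]
  }
  rejected <- bhFdr(tests$p, q)
  tests$significant <- seq_len(nrow(tests)) %in% rejected & !tests$degenerate
  list(means = means, tests = tests, q = q)
}
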