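#' Pairwise Spearman correlation matrix of a feature table
#'
#' Midrank Spearman correlation for every feature pair, pairwise-complete
#' over declared-undefined (NaN) values. Constant columns have undefined
#' correlations (NA) and are flagged in the result.
#'
#' @param table data.frame with `subject_id` plus numeric feature columns,
#'   or a plain numeric matrix/data.frame of features.
#' @return A `correlation_matrix`: the matrix itself (diagonal 1) with
#'   attribute `constant` naming constant columns.
#' @export
spearman_matrix <- function(table) {
  m <- as.matrix(table[, setdiff(colnames(table), "subject_id"), drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) < 3L) stop("need >= 3 subjects for a correlation matrix")
  const <- colnames(m)[apply(m, 2L, function(x) {
    x <- x[is.finite(x)]
    length(x) == 0L || max(x) == min(x)
  })]
  rho <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  diag(rho) <- 1
  structure(rho, constant = const, class = c("correlation_matrix", "matrix"))
}

#' Prune redundant features by pairwise |rho|
#'
#' Greedy, deterministic redundancy elimination: repeatedly find the
#' still-retained pair with the largest `|rho| >= threshold` and drop the
#' member with the larger mean `|rho|` against all currently retained
#' features. Ties (in pair |rho| and in mean |rho|) are broken by
#' lexicographic feature name. Undefined correlations count as 0 in the
#' means; constant features are force-dropped first with their own reason.
#' After pruning, no retained pair has `|rho| >= threshold` (asserted).
#'
#' @param corr a [spearman_matrix()] (or any symmetric correlation matrix).
#' @param threshold redundancy cut-point on `|rho|` (default 0.85).
#' @return A `selection_report`: `kept` (ordered names), `dropped`
#'   (data.frame with feature, trigger partner, trigger |rho|, mean |rho| at
#'   drop time, reason), `threshold`.
#' @export
prune_redundant <- function(corr, threshold = 0.85) {
  rho <- abs(unclass(corr))
  feats <- colnames(rho)
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 0
  dropped <- data.frame(feature = character(0), trigger_pair = character(0),
                        trigger_rho = numeric(0), mean_abs_rho = numeric(0),
                        reason = character(0), stringsAsFactors = FALSE)
  active <- stats::setNames(rep(TRUE, length(feats)), feats)
  for (cf in sort(attr(corr, "constant"))) {
    active[cf] <- FALSE
    dropped <- rbind(dropped, data.frame(
      feature = cf, trigger_pair = NA_character_, trigger_rho = NA_real_,
      mean_abs_rho = NA_real_, reason = "constant", stringsAsFactors = FALSE))
  }
  repeat {
    act <- names(active)[active]
    if (length(act) < 2L) break
    sub <- rho[act, act, drop = FALSE]
    mx <- max(sub)
    if (mx < threshold) break
    hits <- which(sub == mx, arr.ind = TRUE)
    pairs <- t(apply(hits, 1L, function(h) sort(c(act[h[1]], act[h[2]]))))
    pairs <- unique(pairs)
    ord <- order(pairs[, 1], pairs[, 2])
    pair <- pairs[ord[1], ]
    # mean |rho| over the other currently retained features (exclude self)
    means <- vapply(pair, function(f)
      mean(sub[f, setdiff(act, f)]), numeric(1))
    victim <- if (means[1] > means[2]) pair[1]
      else if (means[2] > means[1]) pair[2]
      else sort(pair)[2]  # tie: drop the lexicographically later name
    other <- setdiff(pair, victim)
    active[victim] <- FALSE
    dropped <- rbind(dropped, data.frame(
      feature = victim, trigger_pair = other, trigger_rho = mx,
      mean_abs_rho = means[[victim]], reason = "redundant",
      stringsAsFactors = FALSE))
  }
  kept <- feats[active[feats]]
  if (length(kept) > 1L) {
    worst <- max(rho[kept, kept][upper.tri(matrix(0, length(kept), length(kept)))])
    stopifnot(worst < threshold)
  }
  structure(list(kept = kept, dropped = dropped, threshold = threshold),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> kept %d, dropped %d at |rho| >= %.2f\n",
              length(x$kept), nrow(x$dropped), x$threshold))
  invisible(x)
}
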