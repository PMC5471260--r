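#' Folded ROC AUC of a feature against a binary score
#'
#' The raw AUC is the midrank Mann-Whitney statistic
#' `(R1 - n1 (n1 + 1) / 2) / (n0 n1)` with class 1 ("presence") ranks `R1`;
#' ties receive half credit. The folded AUC maps it to `[0.5, 1]`:
#' `auc_raw` when `>= 0.5`, else `1 - auc_raw`, with the direction retained
#' separately (`proportional` when `auc_raw >= 0.5`, else `inverse`).
#' NaN feature values are excluded pairwise with their labels.
#'
#' @param values numeric feature vector.
#' @param labels 0/1 vector of the binary semantic score, same length.
#' @param semantic_name label used in error messages.
#' @return List: `auc_raw`, `auc_folded`, `direction`, `n0`, `n1`.
#' @export
folded_auc <- function(values, labels, semantic_name = "binary score") {
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n0 < 1L || n1 < 1L)
    stop("both classes must be present for '", semantic_name, "'")
  r <- rank(values)  # midranks
  auc_raw <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  direction <- if (auc_raw >= 0.5) "proportional" else "inverse"
  list(auc_raw = auc_raw,
       auc_folded = if (auc_raw >= 0.5) auc_raw else 1 - auc_raw,
       direction = direction, n0 = n0, n1 = n1)
}

#' Noether's test for AUC != 0.5
#'
#' Asymptotic normal test of departure of a ROC AUC from the chance value
#' 0.5, with null variance `(n0 + n1 + 1) / (12 n0 n1)`:
#' `z = (auc - 0.5) / sqrt(var)`, two-sided p-value `2 (1 - Phi(|z|))`.
#'
#' @param auc_raw raw (unfolded) AUC.
#' @param n0,n1 class sizes (both >= 1).
#' @return Two-sided p-value.
#' @export
noether_test <- function(auc_raw, n0, n1) {
  if (n0 < 1 || n1 < 1) stop("degenerate class sizes")
  z <- (auc_raw - 0.5) / sqrt((n0 + n1 + 1) / (12 * n0 * n1))
  2 * stats::pnorm(-abs(z))
}

#' Association of a feature with an ordinal (categorical) score
#'
#' Strength and direction via the midrank Spearman correlation of the
#' feature with the score; significance via the tie-corrected
#' Kruskal-Wallis test across score groups (chi-square, groups - 1 df).
#' NaN feature values are excluded pairwise.
#'
#' @param values numeric feature vector.
#' @param scores integer ordinal scores, same length.
#' @return List: `rho`, `kw_statistic`, `p`, `n`, `groups`.
#' @export
categorical_association <- function(values, scores) {
  ok <- is.finite(values) & !is.na(scores)
  values <- values[ok]; scores <- scores[ok]
  g <- unique(scores)
  if (length(g) < 2L) stop("need >= 2 distinct score groups")
  rho <- suppressWarnings(stats::cor(values, scores, method = "spearman"))
  kw <- stats::kruskal.test(values, factor(scores))
  list(rho = rho, kw_statistic = unname(kw$statistic), p = kw$p.value,
       n = length(values), groups = length(g))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; NaN/NA p-values are excluded
#' from the family and returned as NA.
#'
#' @param pvalues numeric vector in `[0, 1]` (NA/NaN allowed).
#' @return q-values, monotone in p, capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Interpretation bins for association strength
#'
#' Folded AUC: 0.5 = random; (0.5, 0.7] weak; (0.7, 0.9] moderate;
#' (0.9, 1] excellent. Spearman |rho|: <= 0.5 weak; (0.5, 0.7] moderate;
#' (0.7, 0.9] high; > 0.9 excellent.
#'
#' @param kind `"auc"` or `"rho"`.
#' @param value folded AUC in `[0.5, 1]`, or rho in `[-1, 1]`.
#' @return Strength label.
#' @export
classify_strength <- function(kind = c("auc", "rho"), value) {
  kind <- match.arg(kind)
  if (is.na(value)) return(NA_character_)
  if (kind == "auc") {
    if (value < 0.5 || value > 1) stop("folded AUC must lie in [0.5, 1]")
    if (value == 0.5) "random"
    else if (value <= 0.7) "weak"
    else if (value <= 0.9) "moderate"
    else "excellent"
  } else {
    if (value < -1 || value > 1) stop("rho must lie in [-1, 1]")
    v <- abs(value)
    if (v <= 0.5) "weak"
    else if (v <= 0.7) "moderate"
    else if (v <= 0.9) "high"
    else "excellent"
  }
}

#' Build the full semantic-radiomic association report
#'
#' Scores every (radiomic feature, semantic feature) pair: folded AUC with
#' Noether's test for the 3 binary semantic features, Spearman rho with the
#' Kruskal-Wallis test for the 6 categorical ones. Benjamini-Hochberg
#' adjustment is applied within each semantic feature's family of tests
#' (one semantic column = one family); a pair is significant when
#' `q <= alpha`. Binary columns with a single observed class are skipped
#' with a warning; pairs with fewer than `min_n` usable observations are
#' reported as not evaluated (NA statistics).
#'
#' @param features feature table (data.frame with `subject_id` + numeric
#'   columns), e.g. from [extract_feature_table()], possibly pruned.
#' @param cohort validated semantic score table with matching subjects.
#' @param alpha significance threshold on q (default 0.05).
#' @param min_n minimum usable observations per test (default 10).
#' @return An `association_report` data.frame in long format: columns
#'   `radiomic`, `semantic`, `statistic_type` ("auc"/"rho"), `estimate`
#'   (folded AUC or rho), `direction`, `p`, `q`, `strength`, `significant`,
#'   `n_used`; attribute `alpha`.
#' @export
build_report <- function(features, cohort, alpha = 0.05, min_n = 10L) {
  cohort <- validate_semantic_scores(as.data.frame(cohort))
  if (!("subject_id" %in% names(features)))
    stop("feature table must have a subject_id column")
  ids <- intersect(features$subject_id, cohort$subject_id)
  if (length(ids) != nrow(features) || length(ids) != nrow(cohort))
    stop("subject mismatch between feature table and cohort")
  fmat <- features[match(ids, features$subject_id),
                   setdiff(names(features), "subject_id"), drop = FALSE]
  sem <- cohort[match(ids, cohort$subject_id), , drop = FALSE]
  rows <- list()
  add_row <- function(...) rows[[length(rows) + 1L]] <<- list(...)
  for (sname in SEMANTIC_BINARY) {
    lab <- sem[[sname]]
    if (length(unique(lab)) < 2L) {
      warning("binary semantic feature '", sname,
              "' has a single class; skipped")
      next
    }
    for (fname in names(fmat)) {
      v <- fmat[[fname]]
      if (sum(is.finite(v)) < min_n) {
        add_row(radiomic = fname, semantic = sname, statistic_type = "auc",
                estimate = NA_real_, direction = NA_character_, p = NA_real_,
                n_used = sum(is.finite(v)))
        next
      }
      a <- folded_auc(v, lab, sname)
      add_row(radiomic = fname, semantic = sname, statistic_type = "auc",
              estimate = a$auc_folded, direction = a$direction,
              p = noether_test(a$auc_raw, a$n0, a$n1), n_used = a$n0 + a$n1)
    }
  }
  for (sname in SEMANTIC_CATEGORICAL) {
    sc <- sem[[sname]]
    if (length(unique(sc)) < 2L) {
      warning("categorical semantic feature '", sname,
              "' has a single observed score; skipped")
      next
    }
    for (fname in names(fmat)) {
      v <- fmat[[fname]]
      if (sum(is.finite(v)) < min_n) {
        add_row(radiomic = fname, semantic = sname, statistic_type = "rho",
                estimate = NA_real_, direction = NA_character_, p = NA_real_,
                n_used = sum(is.finite(v)))
        next
      }
      ca <- categorical_association(v, sc)
      add_row(radiomic = fname, semantic = sname, statistic_type = "rho",
              estimate = ca$rho,
              direction = if (is.na(ca$rho)) NA_character_
                          else if (ca$rho >= 0) "proportional" else "inverse",
              p = ca$p, n_used = ca$n)
    }
  }
  rep <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rep$q <- NA_real_
  for (sname in unique(rep$semantic)) {
    i <- rep$semantic == sname
    rep$q[i] <- bh_adjust(rep$p[i])
  }
  rep$strength <- mapply(function(type, est) {
    if (is.na(est)) NA_character_
    else classify_strength(ifelse(type == "auc", "auc", "rho"), est)
  }, rep$statistic_type, rep$estimate, USE.NAMES = FALSE)
  rep$significant <- !is.na(rep$q) & rep$q <= alpha
  rep <- rep[, c("radiomic", "semantic", "statistic_type", "estimate",
                 "direction", "p", "q", "strength", "significant", "n_used")]
  attr(rep, "alpha") <- alpha
  class(rep) <- c("association_report", "data.frame")
  rep
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("<association_report> %d radiomic x %d semantic tests (alpha = %g)\n",
              length(unique(x$radiomic)), length(unique(x$semantic)),
              attr(x, "alpha")))
  tab <- tapply(x$significant, x$semantic, sum)
  for (s in names(tab)) cat(sprintf("  %-18s %3d significant\n", s, tab[[s]]))
  invisible(x)
}

#' Per-semantic summary of an association report
#'
#' @param object an `association_report`.
#' @param ... unused.
#' @return data.frame: per semantic feature, the number of tested and
#'   significant radiomic features and the min/max estimate (folded AUC or
#'   |rho|) among the significant ones.
#' @export
summary.association_report <- function(object, ...) {
  out <- lapply(split(as.data.frame(object), object$semantic), function(d) {
    sig <- d[d$significant, ]
    est <- if (d$statistic_type[1] == "rho") abs(sig$estimate) else sig$estimate
    data.frame(semantic = d$semantic[1], statistic_type = d$statistic_type[1],
               n_tested = sum(!is.na(d$p)), n_significant = nrow(sig),
               min_estimate = if (nrow(sig)) min(est) else NA_real_,
               max_estimate = if (nrow(sig)) max(est) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
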