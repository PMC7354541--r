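# Spearman rank-correlation of texture features against fibrosis markers.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Ranks both vectors with average-rank tie handling and returns the Pearson
#' correlation of the ranks, with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom (the
#' usual approximation at the cohort sizes involved here, n <= ~30). When
#' `|r| = 1` the t statistic is unbounded; the p-value is then reported as
#' the permutation bound `2 / n!` (capped below at the smallest positive
#' double) and flagged `exact_bound`. Pairs with missing values are dropped
#' first (pairwise-complete). An exact permutation p-value is available for
#' n <= 10.
#'
#' @param x,y numeric vectors of equal length.
#' @param exact use exact permutation enumeration for the p-value
#'   (only allowed for pairwise-complete n <= 10).
#' @return A list: `r_s`, `p_value`, `n`, `flags`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", "eqctta_input_error")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    abort("need at least 3 pairwise-complete observations", "eqctta_input_error")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("zero variance: Spearman correlation undefined", "eqctta_input_error")
  }
  rx <- rank(x)
  ry <- rank(y)
  r_s <- stats::cor(rx, ry)
  flags <- character(0)
  if (exact) {
    if (n > 10L) {
      abort("exact permutation p-value limited to n <= 10", "eqctta_input_error")
    }
    perms <- permutations_of(n)
    robs <- abs(r_s)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      if (abs(stats::cor(rx, ry[perms[i, ]])) >= robs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
    flags <- "exact_permutation"
  } else if (abs(r_s) >= 1 - 1e-14) {
    p <- max(exp(log(2) - lfactorial(n)), .Machine$double.xmin)
    flags <- "exact_bound"
  } else {
    tstat <- r_s * sqrt((n - 2) / (1 - r_s^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r_s = r_s, p_value = p, n = n, flags = flags)
}

permutations_of <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Correlate every texture feature with every fibrosis marker
#'
#' Runs [spearman_cor()] for each feature column of a wide feature table
#' against each marker column, using pairwise-complete cases (equilibrium
#' phase missing for part of a cohort drops those patients from diff
#' features only). No multiple-testing correction is applied by design: the
#' filter scales are mutually dependent, so an independence-assuming
#' correction such as Bonferroni is not appropriate; an optional
#' Benjamini-Hochberg column can be added for sensitivity checks.
#'
#' @param features wide feature table from [build_feature_table()] (columns
#'   `region_phase_ssf<v>_<metric>` plus `patient_id`).
#' @param clinical data.frame with `patient_id` and marker columns.
#' @param markers marker column names to correlate against.
#' @param alpha significance level for the `significant` flag.
#' @param p_adjust add a Benjamini-Hochberg adjusted column `p_bh`?
#' @return A `correlation_table`: long data.frame with one row per
#'   (feature, marker) pair: `region`, `phase`, `ssf_mm`, `metric`,
#'   `marker`, `r_s`, `p_value`, `n`, `significant`.
#' @export
correlate_features <- function(features, clinical,
                               markers = c("cpa", "ecv", "elf", "ishak"),
                               alpha = 0.05, p_adjust = FALSE) {
  if (!is.data.frame(features) || !"patient_id" %in% names(features)) {
    abort("features must be a data.frame with a patient_id column",
          "eqctta_input_error")
  }
  markers <- intersect(markers, names(clinical))
  if (length(markers) == 0L) {
    abort("no requested marker column present in the clinical table",
          "eqctta_input_error")
  }
  feat_cols <- grep("^(whole_liver|segment7)_(pre|eq|diff)_ssf", names(features),
                    value = TRUE)
  if (length(feat_cols) == 0L) {
    abort("no feature columns found in the table", "eqctta_input_error")
  }
  merged <- merge(features[, c("patient_id", feat_cols), drop = FALSE],
                  clinical, by = "patient_id", sort = TRUE)
  rows <- vector("list", length(feat_cols) * length(markers))
  k <- 0L
  for (fc in feat_cols) {
    meta <- parse_feature_name(fc)
    for (mk in markers) {
      x <- merged[[fc]]
      y <- merged[[mk]]
      keep <- is.finite(x) & is.finite(y)
      if (sum(keep) < 3L) next
      if (stats::var(x[keep]) == 0 || stats::var(y[keep]) == 0) {
        message(sprintf("skipping constant pair: %s vs %s", fc, mk))
        next
      }
      res <- spearman_cor(x, y)
      k <- k + 1L
      rows[[k]] <- data.frame(
        region = meta$region, phase = meta$phase, ssf_mm = meta$ssf_mm,
        metric = meta$metric, marker = mk,
        r_s = res$r_s, p_value = res$p_value, n = res$n,
        significant = res$p_value <= alpha, stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    abort("no usable feature-marker pair (all constant or too few complete cases)",
          "eqctta_input_error")
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (isTRUE(p_adjust)) {
    out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  }
  class(out) <- c("correlation_table", "data.frame")
  out
}

parse_feature_name <- function(x) {
  m <- regmatches(x, regexec(
    "^(whole_liver|segment7)_(pre|eq|diff)_ssf([0-9.]+)_([a-z]+)$", x))[[1]]
  if (length(m) != 5L) {
    abort(sprintf("malformed feature column name: %s", x), "eqctta_input_error")
  }
  list(region = m[2], phase = m[3], ssf_mm = as.numeric(m[4]), metric = m[5])
}

#' Wide layout of a correlation table
#'
#' Reshapes the long correlation results into the report layout used for
#' texture-analysis summaries: one row per (SSF, marker, quantity), one
#' column per (region, phase, metric) combination, values being r_s (and a
#' companion p row).
#'
#' @param ct a `correlation_table` from [correlate_features()].
#' @param metrics metrics to include as columns.
#' @param marker_rows markers to include as row blocks.
#' @return A data.frame with `ssf_mm`, `marker`, `quantity` (`r_s` / `p`) and
#'   one column per region_phase_metric.
#' @export
correlation_wide <- function(ct, metrics = c("sd", "entropy", "mpp"),
                             marker_rows = c("cpa", "ecv")) {
  stopifnot(inherits(ct, "data.frame"))
  sub <- ct[ct$metric %in% metrics & ct$marker %in% marker_rows, , drop = FALSE]
  if (nrow(sub) == 0L) {
    abort("no rows match the requested metrics/markers", "eqctta_input_error")
  }
  sub$colkey <- paste(sub$region, sub$phase, sub$metric, sep = "_")
  colkeys <- unique(sub$colkey[order(sub$region, sub$phase,
                                     match(sub$metric, texture_metric_names))])
  ssfs <- sort(unique(sub$ssf_mm), decreasing = TRUE)
  out <- list()
  for (s in ssfs) {
    for (mk in marker_rows) {
      blk <- sub[sub$ssf_mm == s & sub$marker == mk, , drop = FALSE]
      if (nrow(blk) == 0L) next
      rrow <- data.frame(ssf_mm = s, marker = mk, quantity = "r_s",
                         stringsAsFactors = FALSE)
      prow <- data.frame(ssf_mm = s, marker = mk, quantity = "p",
                         stringsAsFactors = FALSE)
      for (ck in colkeys) {
        hit <- blk[blk$colkey == ck, , drop = FALSE]
        rrow[[ck]] <- if (nrow(hit)) hit$r_s[1] else NA_real_
        prow[[ck]] <- if (nrow(hit)) hit$p_value[1] else NA_real_
      }
      out[[length(out) + 1L]] <- rrow
      out[[length(out) + 1L]] <- prow
    }
  }
  do.call(rbind, out)
}
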