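## Per-site cross-condition testing, step-up FDR correction, significance
## tiers and the site x condition summary matrix.

#' One-way ANOVA for one lysine site
#'
#' Classical (equal-variance) one-way ANOVA of measurement-level
#' accessibilities across conditions, with F on (k-1, N-k) degrees of
#' freedom. Sites with fewer than two groups, any group smaller than two
#' measurements, or zero variance everywhere are not testable; a site with
#' zero within-group variance but unequal means gets an infinite F and the
#' smallest representable p, flagged as degenerate. When the largest and
#' smallest group variances differ by more than fourfold a heteroscedasticity
#' note is attached (the test itself stays the classical ANOVA).
#'
#' @param values numeric accessibilities.
#' @param groups condition labels, same length as `values`.
#' @return List with `F`, `p`, `df1`, `df2`, `status` (`"ok"`,
#'   `"degenerate"` or `"skipped"`) and `note`.
#' @export
#' @examples
#' siteAnova(c(1, 2, 3, 4), c("a", "a", "b", "b"))$F  # 8
siteAnova <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  counts <- table(groups)
  if (length(counts) < 2)
    return(list(F = NA_real_, p = NA_real_, df1 = NA, df2 = NA,
                status = "skipped", note = "fewer than 2 conditions"))
  if (any(counts < 2))
    return(list(F = NA_real_, p = NA_real_, df1 = NA, df2 = NA,
                status = "skipped",
                note = "a condition has fewer than 2 measurements"))
  k <- length(counts); n <- length(values)
  gm <- tapply(values, groups, mean)
  gv <- tapply(values, groups, stats::var)
  ssw <- sum((counts - 1) * gv)
  ssb <- sum(counts * (gm - mean(values))^2)
  note <- ""
  if (min(gv) > 0 && max(gv) / min(gv) > 4)
    note <- "heteroscedastic: group variance ratio > 4"
  if (ssw <= .Machine$double.eps * n * max(1, mean(values)^2)) {
    if (ssb <= .Machine$double.eps * n * max(1, mean(values)^2))
      return(list(F = NA_real_, p = NA_real_, df1 = k - 1, df2 = n - k,
                  status = "skipped", note = "zero variance everywhere"))
    return(list(F = Inf, p = .Machine$double.xmin, df1 = k - 1, df2 = n - k,
                status = "degenerate",
                note = "zero within-group variance with unequal means"))
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  list(F = f, p = p, df1 = k - 1, df2 = n - k, status = "ok", note = note)
}

## plain BH step-up adjustment (cumulative-minimum enforced), input order
## restored by the callers
.stepUpAdjust <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Step-up FDR adjustment (BH and two-stage BKY)
#'
#' `method = "BH"` is the classical Benjamini-Hochberg step-up with
#' cumulative-minimum enforcement. `method = "BKY"` is the two-stage
#' sharpened procedure: stage one runs BH at level `alpha / (1 + alpha)` to
#' estimate the number of true nulls `m0`, stage two re-runs the step-up at
#' the sharpened level, giving per-entry
#' `q = BH(p) * (1 + alpha) * m0 / m` (clipped at 1). Because of the
#' sharpening, BKY q-values can undercut BH q-values. Input order is
#' preserved.
#'
#' @param p numeric vector of raw p-values in (0, 1\].
#' @param method `"BH"` or `"BKY"`.
#' @param alpha target FDR level of the two-stage procedure (default 0.05).
#' @return Numeric vector of q-values in (0, 1\], same order as `p`.
#' @export
#' @examples
#' adjustPValues(c(0.01, 0.02, 0.03), "BH")  # all 0.03
adjustPValues <- function(p, method = c("BH", "BKY"), alpha = 0.05) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  q <- .stepUpAdjust(p)
  if (method == "BH") return(q)
  m <- length(p)
  r1 <- sum(q <= alpha / (1 + alpha))
  m0 <- m - r1
  if (m0 == 0) return(q)  # every hypothesis rejected at stage one
  pmin(1, q * (1 + alpha) * m0 / m)
}

#' Significance tier from a q-value
#'
#' Default cutoffs: `"****"` for q <= 1e-4, `"***"` for q <= 2e-4,
#' otherwise `"ns"`. Cutoffs are configurable and must be increasing.
#'
#' @param q numeric q-values in (0, 1\].
#' @param cutoffs named numeric vector of inclusive upper bounds per tier,
#'   in increasing order.
#' @return Character vector of tiers.
#' @export
#' @examples
#' significanceTier(c(5e-5, 1.5e-4, 0.01))
significanceTier <- function(q, cutoffs = c("****" = 1e-4, "***" = 2e-4)) {
  if (is.unsorted(cutoffs))
    stop("tier cutoffs must be increasing")
  out <- rep("ns", length(q))
  for (i in rev(seq_along(cutoffs)))
    out[q <= cutoffs[i]] <- names(cutoffs)[i]
  out
}

#' Cross-condition comparison for every site
#'
#' Runs the per-site one-way ANOVA over measurement-level accessibilities
#' grouped by condition, adjusts the resulting p-values for multiplicity
#' (family: all testable sites in this run), and assigns significance tiers.
#'
#' @param x a [CPPMeasurements-class] of retained measurements spanning at
#'   least two conditions.
#' @param method FDR method, `"BH"` or `"BKY"`.
#' @param alpha BKY target level.
#' @param cutoffs tier cutoffs, see [significanceTier()].
#' @return data.frame with one row per site: `protein`, `residue`, `label`,
#'   `conditions`, `F_statistic`, `p_value`, `q_value`, `tier`, `status`,
#'   `note`. Untestable sites carry NA statistics and a reason.
#' @export
compareConditions <- function(x, method = c("BH", "BKY"), alpha = 0.05,
                              cutoffs = c("****" = 1e-4, "***" = 2e-4)) {
  method <- match.arg(method)
  stopifnot(is(x, "CPPMeasurements"))
  m <- measurements(x)
  m$accessibility <- measurementAccessibility(m$light_area, m$heavy_area,
                                              orientation(x))
  key <- interaction(m$protein, m$residue, drop = TRUE)
  groups <- split(m, key)
  rows <- lapply(groups, function(g) {
    a <- siteAnova(g$accessibility, g$condition)
    data.frame(
      protein = g$protein[1], residue = g$residue[1],
      label = paste0("K", g$residue[1]),
      conditions = paste(sort(unique(g$condition)), collapse = ";"),
      F_statistic = a$F, p_value = a$p, status = a$status, note = a$note,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$protein, out$residue), , drop = FALSE]
  out$q_value <- NA_real_
  testable <- out$status %in% c("ok", "degenerate")
  if (any(testable))
    out$q_value[testable] <- adjustPValues(out$p_value[testable], method,
                                           alpha)
  out$tier <- ifelse(is.na(out$q_value), "ns",
                     significanceTier(pmax(out$q_value,
                                           .Machine$double.xmin), cutoffs))
  out
}

#' Long-format site x condition accessibility matrix
#'
#' Expands one or more site tables to the full site x condition grid, one
#' row per cell, flagging missing cells explicitly rather than imputing
#' them. This is the record layout a heatmap rendering consumes.
#'
#' @param siteTable data.frame from [aggregateSites()] (possibly several
#'   conditions row-bound together).
#' @param conditions optional character vector fixing the condition order;
#'   defaults to the conditions present.
#' @return data.frame with `protein`, `residue`, `label`, `condition`,
#'   `mean_accessibility`, `sem`, `missing`.
#' @export
conditionMatrix <- function(siteTable, conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(siteTable$condition)
  sites <- unique(siteTable[, c("protein", "residue", "label"), drop = FALSE])
  grid <- merge(sites, data.frame(condition = conditions), by = NULL)
  out <- merge(grid,
               siteTable[, c("protein", "residue", "condition",
                             "mean_accessibility", "sem")],
               by = c("protein", "residue", "condition"), all.x = TRUE)
  out$missing <- is.na(out$mean_accessibility)
  out <- out[order(out$protein, out$residue,
                   match(out$condition, conditions)), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("protein", "residue", "label", "condition",
          "mean_accessibility", "sem", "missing")]
}
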