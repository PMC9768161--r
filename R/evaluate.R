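# Evaluation of predictions against measured organ fluxes.
#
# Predicted structural fluxes are unitless and nonnegative; measured exchange
# fluxes are signed rates.  Comparison is by Pearson correlation across
# metabolites, which is invariant under positive affine rescaling of either
# vector, so the unit mismatch is immaterial — but the sign convention must
# agree: predicted values of uptake exchange reactions are negated so both
# vectors are release-positive.

#' Align predicted and measured fluxes over shared metabolites
#'
#' Uses the model's exchange map (exchange reaction id -> measured metabolite
#' name) to pair each mapped metabolite's predicted structural flux with its
#' measured exchange flux.  A mapped exchange reaction that consumes an
#' external metabolite is an uptake reaction, so its (nonnegative) structural
#' flux is negated to match the release-positive measured convention.
#' Metabolites missing on either side are reported as exclusions, never
#' silently dropped.
#'
#' @param pred a `structural_flux_table`.
#' @param measured named numeric vector of measured exchange fluxes per
#'   metabolite (release-positive), e.g. group means from [group_summary()].
#' @param model the `metabolic_model` carrying the exchange map.
#' @return data.frame with columns `metabolite`, `predicted`, `measured`;
#'   attribute `excluded` names metabolites dropped from either side.  At
#'   least 3 shared metabolites are required.
#' @export
align_fluxes <- function(pred, measured, model) {
  if (length(model$exchange_map) == 0L)
    stop("model has no exchange map; attach one with apply_sidecar()",
         call. = FALSE)
  map <- model$exchange_map
  ext <- !model$is_internal
  rows <- list()
  excluded <- character(0)
  for (rid in names(map)) {
    met <- map[[rid]]
    pi <- match(rid, pred$reaction)
    if (is.na(pi) || !(met %in% names(measured))) {
      excluded <- c(excluded, met)
      next
    }
    col <- model$stoich_num[, rid]
    is_uptake <- any(ext & col < 0)
    rows[[length(rows) + 1L]] <- data.frame(
      metabolite = met,
      predicted = if (is_uptake) -pred$aStruF[pi] else pred$aStruF[pi],
      measured = unname(measured[met]),
      stringsAsFactors = FALSE)
  }
  if (length(rows) < 3L)
    stop("fewer than 3 shared metabolites between prediction and measurement (",
         length(rows), " found)", call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}

#' Pearson correlation between predicted and measured fluxes
#'
#' Standard product-moment correlation with a two-sided P value from the
#' t transform on n - 2 degrees of freedom.
#'
#' @param pairs data.frame with columns `predicted` and `measured` (as from
#'   [align_fluxes()]), or a numeric vector (then `y` must be given).
#' @param y optional second numeric vector.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_cor <- function(pairs, y = NULL) {
  if (is.null(y)) {
    x <- pairs$predicted
    y <- pairs$measured
  } else {
    x <- pairs
  }
  n <- length(x)
  if (n < 3L)
    stop("at least 3 pairs are required for a correlation", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate correlation: one of the vectors is constant",
         call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Stouffer's combined P value
#'
#' Each one-sided P value is transformed to a z score (signed by its effect
#' direction), the z scores are summed and divided by the square root of
#' their count, and the combined one-sided P is read off the normal
#' distribution.
#'
#' @param p one-sided P values in (0, 1); values at 0 or 1 are clamped to
#'   `eps` / `1 - eps` with a warning.
#' @param direction effect directions (+1 / -1), recycled; default all +1.
#' @param eps clamping bound (default 1e-15).
#' @return the combined one-sided P value.
#' @export
stouffer_combined_p <- function(p, direction = 1, eps = 1e-15) {
  if (any(p < 0 | p > 1))
    stop("P values must lie in [0, 1]", call. = FALSE)
  if (any(p <= 0 | p >= 1)) {
    warning("P value(s) at 0 or 1 clamped to [", eps, ", ", 1 - eps, "]")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  direction <- rep_len(sign(direction), length(p))
  if (any(direction == 0))
    stop("directions must be +1 or -1", call. = FALSE)
  z <- direction * stats::qnorm(1 - p)
  Z <- sum(z) / sqrt(length(z))
  stats::pnorm(Z, lower.tail = FALSE)
}

# Two-tier significance flag: "*" for P < 0.05, "**" for 0.05 <= P < 0.1.
.significance_flag <- function(p) {
  ifelse(p < 0.05, "*", ifelse(p < 0.1, "**", ""))
}

#' Rank evaluation scenarios by correlation
#'
#' Orders scenario reports by descending Pearson r (ties broken
#' alphabetically by scenario name for determinism) and attaches the
#' two-tier significance flag (`*` for P < 0.05, `**` for 0.05 <= P < 0.1)
#' and the rank position.
#'
#' @param reports data.frame with columns `scenario`, `n`, `r`, `p` (one row
#'   per evaluated scenario).
#' @return the same data.frame with `flag` and `rank` columns, ordered by
#'   rank.
#' @export
rank_scenarios <- function(reports) {
  stopifnot(is.data.frame(reports),
            all(c("scenario", "n", "r", "p") %in% names(reports)))
  if (nrow(reports) == 0L)
    stop("at least one report is required", call. = FALSE)
  ord <- order(-reports$r, reports$scenario)
  out <- reports[ord, , drop = FALSE]
  out$flag <- .significance_flag(out$p)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Evaluate a set of structural-flux predictions against measurements
#'
#' Convenience wrapper: aligns each reachable prediction with the measured
#' metabolite fluxes, computes the Pearson correlation, and ranks the
#' scenarios.  Unreachable or inalignable scenarios are reported with `NA`
#' correlation and excluded from the ranking.
#'
#' @param scans named list as returned by [objective_scan()] or
#'   [per_gene_predictions()].
#' @param measured named numeric vector of measured fluxes per metabolite.
#' @param model the `metabolic_model` carrying the exchange map.
#' @return list with `ranking` (ranked report data.frame) and `skipped`
#'   (data.frame of scenarios that could not be evaluated, with reasons).
#' @export
evaluate_scenarios <- function(scans, measured, model) {
  rows <- list()
  skipped <- list()
  for (nm in names(scans)) {
    sc <- scans[[nm]]
    if (is.null(sc$table)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        scenario = nm, reason = if (!is.null(sc$flag) && nzchar(sc$flag))
          sc$flag else "objective unreachable", stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch({
      pairs <- align_fluxes(sc$table, measured, model)
      pearson_cor(pairs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        scenario = nm, reason = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = nm, n = res$n, r = res$r, p = res$p, stringsAsFactors = FALSE)
  }
  ranking <- if (length(rows)) rank_scenarios(do.call(rbind, rows)) else
    data.frame(scenario = character(0), n = integer(0), r = numeric(0),
               p = numeric(0), flag = character(0), rank = integer(0),
               stringsAsFactors = FALSE)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(scenario = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  list(ranking = ranking, skipped = skipped)
}
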