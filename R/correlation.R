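#' Correlate thermal indices with per-sow heat dissipation
#'
#' For each index, evaluates the index at every sow's local air state and
#' regresses the sow's convective heat dissipation on the index value by
#' ordinary least squares (`Q = intercept + slope * index`). The coefficient
#' of determination R^2 = 1 - SS_res/SS_tot measures how well the index
#' predicts heat loss; indices carrying velocity information (ET, ETIS) are
#' expected to outrank the temperature-humidity-only indices, because the
#' convective coefficient is velocity-driven.
#'
#' @param sows A data.frame with columns `temp_c`, `rh_pct`, `vel_ms`,
#'   `q_conv_w` — typically the `sows` element of [simulate_barn()]. At
#'   least 3 rows.
#' @param ids Indices to evaluate (default: all twelve).
#' @param pm_mmhg Barometric pressure used for H, mmHg.
#' @return A data.frame of class `correlation_report`, one row per index:
#'   `index`, `r2`, `slope`, `intercept`, `n`, `rank`. An index with zero
#'   variance across sows has an undefined R^2, reported as `NA` and left
#'   unranked.
#' @examples
#' sim <- simulate_barn(seed = 1)
#' rep <- heat_dissipation_correlation(sim$sows)
#' rank_indices(rep)[1:2] # the velocity-aware indices lead
#' @export
heat_dissipation_correlation <- function(sows, ids = index_ids(),
                                         pm_mmhg = 760) {
  stopifnot(nrow(sows) >= 3,
            all(c("temp_c", "rh_pct", "vel_ms", "q_conv_w") %in%
                  names(sows)))
  ids <- match.arg(ids, index_ids(), several.ok = TRUE)
  rows <- lapply(ids, function(id) {
    x <- compute_index(id, sows$temp_c, sows$rh_pct, sows$vel_ms, pm_mmhg)
    if (stats::var(x) < .Machine$double.eps * max(1, mean(x)^2))
      return(data.frame(index = id, r2 = NA_real_, slope = NA_real_,
                        intercept = NA_real_, n = nrow(sows)))
    fit <- stats::lm(sows$q_conv_w ~ x)
    data.frame(index = id, r2 = summary(fit)$r.squared,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]), n = nrow(sows))
  })
  out <- do.call(rbind, rows)
  # rank by R^2 descending; ties (and only ties) fall back to canonical order
  ord <- order(-out$r2, match(out$index, index_ids()), na.last = TRUE)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out$rank[is.na(out$r2)] <- NA_integer_
  rownames(out) <- NULL
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Rank indices by coefficient of determination
#'
#' @param report A `correlation_report` from
#'   [heat_dissipation_correlation()].
#' @return Character vector of index identifiers sorted by R^2 descending;
#'   ties broken by the canonical order of [index_ids()]. Indices with
#'   undefined R^2 are omitted.
#' @export
rank_indices <- function(report) {
  stopifnot(inherits(report, "correlation_report"))
  kept <- report[!is.na(report$r2), ]
  kept$index[order(kept$rank)]
}
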