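#' Incremental cost-effectiveness ratio
#'
#' `ICER = (C_int - C_comp) / (E_int - E_comp)` with the usual dominance
#' conventions: the intervention is `"dominant"` when cheaper and more
#' effective, `"dominated"` when costlier and less effective. Division uses
#' the unrounded totals.
#'
#' @param intervention,comparator `arm_outcomes` from identical settings.
#' @param effect_measure `"qaly"` (default) or `"ly"`.
#' @return An `incremental_result` list: `comparator`, `delta_cost`,
#'   `delta_effect`, `icer` (NA when a dominance tag or undefined applies),
#'   `dominance` (`"dominant"`, `"dominated"`, or `NA`), `effect_measure`.
#' @examples
#' # a dominant intervention: cheaper and more effective
#' a <- structure(list(arm = "A", qaly_total = 1.2, ly_total = 1.5,
#'                     cost_total = 100), class = "arm_outcomes")
#' b <- structure(list(arm = "B", qaly_total = 1.0, ly_total = 1.3,
#'                     cost_total = 200), class = "arm_outcomes")
#' icer(a, b)$dominance
#' @export
icer <- function(intervention, comparator,
                 effect_measure = c("qaly", "ly")) {
  effect_measure <- match.arg(effect_measure)
  stopifnot(inherits(intervention, "arm_outcomes"),
            inherits(comparator, "arm_outcomes"))
  eff <- paste0(effect_measure, "_total")
  dc <- intervention$cost_total - comparator$cost_total
  de <- intervention[[eff]] - comparator[[eff]]
  dominance <- NA_character_
  ratio <- NA_real_
  if (de == 0) {
    # undefined ICER; report increments only
  } else if (dc <= 0 && de > 0) {
    dominance <- "dominant"
  } else if (dc >= 0 && de < 0) {
    dominance <- "dominated"
  } else {
    ratio <- dc / de
  }
  structure(list(comparator = comparator$arm, delta_cost = dc,
                 delta_effect = de, icer = ratio, dominance = dominance,
                 effect_measure = effect_measure),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  lbl <- if (!is.na(x$dominance)) x$dominance else
    if (is.na(x$icer)) "undefined (dE = 0)" else
      paste0("NT$", format(round(x$icer), big.mark = ","), "/",
             toupper(x$effect_measure))
  cat(sprintf("<incremental_result> vs %s: dC = %s, dE = %.4f %s, ICER %s\n",
              x$comparator, format(round(x$delta_cost), big.mark = ","),
              x$delta_effect, toupper(x$effect_measure), lbl))
  invisible(x)
}

#' Incremental net monetary benefit
#'
#' `INMB = WTP * (E_int - E_comp) - (C_int - C_comp)`. Positive INMB at a
#' willingness-to-pay threshold means the intervention is cost-effective at
#' that threshold; when the effect difference is positive, INMB crosses zero
#' exactly at `WTP = ICER`.
#'
#' @inheritParams icer
#' @param wtp Willingness-to-pay per effect unit, `>= 0`.
#' @return INMB in NT$.
#' @export
inmb <- function(intervention, comparator, wtp,
                 effect_measure = c("qaly", "ly")) {
  effect_measure <- match.arg(effect_measure)
  stopifnot(wtp >= 0)
  eff <- paste0(effect_measure, "_total")
  wtp * (intervention[[eff]] - comparator[[eff]]) -
    (intervention$cost_total - comparator$cost_total)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability of cost-effectiveness
#' is the fraction of PSA draws with positive incremental net monetary
#' benefit for the given comparison.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param wtp_grid Vector of WTP values; defaults to 0 to 6,000,000 NT$ in
#'   steps of 100,000 with the base threshold NT$2,928,570 inserted.
#' @param comparison Comparator arm name (one of `psa$comparators`), or
#'   `NULL` for all.
#' @return Data frame `wtp`, `comparator`, `p_ce`.
#' @export
ceac <- function(psa, wtp_grid = default_wtp_grid(), comparison = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  comps <- comparison %||% psa$comparators
  out <- do.call(rbind, lapply(comps, function(cm) {
    de <- psa$draws[[paste0("d_effect_", cm)]]
    dc <- psa$draws[[paste0("d_cost_", cm)]]
    p <- vapply(wtp_grid, function(w) mean(w * de - dc > 0), numeric(1))
    data.frame(wtp = wtp_grid, comparator = cm, p_ce = p)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname ceac
#' @export
default_wtp_grid <- function() {
  sort(unique(c(seq(0, 6e6, by = 1e5), 2928570)))
}

#' Expected value of perfect information (per person)
#'
#' `EVPI = E[max_s NMB_s] - max_s E[NMB_s]` over the PSA draws, computed
#' pairwise (intervention versus one comparator) for each comparison: the
#' per-person value of eliminating all parameter uncertainty in that
#' two-strategy decision.
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay per QALY.
#' @param comparison Comparator arm name, or `NULL` for all.
#' @return Data frame `comparator`, `evpi` (NT$/person, `>= 0`).
#' @export
evpi <- function(psa, wtp = psa$wtp, comparison = NULL) {
  stopifnot(inherits(psa, "psa_result"), wtp >= 0)
  comps <- comparison %||% psa$comparators
  out <- do.call(rbind, lapply(comps, function(cm) {
    data.frame(comparator = cm,
               evpi = evpi_from_nmb(cbind(
                 0, wtp * psa$draws[[paste0("d_effect_", cm)]] -
                   psa$draws[[paste0("d_cost_", cm)]])))
  }))
  rownames(out) <- NULL
  out
}

#' EVPI from a matrix of per-draw net monetary benefits
#'
#' @param nmb Numeric matrix, one row per PSA draw, one column per strategy.
#' @return `mean(rowMax) - max(colMeans)`, non-negative by Jensen.
#' @examples
#' evpi_from_nmb(rbind(c(10, 0), c(0, 5)))  # 2.5
#' @export
evpi_from_nmb <- function(nmb) {
  nmb <- as.matrix(nmb)
  stopifnot(nrow(nmb) >= 1, ncol(nmb) >= 2)
  mean(apply(nmb, 1, max)) - max(colMeans(nmb))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
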