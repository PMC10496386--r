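#' Parameter specification for sensitivity analyses
#'
#' One model parameter with its base value, deterministic (tornado) bounds
#' and probabilistic sampling distribution. Distribution descriptors:
#' * `normal(mean, sd)` — survival parameters; draws for strictly positive
#'   parameters are redrawn while `<= 0` (truncation, max 100 attempts).
#' * `uniform(lo, hi)` — pemigatinib medication cost, genetic testing fee,
#'   conversion factor.
#' * `gamma(mean, sd)` — other costs, **moment-matched**: shape
#'   `= mean^2/sd^2`, rate `= mean/sd^2`. The published table prints the
#'   gamma arguments as (mean, SD) — the first argument equals the base-case
#'   mean in every row — so the descriptor is interpreted on that scale.
#' * `beta(alpha, beta)` — utilities and the adverse-event disutility; the
#'   distribution means reproduce the base values (e.g.
#'   `4.7 / (4.7 + 1.5) = 0.758` for the progression-free utility 0.76).
#' * `fixed` — held at base in the PSA (adverse-event proportions and the
#'   intravenous-administration disutility have no published distribution).
#'
#' @param name Parameter name (must be one the configuration mapping knows;
#'   see [apply_params()]).
#' @param base Base-case value.
#' @param low,high Deterministic sensitivity bounds, `low <= base <= high`.
#' @param dist One of `"normal"`, `"uniform"`, `"gamma"`, `"beta"`, `"fixed"`.
#' @param args Numeric vector of the two distribution arguments (ignored for
#'   `"fixed"`).
#' @param positive If `TRUE`, normal draws are truncated to `> 0`.
#' @return A `param_spec` list.
#' @export
param_spec <- function(name, base, low, high,
                       dist = c("fixed", "normal", "uniform", "gamma", "beta"),
                       args = NULL, positive = TRUE) {
  dist <- match.arg(dist)
  args <- as.numeric(unlist(args))
  stopifnot(is.character(name), length(name) == 1,
            low <= base + 1e-12, base <= high + 1e-12)
  if (dist != "fixed") {
    if (length(args) != 2 || any(!is.finite(args))) {
      stop("distribution '", dist, "' for ", name,
           " requires two finite arguments", call. = FALSE)
    }
    if (dist %in% c("gamma", "beta") && any(args <= 0)) {
      stop("gamma/beta arguments must be positive for ", name, call. = FALSE)
    }
    if (dist == "uniform" && args[1] > args[2]) {
      stop("uniform bounds out of order for ", name, call. = FALSE)
    }
  }
  structure(list(name = name, base = base, low = low, high = high,
                 dist = dist, args = as.numeric(args),
                 positive = isTRUE(positive)),
            class = "param_spec")
}

validate_param_spec <- function(p) {
  do.call(param_spec, p[intersect(names(p), c("name", "base", "low", "high",
                                              "dist", "args", "positive"))])
}

# deterministic per-parameter substream seed: adding or reordering
# parameters never perturbs another parameter's draws
param_stream_seed <- function(master, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 1000000007
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647)
}

sample_one <- function(spec, n) {
  a <- spec$args
  switch(spec$dist,
    fixed = rep(spec$base, n),
    uniform = stats::runif(n, a[1], a[2]),
    gamma = stats::rgamma(n, shape = a[1]^2 / a[2]^2, rate = a[1] / a[2]^2),
    beta = stats::rbeta(n, a[1], a[2]),
    normal = {
      x <- stats::rnorm(n, a[1], a[2])
      if (spec$positive) {
        for (i in seq_len(100)) {
          bad <- x <= 0
          if (!any(bad)) break
          x[bad] <- stats::rnorm(sum(bad), a[1], a[2])
        }
        if (any(x <= 0)) stop("normal truncation failed for ", spec$name,
                              call. = FALSE)
      }
      x
    })
}

#' Sample parameter sets for probabilistic sensitivity analysis
#'
#' Draws `n` independent values per parameter from its PSA distribution.
#' Each parameter uses its own reproducible random substream derived from
#' the master seed and the parameter name.
#'
#' @param specs Named list of [param_spec()] objects.
#' @param n Number of draws.
#' @param seed Master seed (integer).
#' @return Data frame, one row per draw, one column per parameter.
#' @export
sample_params <- function(specs, n, seed) {
  stopifnot(n >= 1)
  out <- lapply(specs, function(sp) {
    set.seed(param_stream_seed(seed, sp$name))
    sample_one(sp, n)
  })
  names(out) <- vapply(specs, `[[`, character(1), "name")
  as.data.frame(out)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation over the configured parameter distributions
#' (1000 iterations by default): each draw rebuilds the model with the
#' sampled parameter set, runs all arms, and records per-arm discounted
#' totals and pairwise incremental cost and effect. Deterministic given the
#' seed.
#'
#' @param config An `analysis_config`.
#' @param n Number of draws.
#' @param seed Master seed; defaults to `config$seed`.
#' @return A `psa_result`: `draws` (data frame of sampled parameters,
#'   per-arm `cost_`/`qaly_`/`ly_` columns and `d_cost_`/`d_effect_`/
#'   `d_ly_` columns per comparator), `summary` (per-comparator mean
#'   increments, probability cost-effective at the configured WTP, EVPI),
#'   `wtp`, `comparators`, `n`, `seed`.
#' @examples
#' \donttest{
#' psa <- run_psa(default_config(), n = 100, seed = 42)
#' psa$summary
#' }
#' @export
run_psa <- function(config, n = 1000, seed = config$seed) {
  stopifnot(inherits(config, "analysis_config"), n >= 1)
  drawn <- sample_params(config$parameters, n, seed)
  int_key <- intervention_key(config)
  comps <- comparator_keys(config)
  arm_keys <- names(config$arms)

  per_arm <- matrix(NA_real_, n, 3 * length(arm_keys))
  colnames(per_arm) <- as.vector(outer(c("cost_", "qaly_", "ly_"), arm_keys,
                                       paste0))
  for (j in seq_len(n)) {
    cfg_j <- apply_params(config, drawn[j, , drop = FALSE])
    out_j <- run_model(cfg_j)
    for (k in arm_keys) {
      per_arm[j, paste0("cost_", k)] <- out_j[[k]]$cost_total
      per_arm[j, paste0("qaly_", k)] <- out_j[[k]]$qaly_total
      per_arm[j, paste0("ly_", k)] <- out_j[[k]]$ly_total
    }
  }
  draws <- cbind(draw = seq_len(n), drawn, as.data.frame(per_arm))
  for (cm in comps) {
    draws[[paste0("d_cost_", cm)]] <-
      draws[[paste0("cost_", int_key)]] - draws[[paste0("cost_", cm)]]
    draws[[paste0("d_effect_", cm)]] <-
      draws[[paste0("qaly_", int_key)]] - draws[[paste0("qaly_", cm)]]
    draws[[paste0("d_ly_", cm)]] <-
      draws[[paste0("ly_", int_key)]] - draws[[paste0("ly_", cm)]]
  }
  wtp <- config$settings$wtp_per_qaly
  res <- structure(list(draws = draws, wtp = wtp, comparators = comps,
                        intervention = int_key, n = n, seed = seed),
                   class = "psa_result")
  res$summary <- do.call(rbind, lapply(comps, function(cm) {
    de <- draws[[paste0("d_effect_", cm)]]
    dc <- draws[[paste0("d_cost_", cm)]]
    data.frame(comparator = config$arms[[cm]]$label,
               comparator_key = cm,
               mean_d_cost = mean(dc), mean_d_qaly = mean(de),
               p_ce = mean(wtp * de - dc > 0),
               mean_inmb = mean(wtp * de - dc),
               evpi = evpi_from_nmb(cbind(0, wtp * de - dc)))
  }))
  res
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %s), WTP NT$%s/QALY\n",
              x$n, x$seed, format(x$wtp, big.mark = ",")))
  s <- x$summary
  s$mean_d_cost <- round(s$mean_d_cost)
  s$mean_inmb <- round(s$mean_inmb)
  s$evpi <- round(s$evpi)
  print(s[c("comparator", "mean_d_cost", "mean_d_qaly", "p_ce",
            "mean_inmb", "evpi")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies each parameter to its low and high deterministic bound with all
#' others held at base, recording the chosen output (INMB at the configured
#' WTP by default, or the ICER) for the given comparison. Rows are sorted
#' by swing (`|high - low|`) descending — tornado order.
#'
#' @param config An `analysis_config`.
#' @param comparison Comparator arm key (default: the first comparator).
#' @param output `"inmb"` (default) or `"icer"`.
#' @param effect_measure `"qaly"` or `"ly"`.
#' @return Data frame `parameter`, `base`, `low`, `high`, `output_low`,
#'   `output_high`, `output_base`, `swing`.
#' @export
one_way_dsa <- function(config, comparison = comparator_keys(config)[1],
                        output = c("inmb", "icer"),
                        effect_measure = c("qaly", "ly")) {
  output <- match.arg(output)
  effect_measure <- match.arg(effect_measure)
  stopifnot(comparison %in% comparator_keys(config))
  int_key <- intervention_key(config)
  wtp <- config$settings$wtp_per_qaly

  eval_out <- function(cfg) {
    out <- run_model(cfg)
    if (output == "inmb") {
      inmb(out[[int_key]], out[[comparison]], wtp, effect_measure)
    } else {
      icer(out[[int_key]], out[[comparison]], effect_measure)$icer
    }
  }
  base_out <- eval_out(config)
  rows <- lapply(config$parameters, function(sp) {
    lo <- eval_out(apply_params(config, stats::setNames(sp$low, sp$name)))
    hi <- eval_out(apply_params(config, stats::setNames(sp$high, sp$name)))
    data.frame(parameter = sp$name, base = sp$base, low = sp$low,
               high = sp$high, output_low = lo, output_high = hi,
               output_base = base_out, swing = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), , drop = FALSE]
  rownames(out) <- NULL
  out
}
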