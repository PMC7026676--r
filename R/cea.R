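#' Incremental cost-effectiveness ratio
#'
#' `(cost_high - cost_low) / (effect_high - effect_low)`, the extra
#' dollars paid per extra unit of effect (life-year or QALY) when
#' moving from the less to the more effective strategy.
#'
#' @param cost_low,effect_low Cost and effect of the comparator.
#' @param cost_high,effect_high Cost and effect of the alternative.
#' @return Dollars per effect unit.
#' @examples
#' icer(15654, 6.96, 18791, 7.44)  # 6535.42 $/QALY
#' @export
icer <- function(cost_low, effect_low, cost_high, effect_high) {
  if (isTRUE(all.equal(effect_high, effect_low, tolerance = 0)) ||
      effect_high == effect_low)
    stop("ICER undefined: zero effect difference (report as dominance or equivalence)",
         call. = FALSE)
  (cost_high - cost_low) / (effect_high - effect_low)
}

#' Net monetary benefit
#'
#' `wtp * effect - cost`: the strategy's effect valued at the
#' willingness-to-pay threshold, net of its cost. The strategy with the
#' highest NMB at a threshold is the cost-effective choice there.
#'
#' @param cost Cost in dollars.
#' @param effect Effect in life-years or QALYs.
#' @param wtp Willingness-to-pay threshold in dollars per effect unit.
#' @return Dollars; vectorized over all arguments.
#' @export
nmb <- function(cost, effect, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * effect - cost
}

#' Average cost-effectiveness ratio
#'
#' @param cost Cost in dollars.
#' @param effect Effect (> 0).
#' @return `cost / effect`, dollars per effect unit.
#' @export
ce_ratio <- function(cost, effect) {
  if (any(effect <= 0)) stop("effect must be > 0", call. = FALSE)
  cost / effect
}

#' Cost-effectiveness frontier with dominance pruning
#'
#' Orders strategies by effectiveness, flags strongly dominated
#' strategies (at least as effective alternative at lower-or-equal cost,
#' or equal effect at lower cost), then removes extendedly dominated
#' strategies (whose incremental ICER exceeds that of a more effective
#' alternative) iteratively, and computes incremental cost, incremental
#' effect and ICER along the surviving chain. Along the frontier, ICERs
#' are strictly increasing by construction.
#'
#' @param points Data frame with columns `strategy`, `cost`, `effect`.
#' @param wtp Willingness-to-pay threshold used for the NMB column.
#' @return A `cea_table`: `points` ordered by effect with columns
#'   `inc_cost`, `inc_effect`, `icer`, `nmb`, `ce_ratio`, and
#'   `dominance` (`"none"`, `"dominated"`, or `"extended"`). Dominated
#'   rows carry `NA` ICERs.
#' @export
frontier <- function(points, wtp = 50000) {
  stopifnot(is.data.frame(points),
            all(c("strategy", "cost", "effect") %in% names(points)),
            nrow(points) >= 1)
  tab <- points[order(points$effect, points$cost), , drop = FALSE]
  n <- nrow(tab)
  tab$dominance <- "none"
  # strong dominance; of exactly tied strategies only the first survives
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i == k) next
    if (tab$effect[k] >= tab$effect[i] && tab$cost[k] <= tab$cost[i] &&
        (tab$effect[k] > tab$effect[i] || tab$cost[k] < tab$cost[i] || k < i))
      tab$dominance[i] <- "dominated"
  }
  # extended dominance: prune rising-ICER violations along the chain
  repeat {
    chain <- which(tab$dominance == "none")
    if (length(chain) < 3) break
    ic <- diff(tab$cost[chain]) / diff(tab$effect[chain])
    bad <- which(utils::head(ic, -1) >= utils::tail(ic, -1))
    if (!length(bad)) break
    tab$dominance[chain[bad[1] + 1]] <- "extended"
  }
  tab$inc_cost <- NA_real_
  tab$inc_effect <- NA_real_
  tab$icer <- NA_real_
  chain <- which(tab$dominance == "none")
  if (length(chain) >= 1) {
    tab$inc_cost[chain[1]] <- 0
    tab$inc_effect[chain[1]] <- 0
  }
  if (length(chain) >= 2) {
    tab$inc_cost[chain[-1]] <- diff(tab$cost[chain])
    tab$inc_effect[chain[-1]] <- diff(tab$effect[chain])
    tab$icer[chain[-1]] <- tab$inc_cost[chain[-1]] / tab$inc_effect[chain[-1]]
  }
  tab$nmb <- nmb(tab$cost, tab$effect, wtp)
  tab$ce_ratio <- ifelse(tab$effect > 0, tab$cost / tab$effect, NA_real_)
  attr(tab, "wtp") <- wtp
  rownames(tab) <- NULL
  class(tab) <- c("cea_table", "data.frame")
  tab
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that each
#' strategy is cost-effective: the fraction of probabilistic
#' sensitivity-analysis iterations in which it attains the strictly
#' highest net monetary benefit, with exact ties split equally. At each
#' threshold the probabilities sum to 1.
#'
#' @param draws A `psa_draws` object (see [psa()]) or a data frame with
#'   columns `iteration`, `strategy`, `cost`, `effect`.
#' @param wtp_grid Numeric vector of thresholds.
#' @return Long data frame (`wtp`, `strategy`, `probability`) of class
#'   `cea_ceac`.
#' @export
ceac <- function(draws, wtp_grid) {
  d <- if (inherits(draws, "psa_draws")) draws$draws else draws
  stopifnot(nrow(d) > 0, length(wtp_grid) > 0)
  strat <- sort(unique(d$strategy))
  iters <- sort(unique(d$iteration))
  cost <- matrix(NA_real_, length(iters), length(strat),
                 dimnames = list(NULL, strat))
  eff <- cost
  for (s in strat) {
    ds <- d[d$strategy == s, ]
    ds <- ds[match(iters, ds$iteration), ]
    cost[, s] <- ds$cost
    eff[, s] <- ds$effect
  }
  if (anyNA(cost) || anyNA(eff))
    stop("draws must contain every strategy in every iteration", call. = FALSE)
  out <- expand.grid(wtp = wtp_grid, strategy = strat,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$probability <- NA_real_
  for (w in wtp_grid) {
    b <- w * eff - cost
    mx <- apply(b, 1, max)
    win <- b >= mx - 1e-9 * pmax(1, abs(mx))   # ties within fp noise
    share <- win / rowSums(win)
    pr <- colMeans(share)
    out$probability[out$wtp == w] <- pr[match(out$strategy[out$wtp == w],
                                              strat)]
  }
  class(out) <- c("cea_ceac", "data.frame")
  out
}

#' @export
print.cea_table <- function(x, ...) {
  cat("<cea_table> at WTP $", format(attr(x, "wtp"), big.mark = ","),
      " per effect unit\n", sep = "")
  print.data.frame(
    within(as.data.frame(x), {
      cost <- round(cost); nmb <- round(nmb)
      icer <- round(icer, 1); ce_ratio <- round(ce_ratio, 1)
    }), row.names = FALSE)
  invisible(x)
}
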