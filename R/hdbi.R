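#' Proportional shortfall of supply below a target
#'
#' For available supply `q` and benchmark `Q`, the shortfall is
#' \eqn{s = (Q - q)/Q} when `q < Q` and 0 otherwise. Supply at or above the
#' target earns a shortfall of exactly 0; excess never earns credit.
#'
#' @param q Nonnegative numeric vector, available kcal/capita/day.
#' @param Q Positive numeric vector (recycled), target kcal/capita/day.
#' @return Numeric vector of shortfalls in `[0, 1]`.
#' @export
#' @examples
#' shortfall(580, 1160)  # half the target -> 0.5
#' shortfall(2330, 1160) # excess -> 0
shortfall <- function(q, Q) {
  if (any(!is.finite(Q)) || any(Q <= 0)) abort("targets Q must be positive")
  if (any(!is.finite(q)) || any(q < 0)) abort("supplies q must be nonnegative")
  pmax(0, (Q - q) / Q)
}

#' Healthy Diet Basket Index for one supply vector
#'
#' The HDBI is 1 minus the mean proportional shortfall of supply below the
#' HDB target across the six food groups:
#' \deqn{HDBI = 1 - \frac{1}{6}\sum_{i=1}^{6} \frac{Q_i - q_i}{Q_i}
#'       \quad \forall\, q_i < Q_i}
#' Shortfalls are equally weighted and are not offset by excesses in other
#' groups, so the index lies in `[0, 1]`: 1 means every group is supplied at
#' or above its benchmark, 0 the hypothetical extreme where none of the six
#' groups is available at all (e.g. all energy from sugar).
#'
#' Free sugars sit outside the basket; when `sugar_kcal` and `total_kcal` are
#' given, the share of dietary energy from sugar is checked against the WHO
#' guideline that free sugars stay below 10% of total energy (strict
#' inequality: a share of exactly 0.10 violates the limit).
#'
#' @param q Named numeric vector of kcal/capita/day over the groups of
#'   [hdb_groups()]. Groups absent from `q` are treated as zero supply with a
#'   warning (or an error when `strict = TRUE`).
#' @param targets Named numeric targets, as from [hdb_targets()].
#' @param sugar_kcal,total_kcal Optional free-sugar and total energy
#'   (kcal/capita/day) for the WHO sugar-share check.
#' @param sugar_limit Free-sugar share threshold, default 0.10.
#' @param strict Error (rather than warn) on groups missing from `q`.
#' @return A list of class `hdbi_score` with elements `hdbi`, `shortfalls`
#'   (named vector over the six groups), `sugar_share` (`NA` when total energy
#'   is unavailable or zero) and `sugar_within_limit`.
#' @export
#' @examples
#' # all benchmarks met
#' compute_hdbi(hdb_targets())$hdbi
#' # all energy from starchy staples alone
#' compute_hdbi(c(starchy_staples = 2330))$hdbi
compute_hdbi <- function(q, targets = hdb_targets(), sugar_kcal = NA_real_,
                         total_kcal = NA_real_, sugar_limit = 0.10,
                         strict = FALSE) {
  groups <- hdb_groups()
  validate_targets(targets, total_kcal = NULL)
  if (is.null(names(q))) abort("q must be a named vector over HDB groups")
  unknown <- setdiff(names(q), groups)
  if (length(unknown)) {
    abort(paste0("unknown food group(s) in q: ", paste(unknown, collapse = ", ")))
  }
  miss <- setdiff(groups, names(q))
  if (length(miss)) {
    msg <- paste0("groups absent from supply treated as zero: ",
                  paste(miss, collapse = ", "))
    if (strict) abort(msg) else warn(msg)
    q[miss] <- 0
  }
  q <- q[groups]
  s <- shortfall(q, targets[groups])
  share <- if (is.finite(sugar_kcal) && is.finite(total_kcal) && total_kcal > 0) {
    sugar_kcal / total_kcal
  } else {
    NA_real_
  }
  structure(
    list(
      hdbi = 1 - mean(s),
      shortfalls = setNames(s, groups),
      sugar_share = share,
      sugar_within_limit = if (is.na(share)) NA else share < sugar_limit
    ),
    class = "hdbi_score"
  )
}

#' @export
print.hdbi_score <- function(x, digits = 3, ...) {
  cat("Healthy Diet Basket Index:", round(x$hdbi, digits), "\n")
  cat("Shortfalls below target:\n")
  print(round(x$shortfalls, digits))
  if (!is.na(x$sugar_share)) {
    cat(sprintf("Free-sugar share of energy: %.3f (%s WHO <10%% guideline)\n",
                x$sugar_share,
                if (isTRUE(x$sugar_within_limit)) "within" else "exceeds"))
  }
  invisible(x)
}

#' Score a table of food-group supplies
#'
#' Applies [compute_hdbi()] row by row to a food-group supply table (one row
#' per entity-year, as produced by [group_supply()] or [regional_supply()]),
#' returning per-group shortfall columns (`s_<group>`), the HDBI, and the
#' free-sugar share indicator.
#'
#' @param supplies Tibble with columns `entity`, `year`, one column per HDB
#'   group, and optionally `sugar_kcal` and `total_kcal`. Missing group
#'   columns are treated as zero supply with one warning.
#' @param targets Named numeric targets, as from [hdb_targets()].
#' @inheritParams compute_hdbi
#' @return Tibble with one row per input row: `entity`, `year`, the six
#'   `s_<group>` shortfalls, `hdbi`, `sugar_share`, `sugar_within_limit`.
#' @export
score_table <- function(supplies, targets = hdb_targets(), sugar_limit = 0.10,
                        strict = FALSE) {
  validate_targets(targets, total_kcal = NULL)
  groups <- hdb_groups()
  supplies <- as_tibble(supplies)
  out <- supplies[intersect(c("entity", "year"), names(supplies))]
  miss <- setdiff(groups, names(supplies))
  if (length(miss)) {
    msg <- paste0("groups absent from supply table treated as zero: ",
                  paste(miss, collapse = ", "))
    if (strict) abort(msg) else if (nrow(supplies) > 0) warn(msg)
  }
  s_sum <- rep(0, nrow(supplies))
  for (g in groups) {
    qg <- if (g %in% names(supplies)) supplies[[g]] else rep(0, nrow(supplies))
    sg <- shortfall(qg, targets[[g]])
    out[[paste0("s_", g)]] <- sg
    s_sum <- s_sum + sg
  }
  out$hdbi <- 1 - s_sum / length(groups)
  sugar <- supplies[["sugar_kcal"]] %||% rep(NA_real_, nrow(supplies))
  total <- supplies[["total_kcal"]] %||% rep(NA_real_, nrow(supplies))
  share <- ifelse(is.finite(sugar) & is.finite(total) & total > 0,
                  sugar / total, NA_real_)
  out$sugar_share <- share
  out$sugar_within_limit <- ifelse(is.na(share), NA, share < sugar_limit)
  as_tibble(out)
}
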