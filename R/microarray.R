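#' Background-subtract a spot table
#'
#' Subtracts each spot's local background from its raw intensity, flooring at
#' zero. The number of clipped (background > intensity) spots is reported via
#' a message and the `"n_clipped"` attribute.
#'
#' @param table Spot table: data frame with columns `spot_id`, `side`,
#'   `condition_id`, `conc`, `intensity`, `background`.
#' @return The table with corrected intensities and `background` zeroed.
#' @export
subtract_background <- function(table) {
  check_spot_table(table)
  corrected <- table$intensity - table$background
  n_clipped <- sum(corrected < 0)
  if (n_clipped > 0) {
    message(n_clipped, " spot(s) clipped to zero during background subtraction")
  }
  table$intensity <- pmax(corrected, 0)
  table$background <- 0
  attr(table, "n_clipped") <- n_clipped
  table
}

check_spot_table <- function(table) {
  needed <- c("spot_id", "side", "condition_id", "conc", "intensity", "background")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop_multikin("spot table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(table$intensity < 0)) stop_multikin("intensities must be >= 0")
  if (any(!table$side %in% c("left", "right"))) {
    stop_multikin("side must be 'left' or 'right'")
  }
  # every (spot, condition) pair must appear on both duplicate sides
  key <- paste(table$spot_id, table$condition_id)
  sides <- tapply(table$side, key, function(s) length(unique(s)))
  if (any(sides < 2L)) {
    bad <- names(sides)[which(sides < 2L)][1L]
    stop_multikin("spot/condition '", bad, "' is missing a duplicate side",
                  class = "multikin_duplicate_error")
  }
  invisible(table)
}

#' Duplicate-spot deviation
#'
#' Per-spot population standard deviation of the left/right duplicate pair,
#' \eqn{\sqrt{\sum (x - \bar x)^2 / n}} with n = 2 pooled values per spot.
#' (The conventional population SD is used; a printed variant of this
#' formula that omits the square on the deviation is dimensionally
#' inconsistent and is not implemented.)
#'
#' @param left,right Equal-length numeric vectors of duplicate intensities.
#' @return Numeric vector of per-spot deviations.
#' @examples
#' duplicate_stdev(4, 8)  # 2
#' @export
duplicate_stdev <- function(left, right) {
  if (length(left) != length(right)) {
    stop_multikin("left and right must have equal length")
  }
  if (length(left) == 0L) stop_multikin("no data points")
  m <- (left + right) / 2
  sqrt(((left - m)^2 + (right - m)^2) / 2)
}

#' Normalise competition conditions to the no-competitor control
#'
#' Sums the intensities of all spots (both duplicate sides) per condition and
#' divides by the summed intensity of the zero-competitor condition, giving
#' relative binding with the control pinned at exactly 1.
#'
#' @param table Spot table (ideally after [subtract_background()]).
#' @return Data frame with one row per condition: `condition_id`, `conc`,
#'   `total_intensity`, `rel_binding`, `duplicate_sd` (mean per-spot
#'   duplicate deviation).
#' @export
normalize_competition <- function(table) {
  check_spot_table(table)
  if (!any(table$conc == 0)) {
    stop_multikin("no zero-competitor condition present; cannot normalise",
                  class = "multikin_missing_control_error")
  }
  conds <- unique(table[, c("condition_id", "conc")])
  conds <- conds[order(conds$conc), , drop = FALSE]
  totals <- vapply(conds$condition_id, function(cid) {
    sum(table$intensity[table$condition_id == cid])
  }, numeric(1L))
  dup_sd <- vapply(conds$condition_id, function(cid) {
    sub <- table[table$condition_id == cid, , drop = FALSE]
    sub <- sub[order(sub$spot_id, sub$side), , drop = FALSE]
    l <- sub$intensity[sub$side == "left"]
    r <- sub$intensity[sub$side == "right"]
    mean(duplicate_stdev(l, r))
  }, numeric(1L))
  ref <- totals[conds$conc == 0][1L]
  if (ref <= 0) stop_multikin("zero-competitor condition has zero total intensity")
  data.frame(condition_id = conds$condition_id, conc = conds$conc,
             total_intensity = unname(totals),
             rel_binding = unname(totals / ref),
             duplicate_sd = unname(dup_sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Neutralisation IC50 from relative binding
#'
#' Logistic fit ([fit_hill()]) of relative binding versus competitor
#' concentration; the midpoint is the concentration at which the compound
#' neutralises half of the target binding. Compounds are compared by IC50
#' ratios.
#'
#' @param rel_binding Relative binding values (control = 1).
#' @param concs Competitor concentrations (molar), aligned with
#'   `rel_binding`; at least 5 values.
#' @return List with `IC50` (molar), `hill` (the underlying [fit_hill()]
#'   object), and `flag`.
#' @export
neutralization_ic50 <- function(rel_binding, concs) {
  if (length(concs) < 5L) stop_multikin("at least 5 concentrations required")
  hf <- fit_hill(concs, rel_binding)
  list(IC50 = hf$EC50, hill = hf, flag = hf$flag)
}
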