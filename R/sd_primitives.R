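#' First-order exponential smooth
#'
#' Returns the variable pair implementing `dY/dt = (X - Y) / T`: a stock `Y`
#' that approaches the target `X` with adjustment time `T`. This is the
#' standard gradual-adjustment primitive (perception lags, staff adaptation).
#'
#' @param name name of the smooth stock `Y`.
#' @param target name of the target variable `X`.
#' @param adjust_time adjustment time `T` in months: a positive number, or the
#'   name of a model constant.
#' @param initial initial value of `Y` (number or quoted expression of
#'   constants).
#' @param units unit string for `Y`.
#' @return list of two `sd_variable`s (the stock and its net-change flow),
#'   ready to splice into [sd_model()].
#' @export
first_order_smooth <- function(name, target, adjust_time, initial = 0,
                               units = "1") {
  adj <- resolve_time_arg(adjust_time, "adjust_time")
  change <- paste0(name, "_change")
  eq <- bquote((.(as.name(target)) - .(as.name(name))) / .(adj))
  list(
    sd_stock(name, initial = initial, inflows = change, units = units,
             non_negative = FALSE),
    sd_flow(change, eq, units = paste0(units, "/month"))
  )
}

#' First-order material delay
#'
#' Goods that have been ordered reside in an in-transit stock and arrive at
#' rate `in_transit / delay_time`, conserving material: everything ordered is
#' eventually delivered (total ordered = total arrived + in transit).
#'
#' @param arrival_name name of the arrival flow to create.
#' @param order_name name of an existing flow feeding the delay.
#' @param delay_time delay in months: a positive number or the name of a model
#'   constant.
#' @param initial initial in-transit quantity (number or quoted expression).
#' @param units unit string of the material.
#' @return list of two `sd_variable`s: the in-transit stock
#'   (`<arrival_name>_in_transit`, non-negative) and the arrival flow.
#' @export
material_delay <- function(arrival_name, order_name, delay_time, initial = 0,
                           units = "packs") {
  del <- resolve_time_arg(delay_time, "delay_time")
  transit <- paste0(arrival_name, "_in_transit")
  list(
    sd_stock(transit, initial = initial, inflows = order_name,
             outflows = arrival_name, units = units, non_negative = TRUE),
    sd_flow(arrival_name, bquote(.(as.name(transit)) / .(del)),
            units = paste0(units, "/month"))
  )
}

resolve_time_arg <- function(x, what) {
  if (is.numeric(x) && length(x) == 1L) {
    if (!is.finite(x) || x <= 0) stop(what, " must be > 0")
    return(x)
  }
  if (is.character(x) && length(x) == 1L && nzchar(x)) return(as.name(x))
  stop(what, " must be a positive number or a constant name")
}
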