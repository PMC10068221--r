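# Per-block broadband speed aggregation and the joint weight functions
# used by the virtual catchment models.

modal_set <- function(x) {
  # all values attaining the maximal frequency; exact equality of the
  # parsed decimals (FCC speeds are coarse decimals, no epsilon)
  tab <- table(x)
  as.numeric(names(tab)[tab == max(tab)])
}

#' Aggregate the speeds offered in one block to a single value
#'
#' A census block typically has several providers, each advertising a
#' different speed; a per-block model needs one number.  Four metrics:
#' \describe{
#'   \item{`avg`}{arithmetic mean of all offered speeds.  Skewed badly by
#'     gigabit outliers, which is why the alternatives below exist.}
#'   \item{`min_a`}{minimum available speed -- the worst-case subscriber.}
#'   \item{`min_f`}{minimum of the modal set (the speeds attaining the
#'     maximal provider count) -- a common case.}
#'   \item{`max_f`}{maximum of the modal set -- the optimal common case.}
#' }
#' When every speed is unique the modal set is the whole set, so
#' `min_f = min_a` and `max_f` is the overall maximum.
#'
#' @param speeds non-empty numeric vector of offered speeds (Mbps) for one
#'   block and one direction.
#' @param metric one of [speed_metrics()].
#' @return A single aggregated speed in Mbps.
#' @examples
#' dl <- c(2, 3, 18, 25, 25, 35, 100, 500, 1000, 1000)
#' aggregate_block_speed(dl, "min_a")  # 2
#' aggregate_block_speed(dl, "min_f")  # 25
#' aggregate_block_speed(dl, "max_f")  # 1000
#' @export
aggregate_block_speed <- function(speeds, metric) {
  metric <- match_metric(metric)
  if (length(speeds) == 0L)
    stop("no broadband records for block")
  if (any(!is.finite(speeds)) || any(speeds < 0))
    stop("speeds must be finite and >= 0")
  switch(metric,
    avg = mean(speeds),
    min_a = min(speeds),
    min_f = min(modal_set(speeds)),
    max_f = max(modal_set(speeds))
  )
}

#' Aggregate all provider records to one row per block
#'
#' Groups the provider records by block and applies
#' [aggregate_block_speed()] independently to the download and upload
#' speeds of each block.  Blocks with no records are simply absent from
#' the output; the accessibility engines treat them as weight 0 in the
#' broadband-aware modes.
#'
#' @param records a [broadband_records()] table.
#' @param metric one of [speed_metrics()].
#' @return A `data.frame` with columns `block_id`, `download_mbps`,
#'   `upload_mbps` and a `metric` attribute; one row per block present in
#'   `records`.
#' @export
aggregate_all <- function(records, metric) {
  metric <- match_metric(metric)
  if (nrow(records) == 0L) {
    out <- data.frame(block_id = character(0), download_mbps = numeric(0),
                      upload_mbps = numeric(0), stringsAsFactors = FALSE)
  } else {
    ids <- sort(unique(records$block_id))
    grp <- split(records, factor(records$block_id, levels = ids))
    out <- data.frame(
      block_id = ids,
      download_mbps = vapply(grp, function(g)
        aggregate_block_speed(g$download_mbps, metric), numeric(1)),
      upload_mbps = vapply(grp, function(g)
        aggregate_block_speed(g$upload_mbps, metric), numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  attr(out, "metric") <- metric
  out
}

#' Evaluate a step-wise weight schedule at a speed
#'
#' Returns the weight of the half-open bin `[x_i, x_{i+1})` containing
#' `x`, with the first weight on `[0, x_1)` and the last on
#' `[x_n, Inf)` -- any printed upper sentinel (e.g. 9999 Mbps) is treated
#' as infinity so the function is total.
#'
#' @param x speed in Mbps, `>= 0`; vectorized.
#' @param schedule a [step_schedule()].
#' @return Weight(s) in \[0, 1\].
#' @export
stepwise_weight <- function(x, schedule = default_schedule()) {
  stopifnot(inherits(schedule, "step_schedule"))
  if (any(!is.finite(x)) || any(x < 0))
    stop("speed must be finite and >= 0")
  idx <- findInterval(x, schedule$breaks) + 1L  # bins closed-left
  schedule$weights[idx]
}

#' Step-wise broadband joint weight of a demand-supply pair
#'
#' The weight the enhanced virtual catchment model puts on a pair: a video
#' call is constrained by its weakest link, so the step schedule is
#' evaluated at the *minimum* of the four speeds -- demand upload and
#' download, supply upload and download.
#'
#' @param demand_down,demand_up,supply_down,supply_up speeds in Mbps.
#' @param schedule a [step_schedule()].
#' @return Weight in \[0, 1\]; vectorized over the four speed arguments.
#' @examples
#' joint_weight(1, 1, 100, 100)        # 0.33: the 1 Mbps side binds
#' joint_weight(50, 50, 0.1, 50)       # 0: below the 0.6 Mbps floor
#' @export
joint_weight <- function(demand_down, demand_up, supply_down, supply_up,
                         schedule = default_schedule()) {
  stepwise_weight(pmin(demand_down, demand_up, supply_down, supply_up),
                  schedule)
}

#' Binary broadband joint weight
#'
#' The joint function of the plain virtual catchment model: 1 if both the
#' demand and the supply side have internet access at all, else 0.  Speed
#' sufficiency is deliberately ignored -- a pair where the patient has
#' 1 Mbps and the provider 100 Mbps still gets weight 1, which is exactly
#' the overestimate the step-wise function corrects.
#'
#' @param demand_has_internet,supply_has_internet logical flags; vectorized.
#' @return 0 or 1.
#' @export
binary_weight <- function(demand_has_internet, supply_has_internet) {
  as.numeric(demand_has_internet & supply_has_internet)
}

#' Which blocks have internet access at all
#'
#' A block has internet iff it has at least one provider record with both
#' download and upload speed strictly positive.
#'
#' @param records a [broadband_records()] table.
#' @return Character vector of block ids with internet access.
#' @export
blocks_with_internet <- function(records) {
  ok <- records$download_mbps > 0 & records$upload_mbps > 0
  unique(records$block_id[ok])
}
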