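# The two-step catchment-area engines.
#
# All three methods share one skeleton over a sparse pairwise weight map
# W[(demand k, supply j)]:
#   step 1:  R_j = S_j / sum_k D_k * W[k, j]   (supply-demand ratio)
#   step 2:  A_i = sum_j R_j * W[i, j]         (accessibility)
# They differ only in how W is filled inside the travel-time catchment:
# distance decay (2SFCA), the binary both-sides-online function (2SVCA),
# or the step-wise broadband joint function (E2SVCA).

#' Sparse pairwise weights inside the travel-time catchment
#'
#' Builds the weight map driving both steps of every catchment model.  An
#' entry exists only for (demand, supply) pairs whose travel time is
#' recorded and `<= d0` -- absent OD pairs are unreachable and get no
#' entry.  Within the catchment the weight depends on `mode`:
#' \describe{
#'   \item{`distance_only`}{the distance-decay value (indicator decay
#'     gives 1) -- the 2SFCA family.}
#'   \item{`binary_broadband`}{[binary_weight()] of the two blocks'
#'     internet-presence flags -- 2SVCA.}
#'   \item{`stepwise_broadband`}{[joint_weight()] of the pair's aggregated
#'     up/down speeds -- E2SVCA.}
#' }
#' Blocks lacking an aggregated broadband row get weight 0 in the
#' broadband modes (real FCC extracts have gaps); the entry is kept so the
#' pair is visibly in-catchment.
#'
#' @param blocks a [blocks()] table.
#' @param od an [od_pairs()] table (origin = demand, destination =
#'   supply).
#' @param d0 catchment travel-time threshold in minutes, `> 0`.
#' @param mode `"distance_only"`, `"binary_broadband"` or
#'   `"stepwise_broadband"`.
#' @param bb aggregated per-block speeds from [aggregate_all()]
#'   (stepwise mode).
#' @param schedule a [step_schedule()] (stepwise mode).
#' @param has_internet character vector of block ids with internet access
#'   (binary mode), e.g. from [blocks_with_internet()].
#' @param decay a [decay_function()] (distance mode; default indicator).
#' @return `data.frame` with columns `demand`, `supply`, `minutes`,
#'   `weight`.
#' @export
pair_weights <- function(blocks, od, d0,
                         mode = c("distance_only", "binary_broadband",
                                  "stepwise_broadband"),
                         bb = NULL, schedule = NULL, has_internet = NULL,
                         decay = decay_function("indicator")) {
  mode <- match.arg(mode)
  if (!is.numeric(d0) || length(d0) != 1L || !is.finite(d0) || d0 <= 0)
    stop("d0 must be a single positive number of minutes")
  keep <- od$minutes <= d0 &
    od$origin %in% blocks$block_id &
    od$destination %in% blocks$block_id
  W <- data.frame(demand = od$origin[keep], supply = od$destination[keep],
                  minutes = od$minutes[keep], stringsAsFactors = FALSE)
  W$weight <- switch(mode,
    distance_only = decay(W$minutes, d0),
    binary_broadband = {
      if (is.null(has_internet))
        stop("binary_broadband mode requires has_internet flags")
      binary_weight(W$demand %in% has_internet,
                    W$supply %in% has_internet)
    },
    stepwise_broadband = {
      if (is.null(bb) || is.null(schedule))
        stop("stepwise_broadband mode requires bb and schedule")
      di <- match(W$demand, bb$block_id)
      si <- match(W$supply, bb$block_id)
      w <- numeric(nrow(W))
      ok <- !is.na(di) & !is.na(si)
      w[ok] <- joint_weight(bb$download_mbps[di[ok]],
                            bb$upload_mbps[di[ok]],
                            bb$download_mbps[si[ok]],
                            bb$upload_mbps[si[ok]], schedule)
      w
    })
  W
}

#' Step one: supply-demand ratios
#'
#' For each block `j` with supply `S_j > 0`, the weighted demand able to
#' reach it is `denom_j = sum_k D_k * W[k, j]`; the ratio is
#' `R_j = S_j / denom_j`.  A supply no weighted demand can reach
#' (`denom_j = 0`) gets `R_j = 0`: an unreachable clinic provides no
#' accessibility, and the convention avoids NaN propagation.
#'
#' @param blocks a [blocks()] table.
#' @param W pairwise weights from [pair_weights()].
#' @return Named numeric vector `R` over blocks with positive supply.
#' @export
supply_demand_ratios <- function(blocks, W) {
  sup <- blocks[blocks$supply > 0, , drop = FALSE]
  R <- stats::setNames(numeric(nrow(sup)), sup$block_id)
  pop <- blocks$population[match(W$demand, blocks$block_id)]
  contrib <- pop * W$weight
  denom <- tapply(contrib, factor(W$supply, levels = sup$block_id), sum)
  denom[is.na(denom)] <- 0
  pos <- denom > 0
  R[pos] <- sup$supply[pos] / denom[pos]
  R
}

#' Step two: accessibility scores
#'
#' `A_i = sum_j R_j * W[i, j]` over the supply blocks `j` reachable from
#' demand block `i`.  Blocks with no in-catchment supply (or only
#' zero-weight links) score 0.
#'
#' @param blocks a [blocks()] table.
#' @param W pairwise weights from [pair_weights()].
#' @param R ratios from [supply_demand_ratios()].
#' @return Named numeric vector of scores over all blocks.
#' @export
accessibility_step <- function(blocks, W, R) {
  A <- stats::setNames(numeric(nrow(blocks)), blocks$block_id)
  ri <- match(W$supply, names(R))
  ok <- !is.na(ri)
  contrib <- R[ri[ok]] * W$weight[ok]
  acc <- tapply(contrib, factor(W$demand[ok], levels = blocks$block_id),
                sum)
  acc[is.na(acc)] <- 0
  A[] <- acc
  A
}

#' Compute accessibility with a catchment-area model
#'
#' Orchestrates the full pipeline for one method:
#' \describe{
#'   \item{`"2sfca"`}{distance-only weights (default indicator decay --
#'     uniform access within the catchment).}
#'   \item{`"2svca"`}{binary broadband weights: a pair counts fully iff
#'     both blocks have any internet provider.}
#'   \item{`"e2svca"`}{step-wise broadband weights on the minimum of the
#'     four aggregated speeds, under the chosen speed `metric`.}
#' }
#' Catchment membership is by travel time `<= d0` in every method, and
#' both steps use the same `d0`.  The virtual models carry no distance
#' decay inside the catchment: broadband quality, not distance, is the
#' impedance.
#'
#' @param blocks a [blocks()] table.
#' @param od an [od_pairs()] table.
#' @param d0 catchment travel-time threshold in minutes.
#' @param method `"2sfca"`, `"2svca"` or `"e2svca"`.
#' @param metric speed metric for `e2svca` (one of [speed_metrics()]).
#' @param records a [broadband_records()] table (required for the virtual
#'   methods).
#' @param schedule a [step_schedule()]; defaults to [default_schedule()].
#' @param decay a [decay_function()] for `2sfca`.
#' @return An object of class `accessibility_result`: list with `method`,
#'   `metric`, `d0`, `per_capita_factor`, `scores` (named vector, every
#'   block), `ratios` (named vector, supply blocks) and the `blocks`
#'   table.
#' @examples
#' area <- generate_scenario(scenario_config(rows = 5, cols = 5, seed = 1))
#' od <- od_matrix(area$graph, snap_to_graph(area$blocks, area$graph),
#'                 cutoff = 30)
#' res <- compute_accessibility(area$blocks, od, d0 = 30,
#'                              method = "e2svca", metric = "min_f",
#'                              records = area$broadband)
#' res
#' @export
compute_accessibility <- function(blocks, od, d0,
                                  method = c("2sfca", "2svca", "e2svca"),
                                  metric = NULL, records = NULL,
                                  schedule = default_schedule(),
                                  decay = decay_function("indicator")) {
  method <- match.arg(method)
  if (method %in% c("2svca", "e2svca") && is.null(records))
    stop("method '", method, "' requires broadband records")
  W <- switch(method,
    "2sfca" = pair_weights(blocks, od, d0, "distance_only", decay = decay),
    "2svca" = pair_weights(blocks, od, d0, "binary_broadband",
                           has_internet = blocks_with_internet(records)),
    "e2svca" = {
      if (is.null(metric))
        stop("method 'e2svca' requires a speed metric")
      bb <- aggregate_all(records, metric)
      pair_weights(blocks, od, d0, "stepwise_broadband", bb = bb,
                   schedule = schedule)
    })
  R <- supply_demand_ratios(blocks, W)
  A <- accessibility_step(blocks, W, R)
  structure(list(method = method,
                 metric = if (method == "e2svca") match_metric(metric)
                          else NULL,
                 d0 = d0, per_capita_factor = NULL,
                 scores = A, ratios = R, blocks = blocks),
            class = "accessibility_result")
}

#' @export
print.accessibility_result <- function(x, ...) {
  lab <- if (is.null(x$metric)) x$method
         else paste0(x$method, " (", x$metric, ")")
  sc <- x$scores[x$blocks$in_report_region]
  cat(sprintf(
    "<accessibility_result> %s, d0 = %g min%s\n", lab, x$d0,
    if (is.null(x$per_capita_factor)) ""
    else sprintf(", per %g population", x$per_capita_factor)))
  cat(sprintf("  %d blocks in report region: mean %.4g, range [%.4g, %.4g]\n",
              length(sc), mean(sc), min(sc), max(sc)))
  invisible(x)
}
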