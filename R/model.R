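#' Construct a table of census blocks
#'
#' A block is the areal unit of the study area: it carries demand (its
#' population), supply (the number of providers/doctors aggregated to it),
#' and a centroid used for travel-time computation.  Block identifiers are
#' opaque strings -- FIPS-style codes have leading zeros that must survive
#' every round trip -- and are never coerced to numbers.
#'
#' Blocks outside the reporting region (a buffer ring around the study
#' area, used to suppress edge effects) carry `in_report_region = FALSE`:
#' they participate in every computation but are excluded from
#' normalization, classification and summaries.
#'
#' @param block_id character vector of unique block identifiers.
#' @param x,y numeric centroid coordinates (planar or geographic).
#' @param population non-negative integer demand per block.
#' @param supply non-negative provider/doctor count per block.
#' @param in_report_region logical; `FALSE` marks buffer-only blocks.
#' @return A `data.frame` of class `tele_blocks` with one row per block.
#' @examples
#' blocks(c("001", "002"), x = c(0, 1), y = c(0, 0),
#'        population = c(100, 50), supply = c(2, 0))
#' @export
blocks <- function(block_id, x, y, population, supply,
                   in_report_region = TRUE) {
  block_id <- as.character(block_id)
  n <- length(block_id)
  in_report_region <- rep_len(as.logical(in_report_region), n)
  df <- data.frame(
    block_id = block_id,
    x = as.numeric(x),
    y = as.numeric(y),
    population = as.numeric(population),
    supply = as.numeric(supply),
    in_report_region = in_report_region,
    stringsAsFactors = FALSE
  )
  validate_blocks(df)
  class(df) <- c("tele_blocks", "data.frame")
  df
}

validate_blocks <- function(df) {
  if (anyDuplicated(df$block_id))
    stop("duplicate block_id: ",
         paste(unique(df$block_id[duplicated(df$block_id)]), collapse = ", "))
  if (any(!is.finite(df$population)) || any(df$population < 0))
    stop("population must be finite and >= 0")
  if (any(!is.finite(df$supply)) || any(df$supply < 0))
    stop("supply must be finite and >= 0")
  if (!any(df$in_report_region))
    stop("at least one block must have in_report_region = TRUE")
  invisible(df)
}

#' @export
print.tele_blocks <- function(x, ...) {
  cat(sprintf(
    "<tele_blocks> %d blocks (%d in report region), population %s, supply %s\n",
    nrow(x), sum(x$in_report_region),
    format(sum(x$population), big.mark = ","),
    format(sum(x$supply), big.mark = ",")))
  NextMethod()
}

#' Construct per-provider broadband speed records
#'
#' One row per internet service provider offering in a block, in the shape
#' of FCC Form 477 deployment data: the maximum advertised download and
#' upload speed in Mbps.  Several providers per block are expected; the
#' per-block aggregation to a single speed is done by [aggregate_all()].
#'
#' @param block_id,provider_id character identifiers.
#' @param download_mbps,upload_mbps non-negative speeds in Mbps.
#' @return A `data.frame` of class `tele_broadband`.
#' @export
broadband_records <- function(block_id, provider_id, download_mbps,
                              upload_mbps) {
  df <- data.frame(
    block_id = as.character(block_id),
    provider_id = as.character(provider_id),
    download_mbps = as.numeric(download_mbps),
    upload_mbps = as.numeric(upload_mbps),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(df$download_mbps) | df$download_mbps < 0 |
    !is.finite(df$upload_mbps) | df$upload_mbps < 0
  if (any(bad))
    stop("negative or non-finite speed in broadband record row(s): ",
         paste(which(bad), collapse = ", "))
  class(df) <- c("tele_broadband", "data.frame")
  df
}

#' Construct a sparse origin-destination travel-time matrix
#'
#' Long (sparse) representation: one row per reachable (origin,
#' destination) pair with the travel time in minutes.  A pair absent from
#' the table is *unreachable* -- outside every catchment -- which is
#' distinct from a time of 0 (same location).
#'
#' @param origin,destination character block identifiers.
#' @param minutes non-negative travel times.
#' @return A `data.frame` of class `tele_od`.
#' @export
od_pairs <- function(origin, destination, minutes) {
  df <- data.frame(
    origin = as.character(origin),
    destination = as.character(destination),
    minutes = as.numeric(minutes),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(df$minutes)) || any(df$minutes < 0))
    stop("travel times must be finite and >= 0")
  key <- paste(df$origin, df$destination, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate origin-destination pair(s): ",
         paste(unique(sub("\r", " -> ", key[duplicated(key)])),
               collapse = ", "))
  self <- df$origin == df$destination
  if (any(self & df$minutes != 0))
    stop("self-pairs must have travel time 0")
  class(df) <- c("tele_od", "data.frame")
  df
}

#' @export
print.tele_od <- function(x, ...) {
  cat(sprintf("<tele_od> %d reachable pairs, %d origins, %d destinations\n",
              nrow(x), length(unique(x$origin)),
              length(unique(x$destination))))
  NextMethod()
}

#' Step-wise broadband weight schedule
#'
#' Breakpoints `x_1 < ... < x_n` (Mbps) and weights `w_0 ... w_n` in
#' \[0, 1\]: weight `w_0` applies on `[0, x_1)`, `w_i` on `[x_i, x_{i+1})`
#' and `w_n` on `[x_n, Inf)`.  Bins are closed on the left and open on the
#' right.  The default schedule, [default_schedule()], encodes one-to-one
#' video-call bandwidth tiers (0.6 / 1.2 / 3.0 Mbps).
#'
#' @param breaks strictly increasing positive numeric vector (Mbps).
#' @param weights numeric vector of length `length(breaks) + 1`, each in
#'   \[0, 1\].
#' @return An object of class `step_schedule`.
#' @examples
#' sched <- step_schedule(c(0.6, 1.2, 3.0), c(0, 0.33, 0.66, 1))
#' stepwise_weight(2.0, sched)
#' @export
step_schedule <- function(breaks, weights) {
  breaks <- as.numeric(breaks)
  weights <- as.numeric(weights)
  if (length(weights) != length(breaks) + 1L)
    stop("need exactly one more weight than breaks")
  if (length(breaks) == 0L || any(!is.finite(breaks)) || any(breaks <= 0))
    stop("breaks must be positive finite numbers")
  if (any(diff(breaks) <= 0))
    stop("breaks must be strictly increasing")
  if (any(!is.finite(weights)) || any(weights < 0) || any(weights > 1))
    stop("weights must lie in [0, 1]")
  structure(list(breaks = breaks, weights = weights),
            class = "step_schedule")
}

#' @rdname step_schedule
#' @details `default_schedule()` returns the video-conferencing schedule:
#'   weight 0 below 0.6 Mbps (no usable video), 0.33 from 0.6 Mbps
#'   (standard-quality video), 0.66 from 1.2 Mbps (720p), and 1 from
#'   3.0 Mbps (1080p; upload and download requirements taken as equal).
#' @export
default_schedule <- function() {
  step_schedule(c(0.6, 1.2, 3.0), c(0, 0.33, 0.66, 1))
}

#' @export
print.step_schedule <- function(x, ...) {
  lo <- c(0, x$breaks)
  hi <- c(x$breaks, Inf)
  cat("<step_schedule>\n")
  for (i in seq_along(x$weights))
    cat(sprintf("  [%g, %g) -> %g\n", lo[i], hi[i], x$weights[i]))
  invisible(x)
}

#' Distance-decay functions for the 2SFCA step
#'
#' `indicator` gives weight 1 inside the catchment (travel time `<= d0`)
#' and 0 outside; `gaussian` gives `exp(-d^2 / (2 * bandwidth^2))` inside
#' the catchment and 0 outside.  Both take values in \[0, 1\].
#'
#' @param kind `"indicator"` or `"gaussian"`.
#' @param bandwidth Gaussian bandwidth in minutes (required for
#'   `"gaussian"`).
#' @return A function of travel time `d` and catchment radius `d0`, with a
#'   `kind` attribute.
#' @export
decay_function <- function(kind = c("indicator", "gaussian"),
                           bandwidth = NULL) {
  kind <- match.arg(kind)
  f <- if (kind == "indicator") {
    function(d, d0) as.numeric(d <= d0)
  } else {
    if (is.null(bandwidth) || !is.finite(bandwidth) || bandwidth <= 0)
      stop("gaussian decay requires a positive bandwidth")
    force(bandwidth)
    function(d, d0) ifelse(d <= d0, exp(-d^2 / (2 * bandwidth^2)), 0)
  }
  attr(f, "kind") <- kind
  f
}

#' Valid speed-metric tokens
#'
#' The four per-block broadband aggregation metrics: `avg` (arithmetic
#' mean; the baseline the virtual-catchment literature started from),
#' `min_a` (minimum available speed, the worst case), `min_f` and `max_f`
#' (minimum and maximum of the most frequent speeds -- the modal set).
#'
#' @return Character vector of metric tokens.
#' @export
speed_metrics <- function() c("avg", "min_a", "min_f", "max_f")

match_metric <- function(metric) {
  if (length(metric) != 1L || !metric %in% speed_metrics())
    stop("metric must be one of: ", paste(speed_metrics(), collapse = ", "))
  metric
}

#' Cross-check a study area's components for consistency
#'
#' A reporting operation: returns a character vector of human-readable
#' issues (empty when the study area is consistent).  Checked: duplicate
#' block ids, broadband records referencing unknown blocks, OD entries
#' referencing unknown blocks, and blocks with no broadband record.
#'
#' Real block-level datasets from different vintages rarely align exactly;
#' mismatches are surfaced here rather than silently reconciled.
#'
#' @param blocks a [blocks()] table.
#' @param broadband a [broadband_records()] table, or `NULL`.
#' @param od an [od_pairs()] table, or `NULL`.
#' @return Character vector of issues; `character(0)` means valid.
#' @export
validate_study_area <- function(blocks, broadband = NULL, od = NULL) {
  issues <- character(0)
  dup <- unique(blocks$block_id[duplicated(blocks$block_id)])
  if (length(dup))
    issues <- c(issues, paste0("duplicate id: ", dup))
  known <- blocks$block_id
  if (!is.null(broadband)) {
    orphan <- setdiff(unique(broadband$block_id), known)
    if (length(orphan))
      issues <- c(issues,
                  paste0("orphan broadband record for unknown block: ",
                         orphan))
    uncovered <- setdiff(known, unique(broadband$block_id))
    if (length(uncovered))
      issues <- c(issues, paste0("block has no broadband record: ",
                                 uncovered))
  }
  if (!is.null(od)) {
    bad <- setdiff(unique(c(od$origin, od$destination)), known)
    if (length(bad))
      issues <- c(issues,
                  paste0("OD entry references unknown block: ", bad))
  }
  issues
}
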