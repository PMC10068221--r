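# Scaling, normalization, classification, comparison and summaries of
# accessibility results.  Reporting is restricted to in-region blocks;
# buffer blocks exist only to keep border scores honest.

#' Scale accessibility scores to a per-capita rate
#'
#' Raw two-step scores are providers per person and numerically tiny;
#' reporting them per 1,000 population is the field convention.
#'
#' @param result an `accessibility_result`.
#' @param factor positive multiplier, default 1000.
#' @return The result with every score (and ratio) multiplied by `factor`
#'   and `per_capita_factor` recorded.
#' @export
per_capita_scale <- function(result, factor = 1000) {
  stopifnot(inherits(result, "accessibility_result"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("per-capita factor must be a single positive number")
  result$scores <- result$scores * factor
  result$per_capita_factor <-
    factor * (if (is.null(result$per_capita_factor)) 1
              else result$per_capita_factor)
  result
}

#' Min-max normalize accessibility scores to [0, 1]
#'
#' `(x - min) / (max - min)`, with the minimum and maximum taken over the
#' report-region blocks only by default: buffer blocks are computational
#' scaffolding and would distort the range.  If all in-scope scores are
#' equal the normalized scores are all 0, with a warning.
#'
#' @param result an `accessibility_result`.
#' @param region_only restrict scope to `in_report_region` blocks
#'   (default `TRUE`).
#' @return Named numeric vector of normalized scores over the in-scope
#'   blocks.
#' @export
min_max_normalize <- function(result, region_only = TRUE) {
  stopifnot(inherits(result, "accessibility_result"))
  scope <- if (region_only) result$blocks$in_report_region
           else rep(TRUE, nrow(result$blocks))
  if (!any(scope)) stop("no blocks in scope for normalization")
  x <- result$scores[result$blocks$block_id[scope]]
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("all in-scope scores equal; normalized scores set to 0")
    return(stats::setNames(numeric(length(x)), names(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Classify scores into ordered accessibility classes
#'
#' Assigns each score to a half-open class `[b_i, b_{i+1})`, the top class
#' closed at its upper bound.  The default raw breaks follow the common
#' per-1,000 map legend (very poor 0-2, then 2-3, 3-4, 4-5, 5-8); the
#' normalized breaks are even fifths of \[0, 1\].  Scores are classed
#' unrounded.
#'
#' @param scores named numeric vector.
#' @param breaks ordered class boundaries including both endpoints;
#'   `length(breaks) - 1` classes.
#' @return Named ordered factor of class labels `"lo-hi"` per block.
#' @examples
#' classify(c(a = 1.5, b = 6), breaks = c(0, 2, 3, 4, 5, 8))
#' @export
classify <- function(scores, breaks = c(0, 2, 3, 4, 5, 8)) {
  breaks <- as.numeric(breaks)
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  above <- scores > breaks[length(breaks)] | scores < breaks[1]
  if (any(above))
    stop("score out of classification range for block(s): ",
         paste(names(scores)[above], collapse = ", "))
  labs <- paste0(format(breaks[-length(breaks)], trim = TRUE), "-",
                 format(breaks[-1], trim = TRUE))
  idx <- findInterval(scores, breaks, rightmost.closed = TRUE)
  stats::setNames(factor(labs[idx], levels = labs, ordered = TRUE),
                  names(scores))
}

#' Default breaks for normalized scores
#' @return Numeric vector `c(0, 0.2, 0.4, 0.6, 0.8, 1)`.
#' @export
normalized_breaks <- function() c(0, 0.2, 0.4, 0.6, 0.8, 1)

#' Per-block difference between two accessibility results
#'
#' `delta = score_a - score_b` for every compared block, classed by sign
#' into `under` (`delta < 0`), `equal` and `over` (`delta > 0`);
#' `|delta| <= zero_tol` counts as equal.  Subtracting the enhanced model
#' from the binary one, positive deltas mark blocks where ignoring
#' broadband quality overstates accessibility.  Aggregates block counts
#' and summed population per class.
#'
#' @param result_a,result_b `accessibility_result`s over the same block
#'   set, same `d0` and same per-capita scaling.
#' @param zero_tol absolute tolerance for "equal"; default 0 (exact), the
#'   right choice when both results come from the same pipeline.
#' @param region_only compare report-region blocks only (default `TRUE`).
#' @return List of class `difference_result`: `table` (`block_id`,
#'   `delta`, `diff_class`) and `summary` (`diff_class`, `n_blocks`,
#'   `population`).
#' @export
difference <- function(result_a, result_b, zero_tol = 0,
                       region_only = TRUE) {
  stopifnot(inherits(result_a, "accessibility_result"),
            inherits(result_b, "accessibility_result"))
  if (!setequal(result_a$blocks$block_id, result_b$blocks$block_id))
    stop("results cover different block sets")
  if (result_a$d0 != result_b$d0)
    stop("results use different catchment sizes")
  fa <- result_a$per_capita_factor
  fb <- result_b$per_capita_factor
  if (!identical(is.null(fa), is.null(fb)) ||
      (!is.null(fa) && fa != fb))
    stop("results use different per-capita scaling")
  blk <- result_a$blocks
  if (region_only) blk <- blk[blk$in_report_region, , drop = FALSE]
  delta <- result_a$scores[blk$block_id] - result_b$scores[blk$block_id]
  cls <- ifelse(abs(delta) <= zero_tol, "equal",
                ifelse(delta < 0, "under", "over"))
  cls <- factor(cls, levels = c("under", "equal", "over"))
  tab <- data.frame(block_id = blk$block_id, delta = unname(delta),
                    diff_class = cls, stringsAsFactors = FALSE)
  smry <- data.frame(
    diff_class = levels(cls),
    n_blocks = as.integer(table(cls)),
    population = as.numeric(tapply(blk$population, cls, sum,
                                   default = 0)),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, summary = smry),
            class = "difference_result")
}

#' @export
print.difference_result <- function(x, ...) {
  cat("<difference_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Summary statistics of an accessibility result
#'
#' Mean, standard deviation, minimum, maximum and block count over the
#' report-region blocks.  The population standard deviation (divisor `n`)
#' is the default, describing the realized score distribution rather than
#' estimating a sampled one.
#'
#' @param result an `accessibility_result`.
#' @param sample_sd use the sample standard deviation (divisor `n - 1`)
#'   instead.
#' @param region_only summarize report-region blocks only (default
#'   `TRUE`).
#' @return One-row `data.frame`: `method`, `metric`, `mean`, `std`,
#'   `min`, `max`, `count`.
#' @export
summarize_result <- function(result, sample_sd = FALSE,
                             region_only = TRUE) {
  stopifnot(inherits(result, "accessibility_result"))
  scope <- if (region_only) result$blocks$in_report_region
           else rep(TRUE, nrow(result$blocks))
  if (!any(scope)) stop("no blocks in scope for summary")
  x <- unname(result$scores[result$blocks$block_id[scope]])
  n <- length(x)
  v <- if (n > 1) sum((x - mean(x))^2) / (if (sample_sd) n - 1 else n)
       else 0
  data.frame(method = result$method,
             metric = if (is.null(result$metric)) NA_character_
                      else result$metric,
             mean = mean(x), std = sqrt(v), min = min(x), max = max(x),
             count = n, stringsAsFactors = FALSE)
}
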