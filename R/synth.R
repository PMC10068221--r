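# Deterministic synthetic study areas: a lattice of square blocks with a
# buffer ring, clustered supply, heterogeneous population, multi-provider
# broadband mixtures (including a digital-divide tier), and a lattice
# road graph.  Everything any pipeline stage needs, with no downloads.

#' Configuration for a synthetic study area
#'
#' The generated area is a `rows x cols` lattice of unit-square blocks.
#' The outer `buffer_width` ring is flagged as buffer (computed over,
#' never reported), emulating the buffer zone real studies draw around
#' their county to suppress edge effects.
#'
#' Population is log-normal per block (heavy right tail, like real block
#' populations).  Supply is Poisson with intensity decaying exponentially
#' with distance from a few cluster centers, emulating the downtown
#' concentration of providers.  Each block draws a broadband tier --
#' digital-divide (every offered speed below 0.6 Mbps), DSL-like,
#' cable-like or fiber-like -- and then a uniform number of providers
#' whose speeds are drawn from that tier's ranges.  Road edges connect
#' lattice neighbours with uniform traversal minutes.
#'
#' @param rows,cols lattice dimensions, each `>= 2`.
#' @param seed integer seed fixing every draw.
#' @param buffer_width width of the buffer ring in blocks (0 for none).
#' @param pop_meanlog,pop_sdlog log-normal population parameters.
#' @param n_clusters number of supply cluster centers.
#' @param cluster_intensity expected providers per block at a cluster
#'   center.
#' @param cluster_decay e-folding distance (in block widths) of the
#'   supply intensity.
#' @param providers_range integer range (min, max) of providers per
#'   block.
#' @param divide_prob probability a block falls in the digital-divide
#'   tier (all speeds `< 0.6` Mbps).
#' @param tier_probs probabilities of the DSL / cable / fiber tiers,
#'   rescaled to sum to `1 - divide_prob`.
#' @param edge_minutes_range range of per-edge traversal times
#'   (minutes).
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(rows = 10, cols = 10, seed = 1,
                            buffer_width = 1,
                            pop_meanlog = 5, pop_sdlog = 1,
                            n_clusters = 2, cluster_intensity = 8,
                            cluster_decay = 1.5,
                            providers_range = c(1, 6),
                            divide_prob = 0.08,
                            tier_probs = c(dsl = 0.25, cable = 0.45,
                                           fiber = 0.30),
                            edge_minutes_range = c(2, 6)) {
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols),
              seed = as.integer(seed),
              buffer_width = as.integer(buffer_width),
              pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
              n_clusters = as.integer(n_clusters),
              cluster_intensity = cluster_intensity,
              cluster_decay = cluster_decay,
              providers_range = as.integer(providers_range),
              divide_prob = divide_prob,
              tier_probs = tier_probs,
              edge_minutes_range = as.numeric(edge_minutes_range))
  if (cfg$rows < 2L || cfg$cols < 2L)
    stop("lattice must be at least 2x2")
  if (cfg$buffer_width < 0L ||
      cfg$rows - 2L * cfg$buffer_width < 1L ||
      cfg$cols - 2L * cfg$buffer_width < 1L)
    stop("buffer_width leaves no report-region blocks")
  if (cfg$divide_prob < 0 || cfg$divide_prob > 1)
    stop("divide_prob must be in [0, 1]")
  if (length(cfg$providers_range) != 2L ||
      cfg$providers_range[1] < 1L || diff(cfg$providers_range) < 0L)
    stop("providers_range must be an increasing pair of integers >= 1")
  if (length(cfg$edge_minutes_range) != 2L ||
      cfg$edge_minutes_range[1] <= 0 ||
      diff(cfg$edge_minutes_range) < 0)
    stop("edge_minutes_range must be an increasing positive pair")
  if (cfg$cluster_decay <= 0 || cfg$cluster_intensity < 0 ||
      cfg$n_clusters < 0L)
    stop("invalid supply cluster parameters")
  structure(cfg, class = "scenario_config")
}

# speed ranges (Mbps) per broadband tier: down low/high, up low/high
tier_ranges <- list(
  divide = list(down = c(0.10, 0.55), up = c(0.10, 0.55)),
  dsl    = list(down = c(1, 10),      up = c(0.6, 3)),
  cable  = list(down = c(25, 300),    up = c(3, 35)),
  fiber  = list(down = c(300, 1000),  up = c(300, 1000))
)

#' Generate a synthetic study area
#'
#' Reproducible given `config$seed`: the same configuration always yields
#' byte-identical tables.  When `divide_prob > 0` at least one block is
#' guaranteed to come from the digital-divide tier, so the sub-0.6 Mbps
#' path of the step-wise weight function is always exercised.
#'
#' @param config a [scenario_config()].
#' @return List of class `scenario`: `blocks` (a [blocks()] table),
#'   `broadband` (a [broadband_records()] table), `graph` (a
#'   [road_graph()] with one node per block centroid), and `notes`
#'   (ground truth: digital-divide block ids, cluster center ids, the
#'   config).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  nr <- config$rows; nc <- config$cols
  n <- nr * nc
  row <- rep(seq_len(nr), each = nc)
  col <- rep(seq_len(nc), times = nr)
  id <- sprintf("%015d", seq_len(n))
  bw <- config$buffer_width
  inner <- row > bw & row <= nr - bw & col > bw & col <= nc - bw

  pop <- round(stats::rlnorm(n, config$pop_meanlog, config$pop_sdlog))

  # clustered supply: Poisson intensity decaying from sampled centers
  supply <- numeric(n)
  centers <- integer(0)
  if (config$n_clusters > 0L) {
    centers <- sample(which(inner), min(config$n_clusters, sum(inner)))
    lambda <- rowSums(vapply(centers, function(ct) {
      d <- sqrt((row - row[ct])^2 + (col - col[ct])^2)
      config$cluster_intensity * exp(-d / config$cluster_decay)
    }, numeric(n)))
    supply <- stats::rpois(n, lambda)
  }

  blk <- blocks(id, x = col - 0.5, y = row - 0.5, population = pop,
                supply = supply, in_report_region = inner)

  # per-block broadband tier, then per-provider speeds within the tier
  p_other <- config$tier_probs / sum(config$tier_probs) *
    (1 - config$divide_prob)
  tiers <- sample(c("divide", names(config$tier_probs)), n,
                  replace = TRUE, prob = c(config$divide_prob, p_other))
  if (config$divide_prob > 0 && !any(tiers == "divide"))
    tiers[sample.int(n, 1)] <- "divide"
  nprov <- sample(seq(config$providers_range[1], config$providers_range[2]),
                  n, replace = TRUE)
  bb_block <- rep(id, nprov)
  bb_tier <- rep(tiers, nprov)
  total <- sum(nprov)
  rng <- function(dir) vapply(bb_tier, function(t)
    tier_ranges[[t]][[dir]], numeric(2))
  rd <- rng("down"); ru <- rng("up")
  down <- round(stats::runif(total, rd[1, ], rd[2, ]), 2)
  up <- round(stats::runif(total, ru[1, ], ru[2, ]), 2)
  prov <- unlist(lapply(nprov, seq_len))
  bb <- broadband_records(bb_block, sprintf("isp%02d", prov), down, up)

  # lattice road graph: one node per centroid, 4-neighbour edges
  nodes <- data.frame(node_id = id, x = col - 0.5, y = row - 0.5,
                      stringsAsFactors = FALSE)
  right <- which(col < nc)
  upn <- which(row < nr)
  efrom <- c(id[right], id[upn])
  eto <- c(id[right + 1L], id[upn + nc])
  emin <- stats::runif(length(efrom), config$edge_minutes_range[1],
                       config$edge_minutes_range[2])
  graph <- road_graph(nodes,
                      data.frame(from_node = efrom, to_node = eto,
                                 minutes = emin,
                                 stringsAsFactors = FALSE))

  structure(list(blocks = blk, broadband = bb, graph = graph,
                 notes = list(divide_blocks = id[tiers == "divide"],
                              cluster_centers = id[centers],
                              config = config)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario> %d blocks (%d report, %d buffer), %d broadband records, %d digital-divide blocks\n",
    nrow(x$blocks), sum(x$blocks$in_report_region),
    sum(!x$blocks$in_report_region), nrow(x$broadband),
    length(x$notes$divide_blocks)))
  invisible(x)
}

#' Two-block fixture with the canonical worked speed lists
#'
#' A tiny study area carrying the two speed lists used throughout the
#' documentation: one block offering ten download speeds
#' (2, 3, 18, 25, 25, 35, 100, 500, 1000, 1000) -- whose modal set is
#' \{25, 1000\}, so `min_f = 25`, `max_f = 1000`, and `min_a = 2` -- and
#' one block offering ten upload speeds (0.5, 1.3, 2.0, 3.0, 3.0, 3.0,
#' 20.0, 35.0, 200.0, 1000.0), whose mean of 126.78 shows how badly the
#' average misrepresents a block's typical speed.  The unprinted
#' direction of each record mirrors the printed one (synthetic
#' completion, so the records are well-formed).
#'
#' @return List with `blocks` and `broadband` tables; the first block
#'   carries the download list, the second the upload list.
#' @export
worked_example_fixture <- function() {
  dl <- c(2, 3, 18, 25, 25, 35, 100, 500, 1000, 1000)
  ul <- c(0.5, 1.3, 2.0, 3.0, 3.0, 3.0, 20.0, 35.0, 200.0, 1000.0)
  blk <- blocks(c("170310102011004", "170318391002021"),
                x = c(0, 1), y = c(0, 0),
                population = c(100, 100), supply = c(0, 0))
  bb <- broadband_records(
    block_id = rep(blk$block_id, each = 10),
    provider_id = rep(sprintf("isp%02d", 1:10), times = 2),
    download_mbps = c(dl, ul),
    upload_mbps = c(dl, ul))
  list(blocks = blk, broadband = bb)
}
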