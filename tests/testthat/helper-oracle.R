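# Independent reference implementations used as oracles.  Everything here
# is deliberately naive (counting tables, if-chains, triple loops, path
# enumeration) and shares no code with the package internals it checks.

# modal set by explicit count-and-filter
oracle_modal_set <- function(x) {
  counts <- vapply(unique(x), function(v) sum(x == v), numeric(1))
  sort(unique(x)[counts == max(counts)])
}

oracle_agg <- function(speeds, metric) {
  switch(metric,
         avg = sum(speeds) / length(speeds),
         min_a = min(speeds),
         min_f = min(oracle_modal_set(speeds)),
         max_f = max(oracle_modal_set(speeds)))
}

# Table-1 step function as a literal if-chain
oracle_step <- function(x) {
  if (x < 0.6) 0 else if (x < 1.2) 0.33 else if (x < 3.0) 0.66 else 1
}

oracle_joint <- function(dd, du, sd_, su) {
  oracle_step(min(dd, du, sd_, su))
}

# per-block speeds aggregated naively: list(block_id -> c(down, up))
oracle_bb <- function(records, metric) {
  out <- list()
  for (id in unique(records$block_id)) {
    g <- records[records$block_id == id, ]
    out[[id]] <- c(oracle_agg(g$download_mbps, metric),
                   oracle_agg(g$upload_mbps, metric))
  }
  out
}

oracle_has_internet <- function(records, id) {
  g <- records[records$block_id == id, ]
  nrow(g) > 0 && any(g$download_mbps > 0 & g$upload_mbps > 0)
}

# Full two-step engine as a literal triple loop over blocks.
# wfun(k_id, j_id) -> weight in [0,1]; catchment membership is checked
# here against the long OD table (absent pair = unreachable).
oracle_engine <- function(blk, od, d0, wfun) {
  tt <- function(o, d) {
    hit <- od$origin == o & od$destination == d
    if (any(hit)) od$minutes[hit][1] else Inf
  }
  ids <- blk$block_id
  pop <- stats::setNames(blk$population, ids)
  sup <- stats::setNames(blk$supply, ids)
  R <- stats::setNames(numeric(0), character(0))
  for (j in ids[sup > 0]) {
    denom <- 0
    for (k in ids)
      if (tt(k, j) <= d0) denom <- denom + pop[[k]] * wfun(k, j)
    R[[j]] <- if (denom > 0) sup[[j]] / denom else 0
  }
  A <- stats::setNames(rep(0, length(ids)), ids)
  for (i in ids)
    for (j in names(R))
      if (tt(i, j) <= d0) A[[i]] <- A[[i]] + R[[j]] * wfun(i, j)
  list(scores = A, ratios = R)
}

# oracle engine specialised per method, building weights naively
oracle_method <- function(blk, od, d0, method, metric = NULL,
                          records = NULL) {
  wfun <- switch(method,
    "2sfca" = function(k, j) 1,
    "2svca" = function(k, j)
      as.numeric(oracle_has_internet(records, k) &&
                 oracle_has_internet(records, j)),
    "e2svca" = {
      bb <- oracle_bb(records, metric)
      function(k, j) {
        if (is.null(bb[[k]]) || is.null(bb[[j]])) return(0)
        oracle_joint(bb[[k]][1], bb[[k]][2], bb[[j]][1], bb[[j]][2])
      }
    })
  oracle_engine(blk, od, d0, wfun)
}

# all simple paths between two nodes of a small arc list; Inf if none
oracle_shortest <- function(arcs, from, to) {
  best <- Inf
  walk <- function(node, time, seen) {
    if (time >= best) return()
    if (node == to) { best <<- min(best, time); return() }
    nxt <- which(arcs$from == node & !(arcs$to %in% seen))
    for (e in nxt)
      walk(arcs$to[e], time + arcs$minutes[e], c(seen, arcs$to[e]))
  }
  walk(from, 0, from)
  best
}

# Hand-rolled random fixture: irregular OD sparsity, blocks with zero
# population/supply and blocks with no broadband record at all.
make_random_fixture <- function(seed, n = 12) {
  set.seed(seed)
  ids <- sprintf("%03d", sample(900, n))
  blk <- blocks(ids, x = runif(n, 0, 10), y = runif(n, 0, 10),
                population = rpois(n, 80) * rbinom(n, 1, 0.9),
                supply = rpois(n, 2),
                in_report_region = c(TRUE, runif(n - 1) < 0.8))
  pairs <- expand.grid(o = ids, d = ids, stringsAsFactors = FALSE)
  keep <- runif(nrow(pairs)) < 0.6 | pairs$o == pairs$d
  pairs <- pairs[keep, ]
  minutes <- ifelse(pairs$o == pairs$d, 0, runif(nrow(pairs), 1, 45))
  od <- od_pairs(pairs$o, pairs$d, minutes)
  covered <- ids[runif(n) < 0.85]
  nprov <- sample(1:4, length(covered), replace = TRUE)
  lows <- runif(sum(nprov)) < 0.15
  down <- round(ifelse(lows, runif(sum(nprov), 0.05, 0.55),
                       runif(sum(nprov), 0.6, 900)), 2)
  up <- round(ifelse(lows, runif(sum(nprov), 0.05, 0.55),
                     runif(sum(nprov), 0.6, 900)), 2)
  bb <- broadband_records(rep(covered, nprov),
                          sprintf("p%02d", unlist(lapply(nprov, seq_len))),
                          down, up)
  list(blocks = blk, od = od, broadband = bb)
}

table1 <- function() default_schedule()
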