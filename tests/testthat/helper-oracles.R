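# Independent brute-force oracles. Deliberately naive: plain loops and
# exhaustive enumeration, sharing no code path with the package.

# minimum-cost simple path by exhaustive DFS enumeration (graphs <= 8 nodes)
oracle_all_paths_cost <- function(network, from, to, weight = "travel_time_min") {
  e <- network$edges
  # expand bidirectional edges
  if (!"oneway" %in% names(e)) e$oneway <- 0
  rev <- e[e$oneway == 0, ]
  tmp <- rev$from_node; rev$from_node <- rev$to_node; rev$to_node <- tmp
  e <- rbind(e, rev)
  best <- Inf
  dfs <- function(node, visited, cost) {
    if (cost >= best) return(invisible(NULL))
    if (node == to) { best <<- cost; return(invisible(NULL)) }
    out <- e[e$from_node == node & !(e$to_node %in% visited), , drop = FALSE]
    for (i in seq_len(nrow(out)))
      dfs(out$to_node[i], c(visited, out$to_node[i]), cost + out[[weight]][i])
  }
  dfs(from, from, 0)
  best
}

# Bellman-Ford relaxation from one source over all nodes
oracle_bellman_ford <- function(network, from, weight = "travel_time_min") {
  e <- network$edges
  if (!"oneway" %in% names(e)) e$oneway <- 0
  rev <- e[e$oneway == 0, ]
  tmp <- rev$from_node; rev$from_node <- rev$to_node; rev$to_node <- tmp
  e <- rbind(e, rev)
  nodes <- network$nodes$node_id
  d <- setNames(rep(Inf, length(nodes)), nodes)
  d[from] <- 0
  for (iter in seq_along(nodes)) {
    for (i in seq_len(nrow(e))) {
      cand <- d[e$from_node[i]] + e[[weight]][i]
      if (cand < d[e$to_node[i]]) d[e$to_node[i]] <- cand
    }
  }
  d
}

# per-row argmin with lexicographic tie-break, by explicit scan
oracle_nearest <- function(time_mat) {
  out <- data.frame(area_id = character(0), facility_id = character(0),
                    cost = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(time_mat))) {
    best_id <- NA_character_; best <- Inf
    for (j in order(colnames(time_mat))) {
      if (time_mat[i, j] < best) {
        best <- time_mat[i, j]; best_id <- colnames(time_mat)[j]
      }
    }
    out <- rbind(out, data.frame(area_id = rownames(time_mat)[i],
                                 facility_id = best_id, cost = best,
                                 stringsAsFactors = FALSE))
  }
  out
}

oracle_iris_radius <- function(nearest_cost, iris_of_area) {
  out <- c()
  for (ir in unique(iris_of_area)) {
    vals <- sort(nearest_cost[iris_of_area == ir], decreasing = TRUE)
    out[ir] <- vals[1]
  }
  out
}

oracle_zap <- function(time_mat, radius_of_area) {
  lapply(seq_len(nrow(time_mat)), function(i) {
    m <- character(0)
    for (j in seq_len(ncol(time_mat)))
      if (time_mat[i, j] <= radius_of_area[i])
        m <- c(m, colnames(time_mat)[j])
    sort(m)
  })
}

oracle_pressure <- function(time_mat, population, n_professionals) {
  assigned <- setNames(rep(0, ncol(time_mat)), colnames(time_mat))
  nn <- oracle_nearest(time_mat)
  for (i in seq_len(nrow(nn)))
    assigned[nn$facility_id[i]] <- assigned[nn$facility_id[i]] + population[i]
  list(assigned = assigned, pressure = assigned / n_professionals)
}

oracle_pad <- function(costs, weights) {
  if (sum(weights) == 0) return(sum(costs) / length(costs))
  s <- 0; tw <- 0
  for (k in seq_along(costs)) {
    s <- s + weights[k] * costs[k]; tw <- tw + weights[k]
  }
  unname(s / tw)
}

oracle_aggregate <- function(values, units, pops, criterion) {
  out <- c()
  for (u in sort(unique(units))) {
    v <- values[units == u]; p <- pops[units == u]
    out[u] <- switch(criterion,
      min = sort(v)[1],
      max = sort(v, decreasing = TRUE)[1],
      mean = sum(v) / length(v),
      weighted_mean = if (sum(p) == 0) sum(v) / length(v)
                      else sum(v * p) / sum(p))
  }
  out
}

# sort-and-slice decile labels, 1 = highest value; tied values take the
# first (best) slice any of their occurrences falls in
oracle_decile <- function(values) {
  n <- length(values)
  ord <- order(values, decreasing = TRUE)
  slice <- ceiling(seq_len(n) * 10 / n)
  lab <- rep(NA_integer_, n)
  for (v in unique(values)) {
    pos <- which(values[ord] == v)
    lab[values == v] <- min(slice[pos])
  }
  lab
}

oracle_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  hits <- 0
  for (i in seq_along(a)) if (a[i] == b[i]) hits <- hits + 1
  100 * hits / length(a)
}

# Blom plotting-position scores via an explicit sort-based rank
oracle_blom <- function(x) {
  n <- length(x)
  r <- vapply(seq_len(n), function(i) {
    less <- sum(x < x[i]); ties <- sum(x == x[i])
    less + (ties + 1) / 2
  }, numeric(1))
  qnorm((r - 0.375) / (n + 0.25))
}
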