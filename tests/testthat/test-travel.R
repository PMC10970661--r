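test_that("euclidean costs follow plane geometry and unit arithmetic", {
  a <- data.frame(area_id = "A1", x = 1000, y = 1000, population = 10,
                  iris_id = "I1", commune_id = "C1", region_id = "R1")
  f <- data.frame(facility_id = c("F1", "F2"),
                  x = c(4000, 1000), y = c(5000, 1000),
                  facility_type = "gp", range_class = "proximity",
                  n_professionals = 1L)
  od <- euclidean_costs(a, f, speed_kmh = 60)
  # 3-4-5 triangle: dx 3000, dy 4000 -> 5000 m; 5 km at 60 km/h -> 5 min
  expect_equal(od$dist["A1", "F1"], 5000)
  expect_equal(od$time["A1", "F1"], 5)
  # coincident points cost zero
  expect_equal(od$dist["A1", "F2"], 0)
  expect_equal(od$time["A1", "F2"], 0)
  expect_error(euclidean_costs(a, f, speed_kmh = 0), "positive")
})

test_that("euclidean costs are translation- and rotation-invariant", {
  a <- make_areas(6, seed = 11)
  f <- make_facilities(4, seed = 12)
  base <- euclidean_costs(a, f)$dist
  # translate
  a2 <- a; a2$x <- a$x + 5e5; a2$y <- a$y - 2e5
  f2 <- f; f2$x <- f$x + 5e5; f2$y <- f$y - 2e5
  expect_equal(euclidean_costs(a2, f2)$dist, base, tolerance = 1e-9)
  # rotate by 30 degrees about the origin (then shift positive)
  th <- pi / 6
  rot <- function(d) {
    x <- d$x * cos(th) - d$y * sin(th) + 1e6
    y <- d$x * sin(th) + d$y * cos(th) + 1e6
    d$x <- x; d$y <- y; d
  }
  expect_equal(euclidean_costs(rot(a), rot(f))$dist, base,
               tolerance = 1e-6)
})

test_that("network costs match path enumeration on the triangle", {
  net <- triangle_network()
  a <- data.frame(area_id = "A1", x = 300, y = 300, population = 1,
                  iris_id = "I1", commune_id = "C1", region_id = "R1")
  f <- data.frame(facility_id = "F1", x = 2300, y = 300,
                  facility_type = "gp", range_class = "proximity",
                  n_professionals = 1L)
  od <- network_costs(a, f, net)
  # A-B-C (2+2=4) beats the direct A-C edge (5)
  expect_equal(od$time["A1", "F1"], 4)
  expect_equal(od$time["A1", "F1"],
               oracle_all_paths_cost(net, "A", "C"))
  # single-edge graph: cost is that edge's travel time
  net1 <- make_network(
    data.frame(node_id = c("P", "Q"), x = c(300, 1300), y = c(300, 300)),
    data.frame(from_node = "P", to_node = "Q", length_m = 1000,
               travel_time_min = 3.5))
  odq <- network_costs(a, transform(f, x = 1300), net1)
  expect_equal(odq$time["A1", "F1"], 3.5)
})

test_that("network costs equal brute-force oracles on random small graphs", {
  for (seed in 1:6) {
    n_nodes <- sample(4:8, 1)
    net <- random_network(n_nodes, seed = seed)
    # place one area at each node, one facility at each node
    a <- data.frame(area_id = paste0("A", net$nodes$node_id),
                    x = net$nodes$x, y = net$nodes$y, population = 1,
                    iris_id = "I1", commune_id = "C1", region_id = "R1")
    f <- data.frame(facility_id = paste0("F", net$nodes$node_id),
                    x = net$nodes$x, y = net$nodes$y,
                    facility_type = "gp", range_class = "proximity",
                    n_professionals = 1L)
    od <- network_costs(a, f, net)
    for (i in seq_len(nrow(net$nodes))) {
      bf <- oracle_bellman_ford(net, net$nodes$node_id[i])
      expect_equal(unname(od$time[i, ]),
                   unname(bf[net$nodes$node_id]),
                   tolerance = 1e-9,
                   info = sprintf("seed %d source %d", seed, i))
      # exhaustive simple-path enumeration on a sampled pair
      j <- sample(seq_len(nrow(net$nodes)), 1)
      expect_equal(od$time[i, j],
                   oracle_all_paths_cost(net, net$nodes$node_id[i],
                                         net$nodes$node_id[j]),
                   tolerance = 1e-9)
    }
  }
})

test_that("network costs scale linearly with edge travel times", {
  net <- random_network(7, seed = 40)
  a <- make_areas(5, seed = 41, extent = 5000)
  f <- make_facilities(3, seed = 42, extent = 5000)
  base <- network_costs(a, f, net)$time
  for (k in c(0.5, 2, 10)) {
    scaled_net <- net
    scaled_net$edges$travel_time_min <- net$edges$travel_time_min * k
    scaled <- network_costs(a, f, scaled_net)$time
    expect_equal(scaled, base * k, tolerance = 1e-9)
  }
})

test_that("triangle inequality holds for shortest-path costs", {
  net <- random_network(8, seed = 77)
  nodes <- net$nodes
  a <- data.frame(area_id = paste0("A", nodes$node_id), x = nodes$x,
                  y = nodes$y, population = 1, iris_id = "I1",
                  commune_id = "C1", region_id = "R1")
  f <- data.frame(facility_id = paste0("F", nodes$node_id), x = nodes$x,
                  y = nodes$y, facility_type = "gp",
                  range_class = "proximity", n_professionals = 1L)
  tt <- network_costs(a, f, net)$time
  for (i in seq_len(nrow(tt))) for (j in seq_len(ncol(tt)))
    for (k in seq_len(nrow(tt)))
      expect_lte(tt[i, j], tt[i, k] + tt[k, j] + 1e-9)
})

test_that("snapping respects the maximum snap distance", {
  net <- triangle_network()
  far <- data.frame(area_id = "A1", x = -5000, y = 300, population = 1,
                    iris_id = "I1", commune_id = "C1", region_id = "R1")
  f <- data.frame(facility_id = "F1", x = 2300, y = 300,
                  facility_type = "gp", range_class = "proximity",
                  n_professionals = 1L)
  expect_error(network_costs(far, f, net, max_snap_m = 5000),
               "snap distance")
  expect_silent(od <- network_costs(far, f, net, max_snap_m = 10000))
  # snap legs are zero-cost by default ...
  expect_equal(od$time["A1", "F1"], 4)
  # ... and added at walking speed when requested
  od_w <- network_costs(far, f, net, max_snap_m = 10000,
                        snap_speed_kmh = 5)
  expect_gt(od_w$time["A1", "F1"], od$time["A1", "F1"])
})

test_that("chunk plans honor range classes and keep nearest answers", {
  # two regions side by side; communes double as departments
  set.seed(8)
  n <- 40
  areas <- data.frame(
    area_id = sprintf("A%02d", 1:n),
    x = runif(n, 200, 19800), y = runif(n, 200, 9800),
    population = round(runif(n, 10, 300)),
    stringsAsFactors = FALSE)
  areas$region_id <- ifelse(areas$x < 10000, "R1", "R2")
  areas$commune_id <- paste0(areas$region_id, "-C",
                             1 + (areas$y > 5000))
  areas$iris_id <- paste0(areas$commune_id, "-I1")
  fac <- rbind(
    data.frame(facility_id = sprintf("F-gp-%02d", 1:6),
               x = c(2000, 5000, 8000, 12000, 15000, 18000), y = 5000,
               facility_type = "gp", range_class = "proximity",
               n_professionals = 1L, stringsAsFactors = FALSE),
    data.frame(facility_id = sprintf("F-em-%02d", 1:2),
               x = c(4000, 16000), y = 5000,
               facility_type = "emergency", range_class = "tertiary",
               n_professionals = 1L, stringsAsFactors = FALSE))
  adjacency <- rbind(
    data.frame(unit_id = "R1", neighbor_id = "R2", level = "region"),
    expand.grid(unit_id = c("R1-C1", "R1-C2"),
                neighbor_id = c("R2-C1", "R2-C2"),
                level = "department", stringsAsFactors = FALSE))
  chunks <- plan_chunks(areas, fac, adjacency)
  expect_length(chunks, 2)
  ch1 <- chunks[[which(vapply(chunks, `[[`, "", "region_id") == "R1")]]
  facu <- facility_units(fac, areas)
  # proximity candidates include neighbor-department facilities
  expect_true(all(facu$facility_id[facu$region_id == "R1" &
                                     facu$range_class == "proximity"]
                  %in% ch1$candidates$proximity))
  expect_true(any(facu$region_id[match(ch1$candidates$proximity,
                                       facu$facility_id)] == "R2"))
  # tertiary candidates include the neighboring region's facilities
  expect_setequal(ch1$candidates$tertiary, fac$facility_id)

  # chunked vs unchunked nearest-GP must agree (candidate sets cover all)
  gp <- fac[fac$facility_type == "gp", ]
  od <- euclidean_costs(areas, gp)
  whole <- nearest_per_area(od, "gp")
  chunked <- do.call(rbind, lapply(chunks, function(ch) {
    cand <- intersect(ch$candidates$proximity, gp$facility_id)
    nearest_per_area(od_subset(od, ch$area_ids, cand), "gp")
  }))
  chunked <- chunked[match(whole$area_id, chunked$area_id), ]
  expect_equal(whole$nearest_facility_id, chunked$nearest_facility_id)
  expect_equal(whole$nearest_cost, chunked$nearest_cost)

  bad_adj <- adjacency
  bad_adj$unit_id[bad_adj$level == "region"] <- "R2"
  bad_adj$neighbor_id[bad_adj$level == "region"] <- "R3"
  expect_error(plan_chunks(areas, fac, bad_adj), "absent from adjacency")

  # a single region with no declared neighbors is one chunk with all
  one <- areas; one$region_id <- "R1"
  no_adj <- adjacency[0, ]
  ch <- plan_chunks(one, fac, no_adj)
  expect_length(ch, 1)
  expect_setequal(ch[[1]]$area_ids, one$area_id)
  expect_setequal(ch[[1]]$candidates$proximity, fac$facility_id)
  expect_setequal(ch[[1]]$candidates$tertiary, fac$facility_id)
})
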