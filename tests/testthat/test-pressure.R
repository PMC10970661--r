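test_that("Voronoi pressure assigns each population to its nearest facility", {
  areas <- data.frame(area_id = c("A1", "A2", "A3"),
                      x = c(1000, 9000, 4000), y = 1000,
                      population = c(100, 50, 30),
                      iris_id = "I1", commune_id = "C1", region_id = "R1")
  fac <- data.frame(facility_id = c("F1", "F2"), x = c(200, 10200),
                    y = 1000, facility_type = "gp",
                    range_class = "proximity", n_professionals = 1L)
  # hand-derived: A1 (x=1000) and A3 (x=4000) are nearer F1 (x=200);
  # A2 (x=9000) is nearer F2 (x=10200): {F1: 130, F2: 50}
  pt <- compute_pressure(areas, fac, euclidean_costs(areas, fac))
  expect_equal(setNames(pt$assigned_population, pt$facility_id),
               c(F1 = 130, F2 = 50))

  # single facility captures everything
  one <- fac[1, ]
  pt1 <- compute_pressure(areas, one, euclidean_costs(areas, one))
  expect_equal(pt1$assigned_population, sum(areas$population))

  # pressure divides by the professional head count
  fac2 <- fac; fac2$n_professionals <- c(2L, 1L)
  pt2 <- compute_pressure(areas, fac2, euclidean_costs(areas, fac2))
  expect_equal(pt2$pressure[pt2$facility_id == "F1"], 130 / 2)
})

test_that("population is conserved across random fixtures", {
  for (seed in 1:10) {
    areas <- make_areas(sample(10:50, 1), seed = seed)
    fac <- make_facilities(sample(2:10, 1), seed = seed + 500)
    pt <- compute_pressure(areas, fac, euclidean_costs(areas, fac))
    expect_equal(sum(pt$assigned_population), sum(areas$population))
    orc <- oracle_pressure(euclidean_costs(areas, fac)$time,
                           areas$population, fac$n_professionals)
    expect_equal(setNames(pt$assigned_population, pt$facility_id),
                 orc$assigned[pt$facility_id])
    expect_equal(setNames(pt$pressure, pt$facility_id),
                 orc$pressure[pt$facility_id])
  }
})

test_that("PAD is the pressure-weighted mean with unweighted fallback", {
  # hand computation: (2*100 + 6*50) / 150 = 500/150
  expect_equal(compute_pad(c(F1 = 2, F2 = 6), c(F1 = 100, F2 = 50)),
               500 / 150)
  # singleton ZAP returns the single cost whatever the pressure
  expect_equal(compute_pad(c(F1 = 7), c(F1 = 3)), 7)
  expect_equal(compute_pad(c(F1 = 7), c(F1 = 0)), 7)
  # all-zero pressures fall back to the plain mean
  expect_equal(compute_pad(c(F1 = 2, F2 = 6), c(F1 = 0, F2 = 0)), 4)
  expect_error(compute_pad(c(F1 = 2, F9 = 6), c(F1 = 1)),
               "missing pressure")
})

test_that("pad_all matches a brute-force weighted mean on random fixtures", {
  for (seed in 1:6) {
    areas <- make_areas(10, seed = seed,
                        iris = rep(c("I1", "I2"), each = 5))
    types <- c("gp", "nurse", "dentist")
    fac <- do.call(rbind, lapply(types, function(ty)
      make_facilities(4, seed = seed + match(ty, types) * 50, type = ty)))
    od <- euclidean_costs(areas, fac)
    zaps <- list(); pressures <- list()
    for (ty in types) {
      ft <- fac[fac$facility_type == ty, ]
      odt <- od_subset(od, NULL, ft$facility_id)
      radii <- iris_radius(nearest_per_area(odt, ty), areas)
      zaps[[ty]] <- zap_members(odt, radii, areas, ty)
      pressures[[ty]] <- compute_pressure(areas, ft, odt)
    }
    pads <- pad_all(zaps, od, pressures)
    expect_equal(nrow(pads), nrow(areas) * length(types))
    pvec <- setNames(do.call(rbind, pressures)$pressure,
                     do.call(rbind, pressures)$facility_id)
    for (ty in types) {
      z <- zaps[[ty]]
      for (i in seq_len(nrow(z))) {
        costs <- od$time[z$area_id[i], z$members[[i]]]
        expected <- oracle_pad(costs, pvec[z$members[[i]]])
        got <- pads$pad[pads$area_id == z$area_id[i] &
                          pads$facility_type == ty]
        expect_equal(got, expected, tolerance = 1e-12)
        # PAD bounded by the ZAP's cost range
        expect_gte(got, min(costs) - 1e-12)
        expect_lte(got, max(costs) + 1e-12)
      }
    }
  }
})

test_that("PAD is homogeneous in costs and scale-free in pressures", {
  areas <- make_areas(8, seed = 71, iris = rep(c("I1", "I2"), each = 4))
  fac <- make_facilities(5, seed = 72)
  od <- euclidean_costs(areas, fac)
  radii <- iris_radius(nearest_per_area(od, "gp"), areas)
  zaps <- zap_members(od, radii, areas, "gp")
  pr <- compute_pressure(areas, fac, od)
  base <- pad_all(zaps, od, pr)

  # scaling every cost by k scales every PAD by k (same ZAPs: radii scale too)
  for (k in c(0.5, 2, 10)) {
    odk <- scaleaccess:::new_od(od$time * k, od$dist * k, od$metric)
    radk <- iris_radius(nearest_per_area(odk, "gp"), areas)
    zk <- zap_members(odk, radk, areas, "gp")
    pk <- pad_all(zk, odk, pr)
    expect_equal(pk$pad, base$pad * k, tolerance = 1e-12)
  }

  # uniform rescaling of pressures cancels in the weighted mean
  pr2 <- pr; pr2$pressure <- pr$pressure * 37.5
  expect_equal(pad_all(zaps, od, pr2)$pad, base$pad, tolerance = 1e-12)

  # adding a member at exactly the current PAD leaves the PAD unchanged
  z1 <- zaps[1, ]
  costs <- setNames(od$time[z1$area_id, z1$members[[1]]], z1$members[[1]])
  pvec <- setNames(pr$pressure, pr$facility_id)
  pad0 <- compute_pad(costs, pvec)
  costs2 <- c(costs, FX = pad0)
  expect_equal(compute_pad(costs2, c(pvec, FX = 5)), pad0,
               tolerance = 1e-12)
})

test_that("inverse-pressure weighting favors available facilities", {
  costs <- c(F1 = 2, F2 = 6)
  press <- c(F1 = 100, F2 = 10)
  # pressure mode leans toward the loaded F1 (cost 2)
  expect_lt(compute_pad(costs, press, "pressure"),
            mean(costs))
  # inverse mode leans toward the available F2 (cost 6)
  expect_gt(compute_pad(costs, press, "inverse_pressure"),
            mean(costs))
})
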