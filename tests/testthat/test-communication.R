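test_that("shortest paths are exact, canonical and fail gracefully", {
  p3 <- make_canonical_graph("path", 3)
  sp <- shortest_paths(unit_length_matrix(p3))
  expect_equal(unname(sp$dist[1, 3]), 2)
  expect_equal(shortest_path_nodes(sp, 1, 3), c(1L, 2L, 3L))
  # six-node fixture: fewest-hop route i -> j is the 2-hop path via b
  fix <- make_toy_network()
  spf <- shortest_paths(unit_length_matrix(fix))
  expect_equal(unname(spf$dist["i", "j"]), 2)
  expect_identical(fix$labels[shortest_path_nodes(spf, 1, 6)],
                   c("i", "b", "j"))
  # disconnected pair
  two <- weighted_network(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                                c(0, 0, 0, 1), c(0, 0, 1, 0)))
  spd <- shortest_paths(unit_length_matrix(two))
  expect_true(is.infinite(spd$dist[1, 3]))
  expect_length(shortest_path_nodes(spd, 1, 3), 0)
  neg <- matrix(c(Inf, -1, -1, Inf), 2)
  expect_error(shortest_paths(neg), "negative")
})

test_that("weighted shortest distances agree with exhaustive enumeration", {
  for (seed in 1:4) {
    net <- random_connected_network(7, density = 0.5, seed = seed)
    len <- weight_to_length(net)
    sp <- shortest_paths(len)
    for (s in 1:3) {
      for (t in 5:7) {
        expect_equal(sp$dist[s, t], brute_force_shortest(len, s, t),
                     tolerance = 1e-12)
        # the canonical path realizes the optimal distance
        path <- shortest_path_nodes(sp, s, t)
        steps <- cbind(path[-length(path)], path[-1])
        expect_equal(sum(len[steps]), sp$dist[s, t], tolerance = 1e-12)
      }
    }
  }
})

test_that("shortest-path efficiency is symmetric on undirected networks", {
  p3 <- make_canonical_graph("path", 3)
  esp <- shortest_path_efficiency(unit_length_matrix(p3))
  expect_equal(unname(esp[1, 3]), 0.5)
  expect_equal(unname(esp[3, 1]), 0.5)
  for (seed in 1:3) {
    net <- random_connected_network(12, seed = seed)
    esp <- shortest_path_efficiency(weight_to_length(net))
    expect_identical(esp, t(esp))   # exact, not approximate
  }
  # direct edge of length l has efficiency 1/l
  one <- weighted_network(matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(shortest_path_efficiency(weight_to_length(one))[1, 2]),
               1 / log10(2))
})

test_that("greedy navigation realizes the geometric routes of the fixture", {
  fix <- make_toy_network()
  nav <- navigate(fix, lengths = unit_length_matrix(fix))
  expect_equal(unname(nav$hops["i", "j"]), 3)
  expect_identical(fix$labels[nav$paths[[1]][[6]]], c("i", "c", "b", "j"))
  expect_equal(unname(nav$hops["j", "i"]), 2)
  expect_identical(fix$labels[nav$paths[[6]][[1]]], c("j", "b", "i"))
  en <- navigation_efficiency(nav, binary = TRUE)
  expect_equal(unname(en["i", "j"]), 1 / 3)
  expect_equal(unname(en["j", "i"]), 0.5)
})

test_that("navigation fails on revisits (greedy dead end)", {
  # s's closest-to-target neighbor is a dead end that routes back to s
  labels <- c("s", "a", "d", "t")
  coords <- rbind(s = c(0, 0), a = c(5, 3), d = c(2, -1), t = c(10, 0))
  w <- matrix(0, 4, 4, dimnames = list(labels, labels))
  w["s", "a"] <- w["s", "d"] <- w["d", "t"] <- 1
  w <- pmax(w, t(w))
  net <- weighted_network(w, coordinates = coords)
  nav <- navigate(net, lengths = unit_length_matrix(net))
  expect_true(is.infinite(nav$hops["s", "t"]))
  expect_true(is.infinite(nav$pathlength["s", "t"]))
  expect_equal(unname(navigation_efficiency(nav, binary = TRUE)["s", "t"]), 0)
  expect_error(navigate(weighted_network(w)), "coordinates")
})

test_that("navigation efficiency never beats shortest-path efficiency", {
  for (seed in 1:4) {
    net <- random_connected_network(15, density = 0.35, seed = seed,
                                    coords = TRUE)
    len <- weight_to_length(net)
    esp <- shortest_path_efficiency(len)
    en <- navigation_efficiency(navigate(net, lengths = len))
    expect_true(all(en <= esp + 1e-12))
  }
})

test_that("transition matrix is row-stochastic with correct probabilities", {
  fix <- make_toy_network()
  tm <- transition_matrix(fix)
  expect_equal(unname(tm["i", c("x", "c", "b")]), rep(1 / 3, 3))
  expect_equal(unname(tm["j", "b"]), 1)
  expect_equal(unname(rowSums(tm)), rep(1, 6))
  iso <- weighted_network(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)),
                          labels = c("a", "b", "z"))
  expect_error(transition_matrix(iso), "zero-strength.*z")
})

test_that("hitting times match closed forms and the first-step oracle", {
  # single forced step on a dyad
  dyad <- weighted_network(matrix(c(0, 1, 1, 0), 2))
  de <- diffusion_efficiency(dyad)
  expect_equal(unname(de$hitting), rbind(c(0, 1), c(1, 0)))
  expect_equal(unname(de$eff), rbind(c(0, 1), c(1, 0)))
  # 3-node path: end-to-end expected hops = 4
  p3 <- make_canonical_graph("path", 3)
  dp <- diffusion_efficiency(p3)
  expect_equal(unname(dp$hitting[1, 3]), 4)
  expect_equal(unname(dp$eff[1, 3]), 0.25)
  # complete graphs: H = n - 1 for every ordered pair
  for (n in 3:6) {
    kn <- make_canonical_graph("complete", n)
    h <- diffusion_efficiency(kn)$hitting
    expect_equal(unname(h), (n - 1) * (1 - diag(n)), tolerance = 1e-12)
  }
  # six-node fixture worked values
  fix <- make_toy_network()
  hf <- diffusion_efficiency(fix)$hitting
  expect_equal(unname(hf["i", "j"]), 43 / 3, tolerance = 1e-12)
  expect_equal(unname(hf["j", "i"]), 17 / 3, tolerance = 1e-12)
  ef <- diffusion_efficiency(fix)$eff
  expect_true(ef["j", "i"] > ef["i", "j"])
  # random graphs: geometric-series route equals first-step equations
  for (seed in 1:4) {
    net <- random_connected_network(10, seed = seed)
    expect_equal(unname(diffusion_efficiency(net)$hitting),
                 hitting_times_first_step(net), tolerance = 1e-9)
  }
  # cross-component pairs are unreachable
  two <- weighted_network(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                                c(0, 0, 0, 1), c(0, 0, 1, 0)))
  dt <- diffusion_efficiency(two)
  expect_true(is.infinite(dt$hitting[1, 3]))
  expect_equal(unname(dt$eff[1, 3]), 0)
})

test_that("search information follows walk probabilities along the path", {
  fix <- make_toy_network()
  len <- unit_length_matrix(fix)
  esi <- search_information_efficiency(fix, lengths = len)
  expect_equal(unname(esi["j", "i"]), -2)           # P = 1 * 1/4
  expect_equal(unname(esi["i", "j"]), -log2(12))    # P = 1/3 * 1/4
  p3 <- make_canonical_graph("path", 3)
  esi3 <- search_information_efficiency(p3, lengths = unit_length_matrix(p3))
  expect_equal(unname(esi3[1, 3]), -1)              # P = 1 * 1/2
  # unreachable pairs take the -Inf sentinel
  two <- weighted_network(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                                c(0, 0, 0, 1), c(0, 0, 1, 0)))
  esid <- search_information_efficiency(two,
                                        lengths = unit_length_matrix(two))
  expect_true(is.infinite(esid[1, 3]) && esid[1, 3] < 0)
})

test_that("all-paths mode sums probability over co-optimal routes", {
  # 4-cycle: two symmetric 2-hop routes between opposite corners, each with
  # walk probability (1/2) * (1/2)
  c4 <- make_canonical_graph("cycle", 4)
  len <- unit_length_matrix(c4)
  canon <- search_information_efficiency(c4, lengths = len)
  allp <- search_information_efficiency(c4, lengths = len, mode = "all")
  expect_equal(unname(canon[1, 3]), log2(0.25))
  expect_equal(unname(allp[1, 3]), log2(0.5))
  # with a unique shortest path the two modes coincide
  for (seed in 1:2) {
    net <- random_connected_network(8, seed = seed)
    wl <- weight_to_length(net)
    expect_equal(search_information_efficiency(net, lengths = wl),
                 search_information_efficiency(net, lengths = wl,
                                               mode = "all"),
                 tolerance = 1e-9)
  }
})

test_that("uniform complete graphs are fully symmetric for all measures", {
  k5 <- make_canonical_graph("complete", 5)
  len <- unit_length_matrix(k5)
  esp <- shortest_path_efficiency(len)
  nav <- navigate(k5, lengths = len)
  en <- navigation_efficiency(nav, binary = TRUE)
  ed <- diffusion_efficiency(k5)$eff
  esi <- search_information_efficiency(k5, lengths = len)
  off <- !diag(5)
  expect_true(all(nav$hops[off] == 1))
  for (m in list(esp, en, ed, esi)) {
    expect_equal(m, t(m), tolerance = 1e-12)
  }
})

test_that("cohort tensors stack identical pipelines per subject", {
  net <- random_connected_network(10, seed = 3, coords = TRUE)
  subjects <- list(net, net, net)
  tens <- cohort_communication(subjects, "dif")
  expect_equal(dim(tens), c(10, 10, 3))
  expect_equal(tens[, , 1], tens[, , 3])
  single <- cohort_communication(list(net), "dif")
  expect_equal(single[, , 1], unclass(communication_matrix(net, "dif")),
               ignore_attr = TRUE)
  # sp slices inherit exact symmetry
  tsp <- cohort_communication(subjects, "sp", density = 0.3)
  for (k in 1:3) expect_identical(tsp[, , k], t(tsp[, , k]))
  # label mismatch is reported with the subject
  other <- weighted_network(net$weights, labels = paste0("X", 1:10))
  expect_error(cohort_communication(list(net, other), "sp"), "subject 2")
})
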