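test_that("child records round-trip through CSV and invalid rows are rejected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  ch <- tibble::tibble(child_id = c("k1", "k2", "k3"),
                       cluster_id = c("c1", "c1", "c2"),
                       time_months = c(12, 59.5, 0.5),
                       event = c(1L, 0L, 0L),
                       sex = c("m", "f", "f"))
  readr::write_csv(ch, tmp)
  back <- read_children(tmp)
  expect_equal(as.data.frame(back), as.data.frame(ch))

  readr::write_csv(dplyr::mutate(ch, event = c(1L, 2L, 0L)), tmp)
  expect_error(read_children(tmp), "invalid child record")
  readr::write_csv(dplyr::mutate(ch, time_months = c(-1, 3, 4)), tmp)
  expect_error(read_children(tmp), "invalid child record")
  readr::write_csv(ch[, setdiff(names(ch), "event")], tmp)
  expect_error(read_children(tmp), "required column")
})

test_that("a generated survey written to disk re-reads identically", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_clusters = 20, n_children = 150, seed = 42)
  sv <- generate_survey(cfg, out_dir = dir)
  back <- read_children(file.path(dir, "children.csv"))
  expect_equal(as.data.frame(back), as.data.frame(sv$children))
  cl <- read_clusters(file.path(dir, "clusters.csv"))
  expect_equal(as.data.frame(cl), as.data.frame(sv$clusters))
  cov <- read_coverage(file.path(dir, "coverage.csv"))
  expect_equal(as.data.frame(cov), as.data.frame(sv$coverage))
  edges <- read_adjacency(file.path(dir, "adjacency.txt"))
  expect_equal(as.data.frame(edges), as.data.frame(sv$adjacency))
})

test_that("haversine matrix matches the per-pair great-circle formula", {
  # one degree of latitude at the equator on the 6371 km sphere
  d <- haversine_matrix(rbind(c(0, 0), c(0, 1)))
  expect_equal(d[1, 2], 6371 * pi / 180, tolerance = 0.1 / 111)
  expect_equal(haversine_matrix(rbind(c(3, 7), c(3, 7)))[1, 2], 0)

  set.seed(5)
  pts <- cbind(runif(3, -180, 180), runif(3, -90, 90))
  d <- haversine_matrix(pts)
  # independent scalar oracle: spherical law of haversines
  hav_ref <- function(p1, p2) {
    r <- pi / 180
    dlat <- (p2[2] - p1[2]) * r; dlon <- (p2[1] - p1[1]) * r
    a <- sin(dlat / 2)^2 + cos(p1[2] * r) * cos(p2[2] * r) * sin(dlon / 2)^2
    2 * 6371 * asin(sqrt(a))
  }
  for (i in 1:3) for (j in 1:3) {
    expect_equal(d[i, j], hav_ref(pts[i, ], pts[j, ]), tolerance = 1e-9)
  }
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  # invariance under relabeling
  perm <- c(3, 1, 2)
  expect_equal(haversine_matrix(pts[perm, ]), d[perm, perm])
  expect_error(haversine_matrix(rbind(c(0, 95), c(1, 1))), "out of range")
})

test_that("region graph builds C, D and the gamma eigen-bounds", {
  g2 <- two_region_graph()
  expect_equal(unname(g2$C), matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(g2$D), c(1, 1))
  expect_equal(g2$gamma_bounds, c(-1, 1))

  g3 <- path3_graph()
  expect_equal(unname(g3$g), c(1, 2, 1))
  expect_equal(unname(rowSums(g3$C)), rep(1, 3))

  # random connected graph: eigenvalues of D^{-1/2} C D^{1/2} real, max 1
  set.seed(11)
  repeat {
    om <- matrix(0, 6, 6)
    om[upper.tri(om)] <- rbinom(15, 1, 0.5)
    om <- om + t(om)
    if (all(rowSums(om) > 0) && svcsurv:::graph_connected(om)) break
  }
  idx <- which(upper.tri(om) & om == 1, arr.ind = TRUE)
  g6 <- region_graph(tibble::tibble(from = LETTERS[idx[, 1]],
                                    to = LETTERS[idx[, 2]]),
                     region_ids = LETTERS[1:6])
  expect_true(all(abs(Im(g6$eigenvalues)) == 0))
  expect_equal(max(g6$eigenvalues), 1, tolerance = 1e-10)

  # D^{-1}(I - gamma C) is symmetric and the CAR covariance is SPD strictly
  # inside the bounds
  for (gam in c(0.99 * g6$gamma_bounds[1], 0, 0.5, 0.99 * g6$gamma_bounds[2])) {
    M <- diag(g6$g) %*% (diag(6) - gam * g6$C)
    expect_lt(max(abs(M - t(M))), 1e-10)
    S <- car_covariance(g6, 1.3, gam)
    expect_lt(max(abs(S - t(S))), 1e-10)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("degenerate region graphs are rejected or flagged", {
  expect_error(region_graph(tibble::tibble(from = "A", to = "B"),
                            region_ids = c("A", "B", "C")),
               "isolated region")
  expect_warning(region_graph(tibble::tibble(from = c("A", "C"),
                                             to = c("B", "D"))),
                 "not connected")
  expect_error(region_graph(tibble::tibble(from = "A", to = "Z"),
                            region_ids = c("A", "B")), "unknown region")
})

test_that("coverage tables accept percentages and enforce range", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("region_id,x\nA,45.3\nB,0.9", tmp)
  cov <- read_coverage(tmp)
  expect_equal(cov$x, c(0.453, 0.009))
  writeLines("region_id,x\nA,145\nB,90", tmp)
  expect_error(read_coverage(tmp), "exceeds")
  expect_equal(sort(setdiff(names(burkina_coverage()), "region_id")),
               sort(intervention_names()))
})
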