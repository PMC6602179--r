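# shared in-code fixtures; everything is generated, nothing read from disk
# except the shipped extdata tables

two_region_graph <- function() {
  region_graph(tibble::tibble(from = "A", to = "B"))
}

path3_graph <- function() {
  region_graph(tibble::tibble(from = c("A", "B"), to = c("B", "C")),
               region_ids = c("A", "B", "C"))
}

# q-cluster frame with clusters split over two regions
tiny_frame <- function(m = 4, seed = 7) {
  set.seed(seed)
  spatial_frame(tibble::tibble(
    cluster_id = sprintf("c%d", seq_len(m)),
    lon = runif(m, -1, 1), lat = runif(m, 11, 13),
    region_id = rep(c("A", "B"), length.out = m)))
}

tiny_children <- function(n = 12, frame = tiny_frame(), seed = 8) {
  set.seed(seed)
  tibble::tibble(
    child_id = sprintf("k%d", seq_len(n)),
    cluster_id = sample(frame$clusters$cluster_id, n, replace = TRUE),
    time_months = runif(n, 0.5, 59),
    event = rbinom(n, 1, 0.4),
    grp = sample(c("x", "y"), n, replace = TRUE))
}

tiny_coverage <- function() {
  tibble::tibble(region_id = c("A", "B"), cov_x = c(0.5, 0.8))
}

tiny_model <- function(n = 12, adjust = character(), seed = 8) {
  frame <- tiny_frame()
  svc_model(tiny_children(n, frame, seed), frame, two_region_graph(),
            tiny_coverage(), "cov_x", adjust = adjust)
}

# small survey for two-group survival fits: group "b" has hazard ratio hr
two_group_data <- function(n, hr, delta = 1, seed = 1) {
  set.seed(seed)
  grp <- rep(c("a", "b"), length.out = n)
  eta <- log(hr) * (grp == "b") - 1
  t_raw <- (-log(runif(n)) * exp(-eta))^(1 / delta)
  cens <- runif(n, 0, 60)
  tibble::tibble(time_months = pmax(pmin(t_raw, cens), 0.01),
                 event = as.integer(t_raw < cens), grp = grp)
}

# independent dense-normal log density for cross-checking the package's
# precision-based GP/CAR densities
dmvnorm_log_ref <- function(x, Sigma) {
  k <- length(x)
  -0.5 * (k * log(2 * pi) +
            as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
            drop(x %*% solve(Sigma) %*% x))
}
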