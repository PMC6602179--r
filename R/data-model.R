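#' Read a child-record table
#'
#' Reads the per-child survival table: one row per child with time to death or
#' censoring (months), an event indicator, the survey cluster the child
#' belongs to, and any number of categorical or continuous covariate columns.
#'
#' Rows violating the record invariants (`time_months` in (0, 60],
#' `event` in {0, 1}) are dropped with a warning naming the offending rows.
#' Rows with missing values in `time_months`, `event` or `cluster_id` are
#' dropped the same way (complete-case policy); missing covariate values are
#' left to the modelling stage, which excludes them complete-case with a
#' logged count.
#'
#' @param path Path to a UTF-8 CSV with a header row and at least the columns
#'   `child_id`, `cluster_id`, `time_months`, `event`.
#' @return A tibble of validated child records.
#' @export
read_children <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("child_id", "cluster_id", "time_months", "event")
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols) > 0) {
    abort(paste0("children file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_children(dat)
}

validate_children <- function(dat) {
  dat$time_months <- as.numeric(dat$time_months)
  dat$event <- as.integer(dat$event)
  # month-resolution surveys record same-day deaths as age 0; shift them to
  # the conventional mid-first-week value so log(t) is defined
  zero_death <- !is.na(dat$time_months) & dat$time_months == 0 &
    !is.na(dat$event) & dat$event == 1L
  if (any(zero_death)) {
    message(sum(zero_death), " death(s) recorded at 0 months shifted to 0.25")
    dat$time_months[zero_death] <- 0.25
  }
  bad <- !is.finite(dat$time_months) | dat$time_months <= 0 |
    dat$time_months > 60 | !(dat$event %in% c(0L, 1L)) | is.na(dat$cluster_id)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    abort(paste0("invalid child record(s) at row(s): ",
                 paste(head(which(bad), 10), collapse = ", "),
                 if (sum(bad) > 10) " ..." else "",
                 " (need 0 < time_months <= 60 and event in {0,1})"))
  }
  tibble::as_tibble(dat)
}

#' Read a cluster coordinate table
#'
#' @param path CSV with columns `cluster_id`, `lon`, `lat`, `region_id`.
#' @return A tibble with one row per survey cluster.
#' @export
read_clusters <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("cluster_id", "lon", "lat", "region_id")
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols) > 0) {
    abort(paste0("clusters file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  check_lonlat(dat$lon, dat$lat)
  if (anyDuplicated(dat$cluster_id)) abort("duplicate cluster_id in clusters file")
  tibble::as_tibble(dat)
}

#' Read a region-level intervention coverage table
#'
#' Coverage is stored internally as proportions in `[0, 1]`; columns given in
#' percent (any value above 1) are rescaled by 1/100.
#'
#' @param path CSV with a `region_id` column and one column per intervention.
#' @return A tibble, one row per region, coverage as proportions.
#' @export
read_coverage <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"region_id" %in% names(dat)) abort("coverage file lacks region_id column")
  as_coverage(dat)
}

as_coverage <- function(dat) {
  num <- setdiff(names(dat), "region_id")
  for (nm in num) {
    x <- as.numeric(dat[[nm]])
    if (any(is.na(x)) || any(x < 0)) {
      abort(paste0("coverage column '", nm, "' has missing or negative values"))
    }
    if (any(x > 1)) x <- x / 100  # percentages on input
    if (any(x > 1)) abort(paste0("coverage column '", nm, "' exceeds 100%"))
    dat[[nm]] <- x
  }
  tibble::as_tibble(dat)
}

#' Great-circle distance matrix between survey clusters
#'
#' Haversine distances on a sphere of mean radius 6371.0 km, the metric used
#' for all spatial correlation in the package.
#'
#' @param lonlat A two-column matrix or data frame of longitude and latitude
#'   in decimal degrees (columns `lon`, `lat` if named).
#' @return A symmetric matrix of distances in km with zero diagonal.
#' @export
haversine_matrix <- function(lonlat) {
  lonlat <- as_lonlat(lonlat)
  check_lonlat(lonlat[, 1], lonlat[, 2])
  n <- nrow(lonlat)
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      ji <- (i + 1):n
      d[i, ji] <- geosphere::distHaversine(lonlat[i, , drop = FALSE],
                                           lonlat[ji, , drop = FALSE],
                                           r = 6371000) / 1000
      d[ji, i] <- d[i, ji]
    }
  }
  d
}

as_lonlat <- function(lonlat) {
  if (is.data.frame(lonlat)) {
    if (all(c("lon", "lat") %in% names(lonlat))) {
      lonlat <- cbind(lonlat$lon, lonlat$lat)
    } else {
      lonlat <- as.matrix(lonlat[, 1:2])
    }
  }
  storage.mode(lonlat) <- "double"
  lonlat
}

check_lonlat <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
      any(abs(lon) > 180) || any(abs(lat) > 90)) {
    abort("coordinates out of range: need lon in [-180,180], lat in [-90,90]")
  }
  invisible(TRUE)
}

#' Assemble a spatial frame from a cluster table
#'
#' Bundles cluster coordinates, the inter-cluster haversine distance matrix,
#' and the cluster-to-region mapping used by the Gaussian-process frailty and
#' the spatially varying coefficients.
#'
#' @param clusters Tibble with columns `cluster_id`, `lon`, `lat`, `region_id`
#'   (as from [read_clusters()]).
#' @return An object of class `spatial_frame`: a list with elements
#'   `clusters` (the input tibble), `distances` (km matrix, dimnames =
#'   cluster ids) and `region_of` (named character vector cluster -> region).
#' @export
spatial_frame <- function(clusters) {
  clusters <- tibble::as_tibble(clusters)
  stopifnot(all(c("cluster_id", "lon", "lat", "region_id") %in% names(clusters)))
  d <- haversine_matrix(clusters)
  ids <- as.character(clusters$cluster_id)
  dimnames(d) <- list(ids, ids)
  structure(
    list(clusters = clusters,
         distances = d,
         region_of = setNames(as.character(clusters$region_id), ids)),
    class = "spatial_frame"
  )
}

#' @export
print.spatial_frame <- function(x, ...) {
  cat("<spatial_frame> ", nrow(x$clusters), " clusters in ",
      length(unique(x$region_of)), " regions; inter-cluster distances ",
      sprintf("%.1f-%.1f km\n", min(x$distances[upper.tri(x$distances)]),
              max(x$distances)), sep = "")
  invisible(x)
}

#' Read a region adjacency edge list
#'
#' One undirected edge per line, the two region names separated by a tab (or,
#' for single-word names, whitespace). Lines starting with `#` are comments.
#'
#' @param path Path to the edge-list file.
#' @return A two-column tibble of edges (`from`, `to`).
#' @export
read_adjacency <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- lapply(lines, function(l) {
    p <- if (grepl("\t", l)) strsplit(l, "\t+")[[1]] else strsplit(l, "\\s+")[[1]]
    p <- trimws(p)
    if (length(p) != 2) abort(paste0("malformed adjacency line: '", l, "'"))
    p
  })
  tibble::tibble(from = vapply(parts, `[`, "", 1),
                 to   = vapply(parts, `[`, "", 2))
}

#' Build a region adjacency graph for the CAR prior
#'
#' From a symmetric 0/1 adjacency the function derives the neighbour counts
#' g_k, the row-normalised proximity matrix C (C_kl = omega_kl / g_k), the
#' diagonal scaling D (D_kk = 1 / g_k), and the support of the spatial
#' dependence parameter gamma: the open interval (1/lambda_min, 1/lambda_max)
#' where lambda_min, lambda_max are the extreme eigenvalues of
#' D^{-1/2} C D^{1/2} (the symmetric normalised adjacency). For a connected
#' graph lambda_max = 1, so the upper bound is 1 and the interval contains 0.
#'
#' @param edges Two-column data frame of undirected edges, or a path to an
#'   edge-list file readable by [read_adjacency()].
#' @param region_ids Optional character vector fixing the region set and
#'   order; defaults to the sorted set of names appearing in `edges`.
#' @return An object of class `region_graph`: list with `region_ids`, `omega`,
#'   `g`, `C`, `D` (diagonal vector), `gamma_bounds`, and `eigenvalues` (of
#'   the symmetrised proximity, used by the CAR log-density).
#' @export
region_graph <- function(edges, region_ids = NULL) {
  if (is.character(edges) && length(edges) == 1) edges <- read_adjacency(edges)
  edges <- as.data.frame(edges)
  if (is.null(region_ids)) {
    region_ids <- sort(unique(c(as.character(edges[[1]]), as.character(edges[[2]]))))
  }
  region_ids <- as.character(region_ids)
  q <- length(region_ids)
  unknown <- setdiff(unique(c(as.character(edges[[1]]), as.character(edges[[2]]))),
                     region_ids)
  if (length(unknown) > 0) {
    abort(paste0("edge list references unknown region(s): ",
                 paste(unknown, collapse = ", ")))
  }
  omega <- matrix(0, q, q, dimnames = list(region_ids, region_ids))
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges[i, 1]); b <- as.character(edges[i, 2])
    if (a == b) abort(paste0("self-edge on region '", a, "'"))
    omega[a, b] <- 1; omega[b, a] <- 1
  }
  g <- rowSums(omega)
  if (any(g == 0)) {
    abort(paste0("isolated region(s) with no neighbours: ",
                 paste(region_ids[g == 0], collapse = ", "),
                 " (D_kk = 1/g_k undefined)"))
  }
  if (!graph_connected(omega)) {
    warn("region adjacency graph is not connected")
  }
  C <- omega / g                     # row-normalised proximity
  M <- omega / sqrt(outer(g, g))     # D^{-1/2} C D^{1/2}, symmetric
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  structure(
    list(region_ids = region_ids, omega = omega, g = g, C = C, D = 1 / g,
         gamma_bounds = c(1 / min(ev), 1 / max(ev)), eigenvalues = ev),
    class = "region_graph"
  )
}

graph_connected <- function(omega) {
  q <- nrow(omega)
  seen <- logical(q); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(colSums(omega[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.region_graph <- function(x, ...) {
  cat("<region_graph> ", length(x$region_ids), " regions, ",
      sum(x$omega) / 2, " edges; gamma in (",
      sprintf("%.3f, %.3f", x$gamma_bounds[1], x$gamma_bounds[2]), ")\n",
      sep = "")
  invisible(x)
}

#' Shipped 13-region adjacency graph of Burkina Faso
#'
#' The administrative regions and their land borders, transcribed from the
#' national map. Used as the default topology by the survey generator.
#'
#' @return A `region_graph` over the 13 regions.
#' @export
burkina_region_graph <- function() {
  region_graph(system.file("extdata", "burkina_adjacency.txt",
                           package = "svcsurv", mustWork = TRUE))
}

#' Shipped regional intervention-coverage table (Burkina Faso DHS 2010)
#'
#' Published region-level coverage (in percent, converted to proportions) of
#' the 16 child, maternal and household health interventions assessed in the
#' Burkina Faso DHS 2010, used as the default coverage surface by the survey
#' generator.
#'
#' @return A tibble, one row per region, one column per intervention,
#'   coverage as proportions.
#' @export
burkina_coverage <- function() {
  read_coverage(system.file("extdata", "burkina_coverage.csv",
                            package = "svcsurv", mustWork = TRUE))
}

#' Canonical intervention names
#' @return Character vector of the 16 intervention column names.
#' @export
intervention_names <- function() {
  c("itn_use", "malaria_treatment", "exclusive_breastfeeding",
    "breastfeeding_24h", "postnatal_check", "measles_immunization",
    "dpt3_immunization", "all_antigen_immunization", "vitamin_a",
    "skilled_birth_attendance", "antenatal_visits", "family_planning",
    "iptp", "improved_sanitation", "improved_water", "itn_ownership")
}
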