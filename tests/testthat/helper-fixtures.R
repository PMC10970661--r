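# In-code fixture builders shared across test files.

make_areas <- function(n = 5, seed = NULL, extent = 10000,
                       iris = NULL, commune = NULL, region = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    area_id = sprintf("A%02d", seq_len(n)),
    x = runif(n, 200, extent), y = runif(n, 200, extent),
    population = round(runif(n, 10, 500)),
    iris_id = if (is.null(iris)) rep_len(c("I1", "I2"), n) else iris,
    commune_id = if (is.null(commune)) "C1" else commune,
    region_id = if (is.null(region)) "R1" else region,
    stringsAsFactors = FALSE)
}

make_facilities <- function(n = 3, seed = NULL, extent = 10000,
                            type = "gp", range_class = "proximity",
                            n_professionals = 1L) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    facility_id = sprintf("F-%s-%02d", type, seq_len(n)),
    x = runif(n, 200, extent), y = runif(n, 200, extent),
    facility_type = type, range_class = range_class,
    n_professionals = n_professionals, stringsAsFactors = FALSE)
}

# tiny named network: triangle with a slow direct edge A-C
triangle_network <- function() {
  nodes <- data.frame(node_id = c("A", "B", "C"),
                      x = c(300, 1300, 2300), y = c(300, 1200, 300),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from_node = c("A", "B", "A"),
                      to_node = c("B", "C", "C"),
                      length_m = c(1500, 1500, 2000),
                      travel_time_min = c(2, 2, 5),
                      stringsAsFactors = FALSE)
  make_network(nodes, edges)
}

random_network <- function(n_nodes, seed, p_edge = 0.6) {
  set.seed(seed)
  nodes <- data.frame(node_id = sprintf("N%d", seq_len(n_nodes)),
                      x = runif(n_nodes, 200, 5000),
                      y = runif(n_nodes, 200, 5000),
                      stringsAsFactors = FALSE)
  pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  # guarantee connectivity with a spanning chain
  chain <- cbind(seq_len(n_nodes - 1), 2:n_nodes)
  sel <- unique(rbind(pairs[keep, , drop = FALSE], chain))
  edges <- data.frame(from_node = nodes$node_id[sel[, 1]],
                      to_node = nodes$node_id[sel[, 2]],
                      length_m = round(runif(nrow(sel), 100, 3000)),
                      travel_time_min = round(runif(nrow(sel), 1, 10), 2),
                      stringsAsFactors = FALSE)
  make_network(nodes, edges)
}

write_tmp_csv <- function(df, name = "fixture.csv") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                    name)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# locate the CLI script whether the package is installed or under dev
find_cli <- function() {
  p <- system.file("cli", "scale-access.R", package = "scaleaccess")
  if (nzchar(p)) return(p)
  normalizePath(testthat::test_path("..", "..", "inst", "cli",
                                    "scale-access.R"))
}

# run the CLI in a child R process that sees the same library paths
run_cli <- function(args) {
  rs <- file.path(R.home("bin"), "Rscript")
  out <- system2(rs, c(find_cli(), args), stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("CLI failed: ", paste(out, collapse = "\n"))
  out
}
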