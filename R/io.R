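## File formats and command-line surface.
##
## Conventions: TSV edge lists and reports, CSV coordinate tables,
## MatrixMarket matrices; 0-based node indices in every output file, original
## node identifiers preserved through a sidecar mapping; every output file
## starts with a '#' (or '%' for MatrixMarket) comment carrying the tool
## version, resolved parameters and seed; '\n' line endings.

nc_version <- function() {
  as.character(utils::packageVersion("netcongruence"))
}

header_comment <- function(what, params = list()) {
  ps <- if (length(params)) {
    paste(sprintf("%s=%s", names(params),
                  vapply(params, function(x) paste(format(x), collapse = ","),
                         "")), collapse = " ")
  } else ""
  sprintf("# netcongruence %s | %s | %s", nc_version(), what, ps)
}

#' Read an undirected edge list (TSV)
#'
#' Reads a tab-separated edge list with a header line; the first two columns
#' hold node identifiers (arbitrary strings), mapped to indices in order of
#' first appearance. Duplicate edges (in either direction) are collapsed;
#' conflicting duplicate weights, malformed rows and self-loops are errors.
#'
#' @param path file path.
#' @param weight_column optional name or index of a weight column.
#' @return list with sparse `adjacency`, `weights` (symmetric matrix or
#'   `NULL`), and `ids` (original identifiers, index order).
#' @export
read_edge_list <- function(path, weight_column = NULL) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 2) stop("malformed edge list: need at least two columns")
  a <- as.character(d[[1]]); b <- as.character(d[[2]])
  if (anyNA(a) || anyNA(b) || any(a == "") || any(b == "")) {
    stop("malformed edge list: missing node identifier")
  }
  if (any(a == b)) stop("self-loops are not allowed")
  ids <- unique(as.vector(rbind(a, b)))
  i <- match(a, ids); j <- match(b, ids)
  wv <- NULL
  if (!is.null(weight_column)) {
    if (is.character(weight_column) && !(weight_column %in% names(d))) {
      stop(sprintf("weight column '%s' not found", weight_column))
    }
    wv <- as.numeric(d[[weight_column]])
    if (anyNA(wv)) stop("malformed weight column")
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    if (!is.null(wv)) {
      rng <- tapply(wv, key, function(x) diff(range(x)))
      if (any(rng > 0)) stop("conflicting duplicate edge weights")
    }
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]
    if (!is.null(wv)) wv <- wv[keep]
  }
  n <- length(ids)
  adjacency <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = 1,
                                    dims = c(n, n))
  weights <- NULL
  if (!is.null(wv)) {
    weights <- matrix(0, n, n)
    weights[cbind(lo, hi)] <- wv
    weights[cbind(hi, lo)] <- wv
  }
  list(adjacency = adjacency, weights = weights, ids = ids)
}

#' Read a symmetric matrix (MatrixMarket or dense CSV)
#'
#' `.mtx` files go through the MatrixMarket reader; anything else is read as
#' a dense CSV without header. The matrix must be symmetric within an
#' absolute tolerance of 1e-9 (scaled by magnitude) and free of NaN; it is
#' symmetrized exactly, and for distance matrices the diagonal is forced to
#' zero.
#'
#' @param path file path.
#' @param distance force a zero diagonal (default `TRUE`).
#' @return symmetric numeric matrix.
#' @export
read_matrix <- function(path, distance = TRUE) {
  m <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    as.matrix(Matrix::readMM(path))
  } else {
    as.matrix(utils::read.csv(path, header = FALSE, comment.char = "#"))
  }
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  if (anyNA(m)) stop("matrix contains NaN/NA entries")
  if (nrow(m) != ncol(m)) stop("matrix is not square")
  tol <- 1e-9 * max(1, max(abs(m)))
  if (max(abs(m - t(m))) > tol) stop("matrix is asymmetric beyond tolerance")
  m <- (m + t(m)) / 2
  if (distance) diag(m) <- 0
  m
}

write_tsv_with_header <- function(df, path, what, params = list()) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header_comment(what, params), con, sep = "\n")
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    rows <- do.call(paste, c(lapply(df, function(x) {
      if (is.double(x)) sprintf("%.10g", x) else as.character(x)
    }), sep = "\t"))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

#' Write a generated network to disk
#'
#' Writes `edges.tsv` (0-based indices), `coords.csv` (node, r, theta),
#' `communities.csv` (when communities exist) and `geo.mtx` (MatrixMarket
#' symmetric, when the geodesic matrix is available) into `dir`.
#'
#' @param net an `npso_network`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "npso_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- net$params
  par_str <- list(n = p$n, m = p$m, T = p$temperature, gamma = p$gamma,
                  C = p$communities,
                  seed = if (is.null(p$seed)) "NA" else p$seed)
  el <- which(upper.tri(as.matrix(net$adjacency)) &
                as.matrix(net$adjacency) != 0, arr.ind = TRUE)
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  files <- character(0)
  f <- file.path(dir, "edges.tsv")
  write_tsv_with_header(data.frame(i = el[, 1] - 1L, j = el[, 2] - 1L),
                        f, "edges", par_str)
  files <- c(files, f)
  f <- file.path(dir, "coords.csv")
  con <- file(f, "wb")
  writeLines(c(header_comment("coords", par_str), "node,r,theta",
               sprintf("%d,%.10g,%.10g", seq_len(net$n) - 1L, net$r, net$theta)),
             con, sep = "\n")
  close(con)
  files <- c(files, f)
  if (!is.null(net$community)) {
    f <- file.path(dir, "communities.csv")
    con <- file(f, "wb")
    writeLines(c(header_comment("communities", par_str), "node,community",
                 sprintf("%d,%d", seq_len(net$n) - 1L, net$community)),
               con, sep = "\n")
    close(con)
    files <- c(files, f)
  }
  if (!is.null(net$geo)) {
    f <- file.path(dir, "geo.mtx")
    geo_sp <- as(Matrix::forceSymmetric(Matrix::Matrix(net$geo, sparse = TRUE)),
                 "CsparseMatrix")
    Matrix::writeMM(geo_sp, f)
    lines <- readLines(f)
    writeLines(c(lines[1], sub("^#", "%", header_comment("geo", par_str)),
                 lines[-1]), f)
    files <- c(files, f)
  }
  invisible(files)
}

## ---- command-line surface ------------------------------------------------

cli_parse <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a))
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      out[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      out[[key]] <- TRUE   # bare flag
      i <- i + 1
    }
  }
  out
}

# precedence: explicit CLI > config file > defaults
cli_resolve <- function(opts, defaults) {
  cfg <- list()
  if (!is.null(opts$config)) {
    cfg <- yaml::read_yaml(opts$config)
    if (!is.list(cfg)) stop("config file must hold a mapping")
    # YAML 1.1 implicit typing turns a bare `n:` key into FALSE; undo it
    names(cfg)[names(cfg) == "FALSE"] <- "n"
  }
  res <- defaults
  for (k in names(cfg)) res[[k]] <- cfg[[k]]
  for (k in setdiff(names(opts), "config")) res[[k]] <- opts[[k]]
  res
}

cli_num <- function(x) if (is.null(x)) NULL else as.numeric(x)
cli_int <- function(x) if (is.null(x)) NULL else as.integer(as.numeric(x))

cli_load_graph <- function(res) {
  if (is.null(res$edges)) stop("--edges is required")
  wcol <- NULL
  if (!is.null(res$weights) && !(res$weights %in% c("geo", "ebc")) &&
      !file.exists(res$weights)) {
    wcol <- res$weights
  }
  gr <- read_edge_list(res$edges, weight_column = wcol)
  gr
}

# Geo matrices / coordinate tables are stored in 0-based node-id order;
# reorder them to the edge list's first-appearance index order when the
# edge-list identifiers are numeric.
remap_to_ids <- function(mat, ids) {
  num <- suppressWarnings(as.integer(ids))
  if (anyNA(num)) return(mat)          # non-numeric ids: assume aligned
  perm <- num + 1L
  if (length(perm) > nrow(mat) || any(perm < 1) || anyDuplicated(perm)) {
    stop("node identifiers do not index the supplied matrix")
  }
  mat[perm, perm, drop = FALSE]
}

cli_coords_matrix <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  cn <- tolower(names(d))
  if (all(c("r", "theta") %in% cn)) {
    r <- d[[which(cn == "r")]]; th <- d[[which(cn == "theta")]]
    outer(seq_along(r), seq_along(r), function(i, j)
      hyperbolic_distance(r[i], th[i], r[j], th[j]))
  } else if (all(c("x", "y") %in% cn)) {
    xyz <- as.matrix(d[, cn %in% c("x", "y", "z"), drop = FALSE])
    as.matrix(stats::dist(xyz))
  } else {
    stop("coords file must have columns (node, r, theta) or (node, x, y[, z])")
  }
}

cli_reference <- function(res, gr, weights) {
  ref <- if (is.null(res$ref)) "geo" else res$ref
  geo <- NULL
  if (!is.null(res[["geo-matrix"]])) geo <- read_matrix(res[["geo-matrix"]])
  if (!is.null(res$coords) && is.null(geo)) geo <- cli_coords_matrix(res$coords)
  if (!is.null(geo)) geo <- remap_to_ids(geo, gr$ids)
  if (ref == "geo") {
    if (is.null(geo)) stop("reference 'geo' needs --geo-matrix or --coords")
    geo
  } else if (ref == "gsp") {
    gsp_lengths(gr$adjacency, weights)
  } else stop(sprintf("unknown reference '%s'", ref))
}

cli_edge_weights <- function(res, gr) {
  w <- res$weights
  if (is.null(w)) {
    m <- as.matrix(gr$adjacency)   # unit projection: pTSP in hop units
    m
  } else if (identical(w, "ebc")) {
    ebc_weights(gr$adjacency)
  } else if (identical(w, "geo")) {
    geo <- if (!is.null(res[["geo-matrix"]])) read_matrix(res[["geo-matrix"]])
           else if (!is.null(res$coords)) cli_coords_matrix(res$coords)
           else stop("weights 'geo' need --geo-matrix or --coords")
    remap_to_ids(geo, gr$ids)
  } else if (!is.null(gr$weights)) {
    gr$weights
  } else if (file.exists(w)) {
    read_matrix(w)
  } else stop(sprintf("cannot resolve weights '%s'", w))
}

cli_generate <- function(res) {
  need <- c("n", "m")
  if (any(!need %in% names(res))) stop("generate needs --n and --m")
  net <- npso(cli_int(res$n), cli_int(res$m),
              temperature = if (is.null(res$temp)) 0.1 else cli_num(res$temp),
              gamma = if (is.null(res$gamma)) 2.5 else cli_num(res$gamma),
              communities = if (is.null(res$communities)) 0 else cli_int(res$communities),
              seed = cli_int(res$seed))
  dir <- if (is.null(res[["out-dir"]])) "." else res[["out-dir"]]
  files <- write_network(net, dir)
  message(sprintf("wrote %s", paste(basename(files), collapse = ", ")))
  0L
}

cli_ptsp <- function(res) {
  gr <- cli_load_graph(res)
  w <- cli_edge_weights(res, gr)
  variant <- if (is.null(res$variant)) "memo" else res$variant
  pt <- mean_ptsp(gr$adjacency, w, variant = variant,
                  dag_pruned = isTRUE(res[["dag-pruned"]]),
                  workers = if (is.null(res$workers)) 1L else cli_int(res$workers),
                  checkpoint_dir = res[["checkpoint-dir"]])
  pairs <- which(upper.tri(pt$hop) & pt$hop >= 2L, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  out <- if (is.null(res$out)) "ptsp.tsv" else res$out
  params <- list(variant = variant, edges = res$edges,
                 seed = if (is.null(res$seed)) "NA" else res$seed)
  write_tsv_with_header(
    data.frame(i = pairs[, 1] - 1L, j = pairs[, 2] - 1L,
               path_count = pt$path_count[pairs], mean_ptsp = pt$mean[pairs]),
    out, "ptsp", params)
  sch <- depth_schedule(tsp_lengths(gr$adjacency),
                        variant = if (variant == "naive") "brute" else variant)
  write_tsv_with_header(
    sch$profile[, c("L", "M_L", "count")],
    file.path(dirname(out), "depth_profile.tsv"), "depth_profile", params)
  mapping_file <- file.path(dirname(out), "nodes.tsv")
  write_tsv_with_header(data.frame(index = seq_along(gr$ids) - 1L, id = gr$ids),
                        mapping_file, "node_mapping", params)
  message(sprintf("wrote %s (%d pairs)", out, nrow(pairs)))
  0L
}

cli_gc <- function(res, what = "gc") {
  gr <- cli_load_graph(res)
  w <- cli_edge_weights(res, gr)
  rd <- cli_reference(res, gr, w)
  pt <- mean_ptsp(gr$adjacency, w, variant = "memo", dag_pruned = TRUE)
  rep <- geometrical_congruence(pt, rd)
  df <- data.frame(measure = "GC", value = rep$gc, band = rep$band,
                   p_value = rep$p_value, n = rep$n, e = rep$e,
                   pairs = nrow(rep$pairs))
  out <- if (is.null(res$out)) stdout() else res$out
  if (is.character(out)) {
    write_tsv_with_header(df, out, what, list(ref = if (is.null(res$ref)) "geo" else res$ref))
  } else {
    utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  0L
}

cli_gre <- function(res) {
  gr <- cli_load_graph(res)
  if (is.null(res$coords)) stop("gre needs --coords for the myopic guide")
  guide <- remap_to_ids(cli_coords_matrix(res$coords), gr$ids)
  w <- if (is.null(gr$weights)) guide else gr$weights
  rd <- cli_reference(res, gr, w)
  g <- greedy_routing_efficiency(gr$adjacency, guide, weights = w, rd = rd,
                                 include_adjacent = isTRUE(res[["include-adjacent"]]))
  df <- data.frame(measure = "GRE", value = g$gre,
                   success_ratio = g$success_ratio, pairs = g$n_pairs)
  out <- if (is.null(res$out)) stdout() else res$out
  if (is.character(out)) {
    write_tsv_with_header(df, out, "gre", list(ref = if (is.null(res$ref)) "geo" else res$ref))
  } else {
    utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  0L
}

cli_congruence_test <- function(res) {
  if (is.null(res[["geo-matrix"]])) stop("congruence-test needs --geo-matrix")
  res$ref <- "geo"
  if (is.null(res$weights)) res$weights <- "geo"
  cli_gc(res, what = "congruence_test")
}

cli_simulate_cohort <- function(res) {
  need <- c("n-per-group", "nodes")
  if (any(!need %in% names(res))) stop("simulate-cohort needs --n-per-group and --nodes")
  ch <- synthetic_cohort(cli_int(res[["n-per-group"]]), cli_int(res$nodes),
                         effect_size = if (is.null(res$effect)) 0 else cli_num(res$effect),
                         seed = if (is.null(res$seed)) 1L else cli_int(res$seed))
  dir <- if (is.null(res$out)) "cohort" else res$out
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("subject_%03d.csv", seq_along(ch$weights))
  for (k in seq_along(ch$weights)) {
    utils::write.table(ch$weights[[k]], file.path(dir, files[k]), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  write_tsv_with_header(data.frame(id = seq_along(files), file = files,
                                   group = as.character(ch$group)),
                        file.path(dir, "subjects.tsv"), "subjects",
                        ch$params)
  con <- file(file.path(dir, "centroids.csv"), "wb")
  writeLines(c(header_comment("centroids", ch$params), "node,x,y,z",
               sprintf("%d,%.10g,%.10g,%.10g", seq_len(ch$n_nodes) - 1L,
                       ch$centroids[, 1], ch$centroids[, 2], ch$centroids[, 3])),
             con, sep = "\n")
  close(con)
  message(sprintf("wrote cohort of %d subjects to %s", length(files), dir))
  0L
}

cli_markers <- function(res) {
  if (is.null(res$cohort)) stop("markers needs --cohort DIR")
  dir <- res$cohort
  subj <- utils::read.delim(file.path(dir, "subjects.tsv"), comment.char = "#",
                            stringsAsFactors = FALSE)
  cen_path <- file.path(dir, "centroids.csv")
  centroids <- NULL
  if (file.exists(cen_path)) {
    d <- utils::read.csv(cen_path, comment.char = "#")
    centroids <- as.matrix(d[, c("x", "y", "z")])
  }
  weights <- lapply(subj$file, function(f)
    read_matrix(file.path(dir, f), distance = FALSE))
  cohort <- list(weights = weights, group = factor(subj$group),
                 centroids = centroids, n_nodes = nrow(weights[[1]]))
  mode <- if (is.null(res$mode)) "nos" else res$mode
  mt <- compute_markers(cohort, mode = mode)
  B <- if (is.null(res$permutations)) 1000L else cli_int(res$permutations)
  seed <- if (is.null(res$seed)) 1L else cli_int(res$seed)
  tr_gc <- aupr_trustworthiness(mt$gc, mt$group, B = B, seed = seed)
  tr_er <- aupr_trustworthiness(mt$er, mt$group, B = B, seed = seed + 1L)
  out <- if (is.null(res$out)) "report.tsv" else res$out
  write_tsv_with_header(
    data.frame(marker = c("GC", "E_R"), mode = mode,
               aupr = c(tr_gc$aupr, tr_er$aupr),
               p_trustworthiness = c(tr_gc$p_value, tr_er$p_value),
               p_bonferroni = c(tr_gc$p_bonferroni, tr_er$p_bonferroni)),
    out, "markers", list(mode = mode, B = B, seed = seed))
  write_tsv_with_header(as.data.frame(mt),
                        file.path(dirname(out), "markers_by_subject.tsv"),
                        "markers_by_subject", list(mode = mode, seed = seed))
  message(sprintf("wrote %s", out))
  0L
}

#' Command-line entry point
#'
#' Dispatches the subcommands `generate`, `ptsp`, `gc`, `gre`,
#' `congruence-test`, `markers` and `simulate-cohort`. Options are `--key
#' value` pairs (bare `--flag` for switches); `--config file.yaml` supplies
#' defaults, with explicit flags taking precedence. Validation failures print
#' a one-line cause and yield a nonzero status.
#'
#' @param argv character vector of arguments (subcommand first), e.g.
#'   `c("generate", "--n", "100", "--m", "4", "--seed", "7")`.
#' @return integer exit status (0 on success), invisibly.
#' @export
run_cli <- function(argv) {
  status <- tryCatch({
    if (length(argv) == 0) stop("usage: netcongruence <subcommand> [--options]")
    sub <- argv[1]
    opts <- cli_parse(argv[-1])
    res <- cli_resolve(opts, defaults = list())
    message(sprintf("netcongruence %s | %s | %s", nc_version(), sub,
                    paste(sprintf("%s=%s", names(res),
                                  vapply(res, function(x) paste(format(x), collapse = ","), "")),
                          collapse = " ")))
    switch(sub,
           "generate" = cli_generate(res),
           "ptsp" = cli_ptsp(res),
           "gc" = cli_gc(res),
           "gre" = cli_gre(res),
           "congruence-test" = cli_congruence_test(res),
           "markers" = cli_markers(res),
           "simulate-cohort" = cli_simulate_cohort(res),
           stop(sprintf("unknown subcommand '%s'", sub)))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}
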