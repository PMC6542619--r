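#' Read / write a labeled connectivity matrix
#'
#' Delimited text interchange format: first row and first column hold the
#' node labels, the body is the symmetric numeric matrix. On read, row and
#' column labels must agree; asymmetry within tolerance is symmetrized by
#' averaging with a warning, beyond tolerance it is an error naming the
#' offending entry. Matrices are written with 12 significant digits so a
#' write/read round trip is stable well below analysis tolerances.
#'
#' @param path file path.
#' @param sep field delimiter (tab by default).
#' @param tol symmetry tolerance on read.
#' @return `read_matrix()` returns a labeled symmetric matrix;
#'   `write_matrix()` returns `path` invisibly.
#' @export
read_matrix <- function(path, sep = "\t", tol = 1e-9) {
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, row.names = 1L,
                           colClasses = NA)
  W <- as.matrix(raw)
  if (!is.numeric(W))
    stop("non-numeric cell in ", path)
  if (nrow(W) != ncol(W))
    stop(path, ": matrix is not square (", nrow(W), " x ", ncol(W), ")")
  if (nrow(W) < 3L)
    stop(path, ": a connectivity matrix needs at least 3 nodes")
  if (!identical(rownames(W), colnames(W)))
    stop(path, ": row labels do not match column labels (first mismatch: '",
         rownames(W)[which(rownames(W) != colnames(W))[1L]], "' vs '",
         colnames(W)[which(rownames(W) != colnames(W))[1L]], "')")
  asym <- abs(W - t(W))
  if (max(asym) > tol) {
    ij <- arrayInd(which.max(asym), dim(W))
    stop(path, ": asymmetric beyond tolerance at row '",
         rownames(W)[ij[1L]], "', column '", colnames(W)[ij[2L]], "'")
  }
  if (max(asym) > 0) {
    warning(path, ": asymmetry within tolerance; symmetrized by averaging")
    W <- (W + t(W)) / 2
  }
  W
}

#' @rdname read_matrix
#' @param W a labeled square matrix.
#' @export
write_matrix <- function(W, path, sep = "\t") {
  W <- as.matrix(W)
  if (is.null(rownames(W)))
    rownames(W) <- colnames(W) <- paste0("n", seq_len(nrow(W)))
  body <- apply(W, 2L, function(col) formatC(col, digits = 12,
                                             format = "g"))
  df <- cbind(node = rownames(W), as.data.frame(body,
                                                check.names = FALSE))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a study in the interchange layout
#'
#' Layout under `dir`: one `"<id>_<layer>.tsv"` matrix per subject and
#' layer, one `"<id>_manifest.json"` per subject (`subject_id`, `group`,
#' ordered `layers` list of `{name, path}` — manifest order defines the
#' layer index), `behavior.tsv` and `ground_truth.json`.
#'
#' @param study an `"mcp_study"` object (see [generate_cohort()]).
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(study, dir) {
  stopifnot(inherits(study, "mcp_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- names(study$subjects)
  for (s in seq_along(study$subjects)) {
    net <- study$subjects[[s]]
    entries <- vector("list", n_layers(net))
    for (m in seq_len(n_layers(net))) {
      fname <- paste0(ids[s], "_", net$layers[m], ".tsv")
      Wm <- net$W[, , m]
      dimnames(Wm) <- list(net$nodes, net$nodes)
      write_matrix(Wm, file.path(dir, fname))
      entries[[m]] <- list(name = net$layers[m], path = fname)
    }
    manifest <- list(subject_id = ids[s],
                     group = as.character(study$group[s]),
                     layers = entries)
    jsonlite::write_json(manifest,
                         file.path(dir, paste0(ids[s], "_manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  utils::write.table(study$behavior, file.path(dir, "behavior.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- study$ground_truth
  gt$attacked_pairs <- lapply(gt$attacked_pairs, function(m)
    if (nrow(m)) unname(apply(m, 1L, as.list)) else list())
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read one multiplex subject from a manifest
#'
#' @param manifest_path path to a subject manifest JSON.
#' @return a `multiplex` with attributes `"subject_id"` and `"group"`.
#' @export
read_multiplex <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  layers <- lapply(man$layers, function(e) read_matrix(file.path(base,
                                                                 e$path)))
  names(layers) <- vapply(man$layers, `[[`, "", "name")
  net <- multiplex(layers)
  attr(net, "subject_id") <- man$subject_id
  attr(net, "group") <- man$group
  net
}

#' @rdname write_cohort
#' @return `read_cohort()` returns an `"mcp_study"` object.
#' @export
read_cohort <- function(dir) {
  manifests <- sort(list.files(dir, pattern = "_manifest\\.json$",
                               full.names = TRUE))
  if (!length(manifests)) stop("no subject manifests found in ", dir)
  subjects <- list()
  groups <- character(0)
  for (mp in manifests) {
    net <- tryCatch(read_multiplex(mp), error = function(e)
      stop("failed to load subject manifest '", basename(mp), "': ",
           conditionMessage(e), call. = FALSE))
    subjects[[attr(net, "subject_id")]] <- net
    groups <- c(groups, attr(net, "group"))
  }
  nodes <- subjects[[1L]]$nodes
  layers <- subjects[[1L]]$layers
  for (id in names(subjects)) {
    if (!identical(subjects[[id]]$nodes, nodes))
      stop("subject '", id, "' disagrees on node labels")
    if (!identical(subjects[[id]]$layers, layers))
      stop("subject '", id, "' disagrees on layer names")
  }
  lev <- unique(groups)
  if ("hc" %in% lev) lev <- c("hc", setdiff(lev, "hc"))
  behavior <- NULL
  bpath <- file.path(dir, "behavior.tsv")
  if (file.exists(bpath))
    behavior <- utils::read.table(bpath, sep = "\t", header = TRUE)
  gt <- NULL
  gpath <- file.path(dir, "ground_truth.json")
  if (file.exists(gpath)) gt <- jsonlite::read_json(gpath,
                                                    simplifyVector = TRUE)
  structure(list(subjects = subjects,
                 group = factor(groups, levels = lev),
                 behavior = behavior, ground_truth = gt, config = NULL),
            class = "mcp_study")
}
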