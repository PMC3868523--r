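# File formats: TSV matrices (tab-separated, UTF-8, header row = condition
# labels, first column = node names, "." decimals), JSON models/manifests,
# SIF/GraphML network exports.

#' Write a perturbation dataset as a TSV trio
#'
#' @param data a [perturbation_data()].
#' @param x_path,u_path,roles_path output files for the response matrix, the
#'   perturbation matrix and the node-role table.
#' @export
write_perturbation_data <- function(data, x_path, u_path, roles_path) {
  stopifnot(inherits(data, "perturbation_data"))
  wr <- function(m, path) {
    df <- data.frame(node = data$nodes, m, check.names = FALSE)
    colnames(df) <- c("node", data$conditions)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(data$X, x_path)
  wr(data$U, u_path)
  utils::write.table(data.frame(node = data$nodes, role = data$roles),
                     roles_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(data)
}

#' Read a perturbation dataset from a TSV trio
#'
#' Validates the three files against each other: node names must be unique
#' and aligned, condition labels must agree between the response and
#' perturbation matrices, and every cell must be numeric. Errors name the
#' offending cells.
#'
#' @param x_path TSV of observed log2-ratio responses (nodes x conditions).
#' @param u_path TSV of external-force values, same layout.
#' @param roles_path TSV with columns \code{node}, \code{role}.
#' @return a [perturbation_data()].
#' @export
read_perturbation_data <- function(x_path, u_path, roles_path) {
  rd <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, colClasses = "character")
    nodes <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    num <- suppressWarnings(apply(m, c(1, 2), as.numeric))
    if (any(is.na(num) & !is.na(m))) {
      bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric cell in %s: node '%s', condition '%s'",
                   path, nodes[bad[1]], colnames(m)[bad[2]]))
    }
    list(nodes = nodes, m = num, conditions = colnames(m))
  }
  x <- rd(x_path); u <- rd(u_path)
  if (anyDuplicated(x$nodes))
    stop("duplicate node names in ", x_path, ": ",
         paste(unique(x$nodes[duplicated(x$nodes)]), collapse = ", "))
  if (!identical(x$nodes, u$nodes)) {
    bad <- which(x$nodes != u$nodes)[1]
    stop(sprintf("node rows misaligned between X and U (first mismatch row %d: '%s' vs '%s')",
                 bad, x$nodes[bad], u$nodes[bad]))
  }
  if (!identical(x$conditions, u$conditions)) {
    bad <- which(x$conditions != u$conditions)[1]
    stop(sprintf("condition columns misaligned between X and U (first mismatch column %d: '%s' vs '%s')",
                 bad, x$conditions[bad], u$conditions[bad]))
  }
  roles <- utils::read.table(roles_path, sep = "\t", header = TRUE,
                             colClasses = "character")
  ri <- match(x$nodes, roles$node)
  if (anyNA(ri))
    stop("nodes missing from the roles table: ",
         paste(x$nodes[is.na(ri)], collapse = ", "))
  rownames(x$m) <- rownames(u$m) <- x$nodes
  perturbation_data(x$m, u$m, roles = roles$role[ri], nodes = x$nodes,
                    conditions = x$conditions)
}

#' Serialize a network model to JSON
#'
#' @param model a [network_model()].
#' @param path output file.
#' @param seed,config optional provenance recorded in the document (the
#'   config is stored both verbatim and as a short hash).
#' @export
write_model_json <- function(model, path, seed = NULL, config = NULL) {
  doc <- list(nodes = data.frame(name = model$nodes, role = model$roles),
              W = unname(model$W), alpha = model$alpha,
              epsilon = model$epsilon,
              provenance = list(seed = seed %||% attr(model, "seed"),
                                config = sanitize_config(config),
                                config_hash = config_hash(config)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a network model from JSON
#'
#' @param path file written by [write_model_json()].
#' @return a [network_model()].
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(doc$W)
  model <- network_model(W, alpha = doc$alpha, epsilon = doc$epsilon,
                         nodes = doc$nodes$name, roles = doc$nodes$role)
  attr(model, "seed") <- doc$provenance$seed
  model
}

#' Export an inferred network as SIF or GraphML
#'
#' SIF lines are \code{source activates|inhibits target} by the sign of the
#' mean weight; GraphML carries numeric edge attributes \code{mean_weight}
#' and \code{frequency}. Activity nodes are exported with their "a" prefix.
#' Edges with \eqn{|mean| <} \code{threshold} are omitted; all nodes are
#' declared even when no edge survives.
#'
#' @param avg an [average_network()] (or a [bp_infer()] fit / matrix).
#' @param file output path.
#' @param format \code{"sif"} or \code{"graphml"}.
#' @param threshold minimum absolute mean weight.
#' @export
export_network <- function(avg, file, format = c("sif", "graphml"),
                           threshold = 0.2) {
  format <- match.arg(format)
  W <- infer_matrix(avg)
  nodes <- if (inherits(avg, "average_network")) avg$nodes else
    rownames(W) %||% paste0("n", seq_len(nrow(W)))
  roles <- if (inherits(avg, "average_network")) avg$roles else
    rep("protein", nrow(W))
  freq <- if (inherits(avg, "average_network")) avg$edge_frequency else
    (W != 0) * 1
  labels <- ifelse(roles == "activity", paste0("a", nodes), nodes)
  e <- which(abs(W) >= threshold & row(W) != col(W), arr.ind = TRUE)
  if (format == "sif") {
    lines <- if (nrow(e)) sprintf("%s\t%s\t%s", labels[e[, 2]],
                                  ifelse(W[e] > 0, "activates", "inhibits"),
                                  labels[e[, 1]]) else character(0)
    writeLines(lines, file)
  } else {
    g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
    g <- igraph::set_vertex_attr(g, "name", value = labels)
    g <- igraph::set_vertex_attr(g, "role", value = roles)
    if (nrow(e)) {
      g <- igraph::add_edges(g, rbind(e[, 2], e[, 1]))
      g <- igraph::set_edge_attr(g, "mean_weight", value = W[e])
      g <- igraph::set_edge_attr(g, "frequency", value = freq[e])
    }
    igraph::write_graph(g, file, format = "graphml")
  }
  invisible(file)
}

#' Re-import a GraphML network export
#'
#' @param file a GraphML file written by [export_network()].
#' @return list with \code{nodes} and an \code{edges} data.frame (source,
#'   target, mean_weight, frequency).
#' @export
read_network_graphml <- function(file) {
  g <- igraph::read_graph(file, format = "graphml")
  el <- igraph::as_edgelist(g)
  edges <- data.frame(source = el[, 1], target = el[, 2])
  if (igraph::ecount(g)) {
    edges$mean_weight <- igraph::edge_attr(g, "mean_weight")
    edges$frequency <- igraph::edge_attr(g, "frequency")
  } else {
    edges$mean_weight <- numeric(0); edges$frequency <- numeric(0)
  }
  list(nodes = igraph::vertex_attr(g, "name"), edges = edges)
}

#' Export BP marginals as a table
#'
#' One row per free edge: source, target, the K per-value probabilities,
#' the marginal mean and the normalized entropy. The JSON variant embeds the
#' value grid.
#'
#' @param fit a [bp_infer()] fit.
#' @param file output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
export_marginals <- function(fit, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  H <- marginal_entropy(fit)
  idx <- which(fit$edge_mask, arr.ind = TRUE)
  probs <- t(vapply(seq_len(nrow(idx)),
                    function(r) fit$P[idx[r, 1], idx[r, 2], ],
                    numeric(length(fit$grid))))
  df <- data.frame(source = fit$data$nodes[idx[, 2]],
                   target = fit$data$nodes[idx[, 1]],
                   probs,
                   mean = fit$mean_W[idx],
                   entropy = H[idx])
  colnames(df)[2 + seq_along(fit$grid)] <-
    sprintf("p_%g", as.numeric(fit$grid))
  if (format == "tsv") {
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(grid = as.numeric(fit$grid), marginals = df),
                         file, digits = NA)
  }
  invisible(df)
}

#' Write a model ensemble to a directory
#'
#' One JSON model file per member plus a \code{manifest.tsv} (seed, train
#' error, rank, file) and a \code{manifest.json} carrying the configuration
#' hash.
#'
#' @param ensemble a [generate_ensemble()] ensemble.
#' @param dir output directory (created if needed).
#' @param config optional configuration recorded in the manifest.
#' @export
write_ensemble <- function(ensemble, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("model_%03d.json", seq_along(ensemble$models))
  for (g in seq_along(ensemble$models))
    write_model_json(ensemble$models[[g]], file.path(dir, files[g]),
                     seed = ensemble$seeds[g], config = config)
  manifest <- data.frame(rank = seq_along(files), file = files,
                         seed = ensemble$seeds,
                         train_error = ensemble$train_errors)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_models = length(files),
                            n_generate = ensemble$n_generate,
                            refined = ensemble$refined,
                            config = sanitize_config(config),
                            config_hash = config_hash(config)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a model ensemble from a directory
#'
#' @param dir directory written by [write_ensemble()].
#' @return a \code{"model_ensemble"} object (traces are not persisted).
#' @export
read_ensemble <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE)
  models <- lapply(file.path(dir, manifest$file), read_model_json)
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  structure(list(models = models, train_errors = manifest$train_error,
                 traces = NULL, seeds = manifest$seed,
                 all_errors = sort(manifest$train_error),
                 n_generate = meta$n_generate, refined = meta$refined,
                 ranked = TRUE),
            class = "model_ensemble")
}

# Reduce a configuration to JSON-serializable form: atomic leaves are kept,
# anything else is replaced by its class tag. Used for manifests only.
sanitize_config <- function(x) {
  if (is.null(x) || is.atomic(x)) return(x)
  if (is.list(x) && is.null(attr(x, "class")))
    return(lapply(x, sanitize_config))
  paste0("<", class(x)[1], ">")
}

# Small polynomial rolling hash (djb2-style, mod 2^31 - 1) of a deparsed R
# object; stamps manifests so two runs with the same configuration are
# recognizably identical. Not a cryptographic hash.
config_hash <- function(x) {
  if (is.null(x)) return(NA_character_)
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
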