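#' Build the directed bipartite exchange network
#'
#' Pools each growing model's uptake and secretion sets over all iterations
#' of a succession run (union) and connects metabolite nodes to model nodes:
#' an uptake edge points metabolite -> model, a secretion edge points
#' model -> metabolite. With `organic_only` (the default) metabolite nodes
#' that do not classify as organic are dropped, so inorganic by-products
#' such as CO2 or water never enter the network. Metabolite subtypes record
#' provenance: `exudate` (present in the initial environment), `injected`
#' (added exogenously during the run) or `secreted` (microbial product).
#'
#' @param result a [run_mcsm()] result.
#' @param labels optional [label_table()]; growers without a label get class
#'   `"NA"` with a warning.
#' @param organic_only drop non-organic metabolite nodes (default `TRUE`).
#' @return an `igraph` directed graph with vertex attributes `type`
#'   (`"model"`/`"metabolite"`), `subtype`, `class`, and edge attribute
#'   `direction` (`"uptake"`/`"secretion"`).
#' @export
build_network <- function(result, labels = NULL, organic_only = TRUE) {
  stopifnot(inherits(result, "succession_result"))
  pooled <- pool_profiles(result)
  grower_ids <- names(pooled)
  if (is.null(labels)) labels <- label_table(character(0))
  missing <- setdiff(grower_ids, names(labels))
  if (length(missing) > 0L && length(labels) > 0L)
    warning("no label for grower(s) ", paste(missing, collapse = ", "),
            "; classified NA")
  class_of <- function(id) if (id %in% names(labels)) labels[[id]] else "NA"

  formulas <- stats::setNames(result$met_info$formula, result$met_info$id)
  mets <- unique(unlist(lapply(pooled, function(p) c(p$uptaken, p$secreted))))
  if (organic_only) {
    keep <- vapply(mets, function(id) {
      f <- if (id %in% names(formulas)) formulas[[id]] else ""
      suppressWarnings(classify_compound(id, f)) %in%
        c("organic", "organic_p")
    }, TRUE)
    mets <- mets[keep]
  }
  subtype_of <- function(id) {
    if (id %in% result$injected_compounds) "injected"
    else if (id %in% result$initial_compounds) "exudate"
    else "secreted"
  }
  edges <- do.call(rbind, lapply(grower_ids, function(mid) {
    p <- pooled[[mid]]
    up <- intersect(p$uptaken, mets)
    sec <- intersect(p$secreted, mets)
    rbind(
      if (length(up) > 0L)
        data.frame(from = up, to = mid, direction = "uptake",
                   stringsAsFactors = FALSE),
      if (length(sec) > 0L)
        data.frame(from = mid, to = sec, direction = "secretion",
                   stringsAsFactors = FALSE))
  }))
  vertices <- rbind(
    data.frame(name = grower_ids, type = "model", subtype = NA_character_,
               class = vapply(grower_ids, class_of, ""),
               stringsAsFactors = FALSE),
    if (length(mets) > 0L)
      data.frame(name = mets, type = "metabolite",
                 subtype = vapply(mets, subtype_of, ""),
                 class = NA_character_, stringsAsFactors = FALSE))
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        direction = character(0))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = vertices)
  validate_network(g)
  g
}

pool_profiles <- function(result) {
  pooled <- list()
  for (rec in result$iterations) {
    for (p in rec$profiles) {
      if (!p$grew) next
      cur <- pooled[[p$model]]
      if (is.null(cur))
        cur <- list(uptaken = character(0), secreted = character(0))
      cur$uptaken <- union(cur$uptaken, p$uptaken)
      cur$secreted <- union(cur$secreted, p$secreted)
      pooled[[p$model]] <- cur
    }
  }
  pooled
}

# Re-validates bipartiteness and duplicate-freeness post construction.
validate_network <- function(g) {
  type <- igraph::V(g)$type
  el <- igraph::as_edgelist(g)
  if (nrow(el) > 0L) {
    from_type <- type[match(el[, 1L], igraph::V(g)$name)]
    to_type <- type[match(el[, 2L], igraph::V(g)$name)]
    if (any(from_type == to_type))
      stop("network is not bipartite: edge within one node class")
    if (anyDuplicated(paste(el[, 1L], el[, 2L])) > 0L)
      stop("duplicate edges in network")
  }
  invisible(g)
}

#' Per-node degree table
#'
#' @param net network from [build_network()].
#' @return data.frame with `node`, `type`, `subtype`, `class`, `in_degree`,
#'   `out_degree`, `total_degree`, sorted by decreasing total degree.
#' @export
degree_table <- function(net) {
  v <- igraph::V(net)
  if (length(v) == 0L)
    return(data.frame(node = character(0), type = character(0),
                      subtype = character(0), class = character(0),
                      in_degree = integer(0), out_degree = integer(0),
                      total_degree = integer(0)))
  out <- data.frame(
    node = v$name, type = v$type, subtype = v$subtype, class = v$class,
    in_degree = as.integer(igraph::degree(net, mode = "in")),
    out_degree = as.integer(igraph::degree(net, mode = "out")),
    stringsAsFactors = FALSE, row.names = NULL)
  out$total_degree <- out$in_degree + out$out_degree
  out[order(-out$total_degree, out$node), , drop = FALSE]
}

#' Export a trophic network
#'
#' Writes GraphML (node attributes `type`, `subtype`, `class`; edge
#' attribute `direction`) and/or a TSV edge list
#' (`source`, `target`, `direction`).
#'
#' @param net network from [build_network()].
#' @param graphml optional GraphML output path.
#' @param edgelist optional TSV output path.
#' @return invisibly, the network.
#' @export
write_network <- function(net, graphml = NULL, edgelist = NULL) {
  if (!is.null(graphml)) {
    g <- net
    # GraphML writers reject NA attribute values
    igraph::V(g)$subtype[is.na(igraph::V(g)$subtype)] <- ""
    igraph::V(g)$class[is.na(igraph::V(g)$class)] <- ""
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(edgelist)) {
    el <- igraph::as_edgelist(net)
    tab <- data.frame(source = el[, 1L], target = el[, 2L],
                      direction = igraph::E(net)$direction)
    utils::write.table(tab, edgelist, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(net)
}
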