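# Bait-prey protein-interaction network: deduplicated directed graph,
# Girvan-Newman module detection on the undirected projection, extraction of
# transcription-machinery <-> ribosomal-protein interactions.

#' Build a deduplicated directed interaction network
#'
#' Removes duplicate (bait, prey) records, keeps self-loops (reported), and
#' attaches node roles when given.
#'
#' @param edges Data frame with columns `bait`, `prey` (and optionally
#'   `bait_role`).
#' @param roles Optional node role table with columns `node`, `role` (one of
#'   `TBP`, `TFB`, `Bat`, `RP`, `other`) and optionally `subunit`.
#' @return A list of class `"interaction_network"`: `graph` (directed
#'   igraph), `edges` (deduplicated), `roles`, `counts` (nodes, edges,
#'   duplicates removed, self-loops).
#' @export
build_network <- function(edges, roles = NULL) {
  stopifnot(all(c("bait", "prey") %in% names(edges)))
  n_in <- nrow(edges)
  dup <- duplicated(edges[, c("bait", "prey")])
  edges <- edges[!dup, , drop = FALSE]
  self <- sum(edges$bait == edges$prey)
  nodes <- unique(c(edges$bait, edges$prey))
  if (!is.null(roles)) {
    stopifnot(all(c("node", "role") %in% names(roles)))
    missing_roles <- setdiff(nodes, roles$node)
    if (length(missing_roles)) {
      roles <- rbind(roles[, c("node", "role")],
                     data.frame(node = missing_roles, role = "other",
                                stringsAsFactors = FALSE))
      if ("subunit" %in% names(roles)) roles$subunit <- NA_character_
    }
    roles <- roles[roles$node %in% nodes | roles$node %in% roles$node, , drop = FALSE]
  }
  vertices <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (!is.null(roles)) {
    vertices$role <- roles$role[match(nodes, roles$node)]
    if ("subunit" %in% names(roles)) {
      vertices$subunit <- roles$subunit[match(nodes, roles$node)]
    }
  }
  g <- igraph::graph_from_data_frame(edges[, c("bait", "prey")],
                                     directed = TRUE, vertices = vertices)
  out <- list(graph = g, edges = edges, roles = roles,
              counts = c(nodes = length(nodes), edges = nrow(edges),
                         duplicates_removed = n_in - nrow(edges),
                         self_loops = self))
  class(out) <- "interaction_network"
  out
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d nodes, %d directed edges (%d duplicates removed, %d self-loops)\n",
              x$counts["nodes"], x$counts["edges"],
              x$counts["duplicates_removed"], x$counts["self_loops"]))
  invisible(x)
}

#' Girvan-Newman network modules
#'
#' Community detection by iterative removal of the highest-edge-betweenness
#' edge on the undirected simple projection (direction is reporting-only),
#' cut at the global modularity maximum over the removal sequence.
#'
#' @param net An `"interaction_network"` from [build_network()].
#' @return A data frame with columns `node`, `module`; the partition
#'   modularity in `attr(, "modularity")`.
#' @export
girvan_newman_modules <- function(net) {
  g <- igraph::as_undirected(net$graph, mode = "collapse")
  g <- igraph::simplify(g)
  if (igraph::ecount(g) < 1) stop("network has no edge")
  cl <- igraph::cluster_edge_betweenness(g, directed = FALSE)
  mem <- igraph::membership(cl)
  out <- data.frame(node = names(mem), module = as.integer(mem),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "modularity") <- igraph::modularity(g, mem)
  out
}

#' Extract transcription-machinery to ribosomal-protein interactions
#'
#' Returns the edges whose bait is a transcription-complex component (role in
#' `bait_roles`) and whose prey is annotated as a ribosomal protein, with
#' counts by bait role and, when a `subunit` annotation is present, by
#' ribosomal subunit.
#'
#' @param net An `"interaction_network"` whose nodes carry roles.
#' @param bait_roles Roles counting as transcription machinery
#'   (default TBP, TFB, Bat).
#' @param prey_role Prey role to keep (default `"RP"`).
#' @return A list with `edges` (the matching subset), `by_role` (bait-role
#'   counts), `by_role_subunit` (role-by-subunit table or `NULL`), `n`.
#' @export
extract_bait_prey_subnetwork <- function(net,
                                         bait_roles = c("TBP", "TFB", "Bat"),
                                         prey_role = "RP") {
  if (is.null(net$roles)) stop("network has no role annotation")
  role_of <- stats::setNames(net$roles$role, net$roles$node)
  if (!any(role_of == prey_role)) stop("no node annotated with role ", prey_role)
  e <- net$edges
  keep <- role_of[e$bait] %in% bait_roles & role_of[e$prey] == prey_role
  sub <- e[keep & !is.na(keep), , drop = FALSE]
  by_role <- table(factor(role_of[sub$bait], levels = bait_roles))
  by_role_subunit <- NULL
  if (!is.null(net$roles$subunit)) {
    su <- stats::setNames(net$roles$subunit, net$roles$node)
    by_role_subunit <- table(factor(role_of[sub$bait], levels = bait_roles),
                             su[sub$prey])
  }
  list(edges = sub, by_role = by_role, by_role_subunit = by_role_subunit,
       n = nrow(sub))
}
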