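#' Egocentric reply-network metrics
#'
#' Interactions are directed @-reply exchanges `(from, to, count)`. The ego
#' graph of a user u is the undirected simple graph on u's two-hop
#' neighborhood (u, reply partners, and partners-of-partners), with an edge
#' wherever at least one exchange occurred in either direction; directed
#' counts are retained for reciprocity and prestige. The cited literature
#' does not restate the metric formulas, so the definitions documented in
#' [ego_metrics()] are authoritative for this package and are unit-tested
#' against brute-force recomputation.
#'
#' @name network_features
NULL

#' Build a user's two-hop ego graph
#'
#' @param user user id.
#' @param edges data.frame with columns `from`, `to`, `count` (directed
#'   @-reply counts); duplicate rows are summed.
#' @return list of class `ego_graph`: `graph` (undirected igraph on the
#'   two-hop node set), `ego`, `out_counts`/`in_counts` (named, u's directed
#'   reply totals per partner).
#' @export
build_ego_graph <- function(user, edges) {
  stopifnot(all(c("from", "to", "count") %in% names(edges)))
  edges <- edges[edges$count > 0, , drop = FALSE]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  out_c <- tapply(edges$count[edges$from == user], edges$to[edges$from == user], sum)
  in_c <- tapply(edges$count[edges$to == user], edges$from[edges$to == user], sum)
  # undirected adjacency for the BFS
  und <- unique(rbind(
    data.frame(a = edges$from, b = edges$to),
    data.frame(a = edges$to, b = edges$from)
  ))
  n1 <- unique(und$b[und$a == user])
  n2 <- unique(und$b[und$a %in% n1])
  nodes <- unique(c(user, n1, n2))
  sub <- und[und$a %in% nodes & und$b %in% nodes & und$a < und$b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sub, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g <- igraph::simplify(g)
  structure(list(
    graph = g, ego = user,
    out_counts = as.list(out_c %||% list()),
    in_counts = as.list(in_c %||% list())
  ), class = "ego_graph")
}

#' Egocentric network metrics
#'
#' Definitions (fixed here, tested against adjacency-matrix recomputation):
#' \itemize{
#' \item reciprocity: among partners u exchanged replies with, the fraction
#'   with replies in both directions;
#' \item prestige_ratio: total replies received / max(1, total replies sent);
#' \item graph_density: edge density of the undirected two-hop graph;
#' \item clustering_coefficient: u's local clustering coefficient;
#' \item embeddedness: mean over neighbors v of
#'   |N(u) n N(v)| / |N(u) u N(v)| (neighborhoods within the ego graph);
#' \item ego_components: connected components of the ego graph with u removed;
#' \item two_hop_size: node count of the ego graph minus u.
#' }
#' A singleton graph returns all-zero metrics with `degenerate = TRUE`.
#'
#' @param eg an `ego_graph` from [build_ego_graph()].
#' @return named list of metrics.
#' @export
ego_metrics <- function(eg) {
  g <- eg$graph
  u <- eg$ego
  n <- igraph::vcount(g)
  if (n <= 1) {
    return(list(reciprocity = 0, prestige_ratio = 0, graph_density = 0,
                clustering_coefficient = 0, embeddedness = 0,
                ego_components = 0L, two_hop_size = 0L, degenerate = TRUE))
  }
  outp <- names(eg$out_counts)
  inp <- names(eg$in_counts)
  either <- union(outp, inp)
  reciprocity <- if (length(either) == 0) 0 else length(intersect(outp, inp)) / length(either)
  prestige <- sum(unlist(eg$in_counts)) / max(1, sum(unlist(eg$out_counts)))
  density <- igraph::edge_density(g)
  cc <- unname(igraph::transitivity(g, type = "local", vids = u, isolates = "zero"))
  nb <- function(v) igraph::neighbors(g, v)$name
  nu <- nb(u)
  emb <- if (length(nu) == 0) 0 else mean(vapply(nu, function(v) {
    nv <- nb(v)
    length(intersect(nu, nv)) / length(union(nu, nv))
  }, numeric(1)))
  comp <- igraph::components(igraph::delete_vertices(g, u))$no
  list(reciprocity = reciprocity, prestige_ratio = prestige,
       graph_density = density, clustering_coefficient = cc,
       embeddedness = emb, ego_components = as.integer(comp),
       two_hop_size = n - 1L, degenerate = FALSE)
}

#' Network feature block for a cohort
#'
#' @param cohort cohort bundle (or list of user records with `user_id`).
#' @param edges interaction edge list; defaults to the bundle's.
#' @return data.frame, one row per user, metric columns.
#' @export
network_features <- function(cohort, edges = cohort$interactions) {
  users <- if (!is.null(cohort$users)) cohort$users else cohort
  ids <- vapply(users, function(u) u$user_id, character(1))
  rows <- lapply(ids, function(id) {
    m <- ego_metrics(build_ego_graph(id, edges))
    data.frame(user_id = id, reciprocity = m$reciprocity,
               prestige_ratio = m$prestige_ratio, graph_density = m$graph_density,
               clustering_coefficient = m$clustering_coefficient,
               embeddedness = m$embeddedness, ego_components = m$ego_components,
               two_hop_size = m$two_hop_size)
  })
  do.call(rbind, rows)
}
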