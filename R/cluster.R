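# Shipped stopword list for cluster labels: common English function words
# plus generic pathway-nomenclature filler. Informative biology words
# ("regulation", "signaling", gene names) are deliberately kept.
#' Default stopword list for cluster labeling
#' @return Character vector of lowercase stopwords.
#' @export
em_stopwords <- function() {
  c("a", "an", "and", "as", "at", "by", "for", "from", "in", "into", "its",
    "of", "on", "or", "the", "to", "via", "with", "within", "through",
    "during", "involved", "other",
    "pathway", "pathways", "process", "processes", "gene", "genes",
    "set", "sets", "go", "gobp", "kegg", "reactome", "wp", "hsa")
}

#' Cluster the enrichment network
#'
#' Default method: connected components of the similarity-thresholded graph
#' (the minimal reading of clustering pathways by gene overlap). Optional
#' method `"modularity"`: greedy modularity communities on
#' similarity-weighted edges, for dense graphs. Singleton nodes form
#' singleton clusters. Cluster ids are assigned in decreasing size order,
#' ties broken by the lexicographically smallest member name; assignments
#' are written onto the returned network.
#'
#' @param net An `enrichment_network` from [build_network()].
#' @param method `"components"` or `"modularity"`.
#' @return `net` with `clusters` set (named integer vector, node -> id).
#' @export
cluster_network <- function(net, method = c("components", "modularity")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "enrichment_network"))
  if (nrow(net$nodes) == 0L) {
    net$clusters <- stats::setNames(integer(0), character(0))
    return(net)
  }
  g <- as_igraph(net)
  membership <- if (method == "components") {
    igraph::components(g)$membership
  } else {
    w <- igraph::E(g)$similarity
    igraph::membership(igraph::cluster_fast_greedy(
      g, weights = if (length(w)) w else NULL))
  }
  groups <- split(names(membership), membership)
  first_member <- vapply(groups, function(m) min(m), "")
  o <- order(-lengths(groups), first_member, method = "radix")
  ids <- integer(length(membership))
  names(ids) <- names(membership)
  for (i in seq_along(o)) ids[groups[[o[i]]]] <- i
  net$clusters <- ids[net$nodes$name]
  net
}

#' Label one cluster from member set names
#'
#' Member set names are tokenized on non-alphanumeric characters,
#' lowercased, and stripped of stopwords and pure numbers; the label is the
#' three most frequent remaining words (frequency ties broken
#' alphabetically), space-joined. A singleton cluster is labeled with its
#' own set name truncated to 60 characters; an empty token pool falls back
#' to the first member name.
#'
#' @param members Character vector of node (set) names in the cluster.
#' @param stopwords Words to drop (lowercase); see [em_stopwords()].
#' @return A label string.
#' @export
label_cluster <- function(members, stopwords = em_stopwords()) {
  if (length(members) == 0L) stop("cluster has no members")
  if (length(members) == 1L) return(substr(members, 1L, 60L))
  tokens <- unlist(strsplit(tolower(members), "[^a-z0-9]+"))
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!tokens %in% stopwords & !grepl("^[0-9]+$", tokens)]
  if (length(tokens) == 0L) return(substr(sort(members)[1L], 1L, 60L))
  tab <- table(tokens)
  o <- order(-tab, names(tab), method = "radix")
  paste(names(tab)[o][seq_len(min(3L, length(tab)))], collapse = " ")
}

#' Label every cluster of a clustered network
#'
#' @param net An `enrichment_network` with `clusters` set.
#' @param stopwords Passed to [label_cluster()].
#' @return `net` with `cluster_labels` (named by cluster id).
#' @export
annotate_clusters <- function(net, stopwords = em_stopwords()) {
  stopifnot(inherits(net, "enrichment_network"))
  if (is.null(net$clusters)) stop("run cluster_network() first")
  groups <- split(names(net$clusters), net$clusters)
  net$cluster_labels <- vapply(groups, label_cluster, "",
                               stopwords = stopwords)
  net
}

#' Cluster membership table
#'
#' @param net A clustered, optionally annotated `enrichment_network`.
#' @return Data frame with one row per cluster: `id`, `size`, `label`,
#'   `members` (list column, lexicographically sorted).
#' @export
network_clusters <- function(net) {
  stopifnot(inherits(net, "enrichment_network"))
  if (is.null(net$clusters)) stop("run cluster_network() first")
  groups <- split(names(net$clusters), net$clusters)
  ids <- as.integer(names(groups))
  o <- order(ids)
  groups <- lapply(groups[o], function(m) sort(m, method = "radix"))
  labels <- if (!is.null(net$cluster_labels))
    unname(net$cluster_labels[as.character(ids[o])])
  else vapply(groups, label_cluster, "")
  data.frame(id = ids[o], size = lengths(groups), label = labels,
             members = I(unname(groups)),
             stringsAsFactors = FALSE, row.names = NULL)
}
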