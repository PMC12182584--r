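# Linkage structure of a dataset: samples, animals, tests, and parasites
# can relate one-to-one, many-to-one, or one-to-many (repeat sampling,
# confirmatory tests, pooled samples, nested detections). Animal IDs and
# Parasite IDs share one identifier namespace so that a parasite sampled
# from a host can itself be tested in another row.

# split a (possibly ';'-separated) Animal ID cell into individual IDs
.split_animals <- function(aid) {
  if (is.na(aid) || !nzchar(aid)) return(character(0))
  trimws(strsplit(aid, ";", fixed = TRUE)[[1]])
}

#' Build the linkage graph of a dataset
#'
#' Nodes are typed identifiers: one `sample` node per distinct Sample ID,
#' one `animal` node per distinct Animal ID (after expanding `;`-separated
#' pooled lists and joining the pooled-links side table), one `record`
#' node per row (the test), and one `parasite` node per distinct Parasite
#' ID. Edges: `tests` (record to sample), `collected_from` (sample to each
#' linked animal), `detected_in` (parasite to record), and `nests` (host
#' animal to the organism whose Parasite ID reappears as an Animal ID in
#' another row).
#'
#' @param dataset a `wdds_dataset`.
#' @return A `wdds_graph`: list with `nodes` (id, type) and `edges`
#'   (from, to, type) data frames.
#' @export
build_link_graph <- function(dataset) {
  rec <- dataset$records
  n <- nrow(rec)
  rec_ids <- if (n) paste0("record:", seq_len(n)) else character(0)

  sample_ids <- unique(rec$sample_id[!is.na(rec$sample_id)])

  # sample -> animal links from list expansion plus side table
  aid <- if (n == 0) character(0) else
    ifelse(is.na(rec$animal_id) | is.na(rec$sample_id), "", rec$animal_id)
  spl <- strsplit(aid, ";", fixed = TRUE)
  counts <- lengths(spl)
  from <- rep(rec$sample_id, counts)
  to <- trimws(unlist(spl, use.names = FALSE))
  keep <- !is.na(to) & nzchar(to)
  from <- from[keep]; to <- to[keep]
  if (!is.null(dataset$pooled_links) && nrow(dataset$pooled_links)) {
    pl <- dataset$pooled_links
    keep <- pl$sample_id %in% sample_ids
    from <- c(from, pl$sample_id[keep]); to <- c(to, pl$animal_id[keep])
  }
  collected <- unique(data.frame(from = from, to = to,
                                 type = rep("collected_from", length(from)),
                                 stringsAsFactors = FALSE))
  animal_ids <- unique(collected$to)

  hassamp <- !is.na(rec$sample_id)
  tests <- data.frame(from = rec_ids[hassamp], to = rec$sample_id[hassamp],
                      type = rep("tests", sum(hassamp)),
                      stringsAsFactors = FALSE)

  haspid <- !is.na(rec$parasite_id)
  detected <- data.frame(from = rec$parasite_id[haspid],
                         to = rec_ids[haspid],
                         type = rep("detected_in", sum(haspid)),
                         stringsAsFactors = FALSE)
  parasite_ids <- unique(rec$parasite_id[haspid])

  nest <- .nesting_edges(rec)
  nests <- if (nrow(nest))
    data.frame(from = nest$host, to = nest$child, type = "nests",
               stringsAsFactors = FALSE)
  else data.frame(from = character(0), to = character(0),
                  type = character(0), stringsAsFactors = FALSE)

  nodes <- rbind(
    data.frame(id = animal_ids, type = rep("animal", length(animal_ids)),
               stringsAsFactors = FALSE),
    data.frame(id = sample_ids, type = rep("sample", length(sample_ids)),
               stringsAsFactors = FALSE),
    data.frame(id = rec_ids, type = rep("record", length(rec_ids)),
               stringsAsFactors = FALSE),
    data.frame(id = parasite_ids,
               type = rep("parasite", length(parasite_ids)),
               stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- rbind(tests, collected, detected, nests)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "wdds_graph")
}

#' @export
print.wdds_graph <- function(x, ...) {
  tn <- table(x$nodes$type)
  te <- table(x$edges$type)
  cat("<wdds_graph:",
      paste(sprintf("%d %s", as.integer(tn), names(tn)), collapse = ", "),
      "nodes;",
      if (length(te)) paste(sprintf("%d %s", as.integer(te), names(te)),
                            collapse = ", ") else "no",
      "edges>\n")
  invisible(x)
}

#' Maximal nested-detection chains
#'
#' Follows `nests` edges (host animal to nested organism) from root hosts
#' to leaves and returns each maximal chain as an ordered vector of
#' identifiers, e.g. `c("RAT1", "FLEA1")` when a flea sampled from a rat
#' is itself tested in another row. Chains deeper than one hop are
#' supported.
#'
#' @param graph a `wdds_graph` from [build_link_graph()].
#' @return List of character vectors, each of length >= 2.
#' @export
nested_chains <- function(graph) {
  edges <- graph$edges[graph$edges$type == "nests", , drop = FALSE]
  if (nrow(edges) == 0) return(list())
  if (.has_cycle(data.frame(host = edges$from, child = edges$to,
                            stringsAsFactors = FALSE)))
    stop("NEST_CYCLE: nested detections form a cycle")
  roots <- setdiff(unique(edges$from), edges$to)
  chains <- list()
  walk <- function(path) {
    nxt <- edges$to[edges$from == path[length(path)]]
    if (length(nxt) == 0) {
      if (length(path) >= 2) chains[[length(chains) + 1L]] <<- path
      return(invisible())
    }
    for (v in nxt) walk(c(path, v))
  }
  for (r in roots) walk(r)
  chains
}

#' Summarize pooled samples
#'
#' One row per distinct sample: how many individual animals are linked
#' (from `;`-separated Animal ID lists plus the pooled-links side table),
#' whether the pool is unidentified (no linked animals but an organism
#' quantity recorded, e.g. "a pool of 30 mosquitoes"), and whether the
#' sample is pooled at all.
#'
#' @param dataset a `wdds_dataset`.
#' @return Data frame with columns `sample_id`, `n_linked_animals`,
#'   `unidentified`, `pooled`.
#' @export
pool_summary <- function(dataset) {
  rec <- dataset$records
  ids <- unique(rec$sample_id[!is.na(rec$sample_id)])
  res <- data.frame(sample_id = ids, n_linked_animals = 0L,
                    unidentified = FALSE, pooled = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    rows <- which(!is.na(rec$sample_id) & rec$sample_id == ids[i])
    animals <- unlist(lapply(rec$animal_id[rows], .split_animals))
    if (!is.null(dataset$pooled_links))
      animals <- c(animals,
                   dataset$pooled_links$animal_id[
                     dataset$pooled_links$sample_id == ids[i]])
    animals <- unique(animals[nzchar(animals)])
    qty <- rec$organism_quantity[rows]
    has_qty <- any(!is.na(qty))
    res$n_linked_animals[i] <- length(animals)
    res$unidentified[i] <- length(animals) == 0 && has_qty
    res$pooled[i] <- length(animals) > 1 ||
      (length(animals) == 0 && has_qty && any(qty > 1, na.rm = TRUE))
  }
  res
}

#' Export graph edges for visualization
#'
#' @param graph a `wdds_graph`.
#' @param path optional CSV output path.
#' @return The edge data frame (columns `from`, `to`, `type`).
#' @export
edge_list <- function(graph, path = NULL) {
  if (!is.null(path))
    utils::write.csv(graph$edges, path, row.names = FALSE, quote = TRUE)
  graph$edges
}
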