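#' @title Co-participation networks
#'
#' @description Two participants are connected when they take part in the
#' same reaction. Node identity is chosen by granularity: gene name, protein
#' accession, or full proteoform serialization. Edges are recorded per
#' reaction (a multigraph on disk, annotated with each endpoint's role and
#' complex/set context), while degrees and subnetwork membership collapse
#' the multiplicity to distinct neighbor identities. Nodes are labelled
#' \code{canonical} when every proteoform projecting onto them is the
#' unmodified canonical isoform, otherwise \code{specific}.
#'
#' @name network
NULL

GRANULARITIES <- c("gene", "protein", "proteoform")

# identity of a participant proteoform string at a granularity
project_identity <- function(pf_strings, granularity, kb) {
  if (granularity == "proteoform") return(pf_strings)
  accs <- vapply(pf_strings, function(s) parse_proteoform(s)$accession,
                 character(1), USE.NAMES = FALSE)
  if (granularity == "protein") return(accs)
  gm <- kb$gene_map
  idx <- match(accs, gm$accession)
  genes <- gm$gene_name[idx]
  if (anyNA(idx)) {
    warning("no gene mapping for accession(s): ",
            paste(unique(accs[is.na(idx)]), collapse = ", "),
            "; keeping accession as node identity")
    genes[is.na(idx)] <- accs[is.na(idx)]
  }
  genes
}

#' Build the co-participation network of a knowledge base
#'
#' For each reaction, every unordered pair of distinct participant
#' identities (after projection to the chosen granularity) yields one edge
#' record; endpoints are stored in lexicographic order. A participant whose
#' identities collapse under projection (e.g. two proteoforms of one
#' accession at protein granularity) contributes a single node and no
#' self-edge. When a participant holds several roles or contexts in one
#' reaction, the annotation joins the sorted distinct values with "|".
#'
#' @param kb a \code{"knowledge_base"}.
#' @param granularity \code{"gene"}, \code{"protein"} or \code{"proteoform"}.
#' @return A \code{"pathway_network"}: list with \code{granularity},
#'   \code{nodes} (data.frame \code{identity}, \code{category}) and
#'   \code{edges} (data.frame \code{node_a}, \code{node_b},
#'   \code{reaction_id}, \code{role_a}, \code{role_b}, \code{context_a},
#'   \code{context_b}).
#' @export
build_network <- function(kb, granularity = c("proteoform", "protein",
                                              "gene")) {
  stopifnot(inherits(kb, "knowledge_base"))
  granularity <- match.arg(granularity)
  prt <- kb$participants
  prt$identity <- project_identity(prt$proteoform, granularity, kb)

  # node category from the underlying proteoforms
  is_canonical_pf <- function(s) {
    p <- parse_proteoform(s)
    is.na(p$isoform) && ptm_count(p) == 0L
  }
  canon <- vapply(unique(prt$proteoform), is_canonical_pf, logical(1))
  node_canon <- tapply(canon[match(prt$proteoform, names(canon))],
                       prt$identity, all)
  ids <- sort(names(node_canon))
  nodes <- data.frame(identity = ids,
                      category = ifelse(node_canon[ids], "canonical",
                                        "specific"),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL

  edges <- list()
  for (rid in sort(unique(prt$reaction_id))) {
    sub <- prt[prt$reaction_id == rid, , drop = FALSE]
    # aggregate per identity: joined roles/contexts within this reaction
    agg_role <- tapply(sub$role, sub$identity, function(v) {
      paste(sort(unique(v)), collapse = "|")
    })
    agg_ctx <- tapply(sub$context, sub$identity, function(v) {
      paste(sort(unique(v)), collapse = "|")
    })
    members <- sort(unique(sub$identity))
    m <- length(members)
    if (m < 2L) next
    pairs <- utils::combn(members, 2L)
    edges[[length(edges) + 1L]] <- data.frame(
      node_a = pairs[1, ], node_b = pairs[2, ], reaction_id = rid,
      role_a = unname(agg_role[pairs[1, ]]),
      role_b = unname(agg_role[pairs[2, ]]),
      context_a = unname(agg_ctx[pairs[1, ]]),
      context_b = unname(agg_ctx[pairs[2, ]]), stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node_a = character(), node_b = character(),
               reaction_id = character(), role_a = character(),
               role_b = character(), context_a = character(),
               context_b = character(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b, edges$reaction_id), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(granularity = granularity, nodes = nodes, edges = edges),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("<pathway_network> granularity=", x$granularity,
      " nodes=", nrow(x$nodes), " edges=", nrow(x$edges), "\n", sep = "")
  invisible(x)
}

#' Split a network into internal and external connections
#'
#' Internal edges connect two input identities; external edges connect one
#' input identity to a node outside the input. Edges touching no input node
#' are dropped.
#'
#' @param network a \code{"pathway_network"}.
#' @param input_identities character vector of node identities at the
#'   network's granularity.
#' @return A list of two edge data.frames, \code{internal} and
#'   \code{external}, each with a \code{locality} column.
#' @export
extract_subnetworks <- function(network, input_identities) {
  stopifnot(inherits(network, "pathway_network"))
  e <- network$edges
  a_in <- e$node_a %in% input_identities
  b_in <- e$node_b %in% input_identities
  internal <- e[a_in & b_in, , drop = FALSE]
  external <- e[xor(a_in, b_in), , drop = FALSE]
  if (nrow(internal)) internal$locality <- "internal"
  else internal$locality <- character()
  if (nrow(external)) external$locality <- "external"
  else external$locality <- character()
  rownames(internal) <- rownames(external) <- NULL
  list(internal = internal, external = external)
}

#' Per-node degree with category labels
#'
#' Degree counts distinct neighbor identities; edge multiplicity across
#' reactions is collapsed.
#'
#' @param network a \code{"pathway_network"}.
#' @return A data.frame \code{identity}, \code{category}, \code{degree}.
#' @export
degree_summary <- function(network) {
  stopifnot(inherits(network, "pathway_network"))
  e <- unique(network$edges[, c("node_a", "node_b")])
  neighbors <- c(split(e$node_b, e$node_a), split(e$node_a, e$node_b))
  deg <- vapply(network$nodes$identity, function(id) {
    length(unique(unlist(neighbors[names(neighbors) == id],
                         use.names = FALSE)))
  }, integer(1))
  out <- data.frame(identity = network$nodes$identity,
                    category = network$nodes$category,
                    degree = unname(deg), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a network (or subnetworks) to TSV files
#'
#' Writes \code{<prefix>nodes.tsv} (identity, category) and
#' \code{<prefix>edges.tsv} (node_a, node_b, reaction_id, role_a, role_b,
#' context_a, context_b, locality) in deterministic order; optionally a SIF
#' file with lines \code{node_a reaction:<id> node_b}.
#'
#' @param network a \code{"pathway_network"}.
#' @param dir destination directory (created if absent).
#' @param prefix filename prefix, e.g. \code{"proteoform_"}.
#' @param subnetworks optional result of \code{\link{extract_subnetworks}};
#'   when given, \code{<prefix>internal_edges.tsv} and
#'   \code{<prefix>external_edges.tsv} are written as well.
#' @param sif also write \code{<prefix>network.sif}.
#' @return \code{dir}, invisibly.
#' @export
write_network <- function(network, dir, prefix = "", subnetworks = NULL,
                          sif = FALSE) {
  stopifnot(inherits(network, "pathway_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  write_tsv(network$nodes, paste0(prefix, "nodes.tsv"))
  edges <- network$edges
  edges$locality <- "-"
  write_tsv(edges, paste0(prefix, "edges.tsv"))
  if (!is.null(subnetworks)) {
    write_tsv(subnetworks$internal, paste0(prefix, "internal_edges.tsv"))
    write_tsv(subnetworks$external, paste0(prefix, "external_edges.tsv"))
  }
  if (sif) {
    lines <- paste(network$edges$node_a,
                   paste0("reaction:", network$edges$reaction_id),
                   network$edges$node_b, sep = "\t")
    writeLines(lines, file.path(dir, paste0(prefix, "network.sif")))
  }
  invisible(dir)
}

#' Read edges written by \code{\link{write_network}}
#'
#' @param path path to an \code{edges.tsv}-style file.
#' @return A data.frame of edges.
#' @export
read_network_edges <- function(path) {
  read_kb_tsv(path)
}
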