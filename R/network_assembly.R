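# Fusing the gene relation network, ontology is-a edges, disease-name mapping
# edges and association edges into one typed heterogeneous network.

new_hetero_network <- function(nodes, edges, report = list()) {
  # canonical form: endpoints sorted within an edge, rows sorted, deduplicated
  if (nrow(edges)) {
    n1 <- pmin(edges$node1, edges$node2)
    n2 <- pmax(edges$node1, edges$node2)
    edges$node1 <- n1
    edges$node2 <- n2
    edges <- edges[edges$node1 != edges$node2, , drop = FALSE]
    key <- paste(edges$node1, edges$node2, edges$edge_type, sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges <- edges[order(edges$edge_type, edges$node1, edges$node2), ,
                   drop = FALSE]
  }
  nodes <- nodes[!duplicated(nodes$node), , drop = FALSE]
  nodes <- nodes[order(nodes$node_type, nodes$node), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  ntype <- stats::setNames(nodes$node_type, nodes$node)
  if (nrow(edges)) {
    t1 <- ntype[edges$node1]
    t2 <- ntype[edges$node2]
    want <- rbind(gene_gene = c("gene", "gene"),
                  disease_disease = c("disease", "disease"),
                  gene_disease = c("disease", "gene"))
    ok <- vapply(seq_len(nrow(edges)), function(i) {
      setequal(c(t1[i], t2[i]), want[edges$edge_type[i], ]) &&
        (edges$edge_type[i] != "gene_disease" || t1[i] != t2[i])
    }, logical(1))
    if (any(is.na(ok)) || !all(ok)) {
      stop_arg("edge endpoint types do not match edge_type (first offender: ",
               paste(edges[which(!ok | is.na(ok))[1], 1:3], collapse = " "),
               ")")
    }
  }
  structure(list(nodes = nodes, edges = edges, report = report),
            class = "hetero_network")
}

#' Assemble the heterogeneous gene-disease network
#'
#' Fuses four evidence layers into one undirected typed network:
#' \itemize{
#'   \item `gene_gene` edges from the thresholded gene relation network
#'     (weight = similarity);
#'   \item `disease_disease` is-a edges between ontology terms (weight 1);
#'   \item `disease_disease` mapping edges from each lower-tier association
#'     disease name to its matched terms (weight = mapping score); names
#'     matched at the direct or xref tier (score 1) collapse into the term
#'     node itself;
#'   \item `gene_disease` edges, weight 1, for every association row whose
#'     gene symbol is a gene node -- curated links are taken as reliable.
#' }
#' Association rows whose gene symbol is outside the gene universe are
#' skipped and counted in the report. Duplicate rows collapse to one edge.
#' Disease class is carried as metadata only.
#'
#' @param gene_edges data.frame from [build_gene_network()].
#' @param ontology a `disease_ontology`, or `NULL` for none.
#' @param mappings a `disease_mapping_set` covering every distinct
#'   `disease_name` in `associations` (unmapped is fine).
#' @param associations data.frame from [read_associations()].
#' @param genes optional character vector fixing the gene universe; defaults
#'   to the genes incident to `gene_edges` plus association gene symbols that
#'   appear there.
#' @return a `hetero_network`: list with `nodes` (columns `node`,
#'   `node_type`), `edges` (columns `node1`, `node2`, `edge_type`, `weight`),
#'   and `report` (counts of skipped rows), in canonical deterministic order.
#' @export
assemble_network <- function(gene_edges = NULL, ontology = NULL,
                             mappings = NULL, associations = NULL,
                             genes = NULL) {
  gene_edges <- gene_edges %||%
    data.frame(gene1 = character(0), gene2 = character(0),
               weight = numeric(0), stringsAsFactors = FALSE)
  genes <- sort(unique(c(genes, gene_edges$gene1, gene_edges$gene2)))
  edges <- list(data.frame(node1 = gene_edges$gene1,
                           node2 = gene_edges$gene2,
                           edge_type = rep("gene_gene", nrow(gene_edges)),
                           weight = gene_edges$weight,
                           stringsAsFactors = FALSE))
  term_ids <- if (is.null(ontology)) character(0) else names(ontology)
  disease_nodes <- term_ids
  dis_meta <- list()

  if (!is.null(ontology)) {
    isa <- do.call(rbind, lapply(ontology, function(t) {
      p <- intersect(t$parents, term_ids)
      if (!length(p)) return(NULL)
      data.frame(node1 = t$term_id, node2 = p,
                 edge_type = "disease_disease", weight = 1,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(isa)) edges <- c(edges, list(isa))
  }

  n_skipped <- 0L
  if (!is.null(associations) && nrow(associations)) {
    used <- unique(associations$disease_name)
    miss <- setdiff(used, names(mappings %||% list()))
    if (length(miss)) {
      stop_arg("mappings missing for association disease name(s): ",
               paste(utils::head(miss, 3), collapse = ", "))
    }
    # which network node(s) does a disease name resolve to?
    anchors <- lapply(used, function(nm) {
      m <- mappings[[nm]]
      if (m$tier %in% c("direct", "xref")) {
        m$matched_terms$term_id            # collapse into the term node(s)
      } else {
        nm                                 # the name keeps its own node
      }
    })
    names(anchors) <- used
    for (nm in used) {
      m <- mappings[[nm]]
      if (!m$tier %in% c("direct", "xref")) {
        disease_nodes <- c(disease_nodes, nm)
        dis_meta[[nm]] <- m$tier
        if (nrow(m$matched_terms)) {       # half_ambiguous / ambiguous
          edges <- c(edges, list(data.frame(
            node1 = nm, node2 = m$matched_terms$term_id,
            edge_type = "disease_disease", weight = m$matched_terms$score,
            stringsAsFactors = FALSE)))
        }
      }
    }
    known <- associations$gene_symbol %in% genes
    n_skipped <- sum(!known)
    if (any(known)) {
      assoc <- associations[known, , drop = FALSE]
      ge <- do.call(rbind, lapply(seq_len(nrow(assoc)), function(i) {
        data.frame(node1 = anchors[[assoc$disease_name[i]]],
                   node2 = assoc$gene_symbol[i],
                   edge_type = "gene_disease", weight = 1,
                   stringsAsFactors = FALSE)
      }))
      edges <- c(edges, list(ge))
    }
  }

  disease_nodes <- unique(disease_nodes)
  clash <- intersect(disease_nodes, genes)
  if (length(clash)) {
    stop_arg("node id used as both gene and disease: ",
             paste(utils::head(clash, 3), collapse = ", "))
  }
  nodes <- data.frame(
    node = c(genes, disease_nodes),
    node_type = c(rep("gene", length(genes)),
                  rep("disease", length(disease_nodes))),
    stringsAsFactors = FALSE)
  new_hetero_network(nodes, do.call(rbind, edges),
                     report = list(n_skipped_associations = n_skipped))
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("Heterogeneous gene-disease network\n")
  cat("  nodes:", nrow(x$nodes),
      sprintf("(%d gene, %d disease)\n",
              sum(x$nodes$node_type == "gene"),
              sum(x$nodes$node_type == "disease")))
  et <- table(factor(x$edges$edge_type,
                     levels = c("gene_gene", "disease_disease",
                                "gene_disease")))
  cat("  edges:", nrow(x$edges),
      sprintf("(%d gene-gene, %d disease-disease, %d gene-disease)\n",
              et[1], et[2], et[3]))
  invisible(x)
}

#' @export
summary.hetero_network <- function(object, ...) {
  w <- split(object$edges$weight, object$edges$edge_type)
  cat("Edge weight ranges by type:\n")
  for (t in names(w)) {
    cat(sprintf("  %-16s [%.4g, %.4g]  n=%d\n", t, min(w[[t]]), max(w[[t]]),
                length(w[[t]])))
  }
  if (!is.null(object$report$n_skipped_associations)) {
    cat("Associations skipped (unknown gene):",
        object$report$n_skipped_associations, "\n")
  }
  invisible(object)
}

#' Serialize a network as edge-list + node-table TSVs
#'
#' Edge list columns: `node1 \t node2 \t edge_type \t weight`; node table:
#' `node \t node_type`. Output is canonical (sorted, deduplicated), so
#' assembling twice from the same inputs yields byte-identical files.
#'
#' @param net a `hetero_network`.
#' @param edge_path,node_path output TSVs (node table optional).
#' @export
write_network <- function(net, edge_path, node_path = NULL) {
  stopifnot(inherits(net, "hetero_network"))
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(node_path)) {
    utils::write.table(net$nodes, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(edge_path)
}

#' Load a network serialized by [write_network()]
#'
#' @param edge_path edge-list TSV.
#' @param node_path node-table TSV; if missing, node types are inferred from
#'   the edge types they occur in.
#' @return a `hetero_network`.
#' @export
read_network <- function(edge_path, node_path = NULL) {
  edges <- utils::read.delim(edge_path, colClasses = c("character",
                                                       "character",
                                                       "character",
                                                       "numeric"),
                             quote = "", comment.char = "")
  names(edges) <- c("node1", "node2", "edge_type", "weight")
  if (!is.null(node_path)) {
    nodes <- utils::read.delim(node_path,
                               colClasses = c("character", "character"),
                               quote = "", comment.char = "")
    names(nodes) <- c("node", "node_type")
  } else {
    # infer node types: same-type edges fix their endpoints, then types
    # propagate across gene_disease edges by elimination
    gg <- edges$edge_type == "gene_gene"
    dd <- edges$edge_type == "disease_disease"
    gd <- which(edges$edge_type == "gene_disease")
    ty <- stats::setNames(
      rep(NA_character_, length(unique(c(edges$node1, edges$node2)))),
      unique(c(edges$node1, edges$node2)))
    ty[unique(c(edges$node1[gg], edges$node2[gg]))] <- "gene"
    ty[unique(c(edges$node1[dd], edges$node2[dd]))] <- "disease"
    flip <- c(gene = "disease", disease = "gene")
    repeat {
      changed <- FALSE
      for (i in gd) {
        a <- edges$node1[i]; b <- edges$node2[i]
        if (!is.na(ty[[a]]) && is.na(ty[[b]])) {
          ty[[b]] <- flip[[ty[[a]]]]; changed <- TRUE
        } else if (is.na(ty[[a]]) && !is.na(ty[[b]])) {
          ty[[a]] <- flip[[ty[[b]]]]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    # an isolated gene_disease component is orientation-ambiguous without a
    # node table; take node1 as the disease end
    for (i in gd) {
      if (is.na(ty[[edges$node1[i]]])) {
        ty[[edges$node1[i]]] <- "disease"
        ty[[edges$node2[i]]] <- "gene"
      } else if (is.na(ty[[edges$node2[i]]])) {
        ty[[edges$node2[i]]] <- flip[[ty[[edges$node1[i]]]]]
      }
    }
    nodes <- data.frame(node = names(ty), node_type = unname(ty),
                        stringsAsFactors = FALSE)
  }
  new_hetero_network(nodes, edges)
}

# adjacency index: per node, a data.frame of (neighbor, edge_type, weight)
net_adjacency <- function(net) {
  adj <- new.env(parent = emptyenv())
  add <- function(a, b, ty, w) {
    adj[[a]] <- rbind(adj[[a]],
                      data.frame(neighbor = b, edge_type = ty, weight = w,
                                 stringsAsFactors = FALSE))
  }
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    add(e$node1[i], e$node2[i], e$edge_type[i], e$weight[i])
    add(e$node2[i], e$node1[i], e$edge_type[i], e$weight[i])
  }
  for (nd in net$nodes$node) if (is.null(adj[[nd]])) {
    adj[[nd]] <- data.frame(neighbor = character(0),
                            edge_type = character(0), weight = numeric(0),
                            stringsAsFactors = FALSE)
  }
  adj
}
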