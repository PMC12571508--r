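#' Load a STRING-like PPI edge list
#'
#' Reads a TSV with columns \code{protein1}, \code{protein2},
#' \code{combined_score}, keeps edges with score >= \code{score_threshold},
#' collapses duplicate undirected edges (keeping the maximum score) and drops
#' self-loops.
#'
#' @param path TSV file path.
#' @param score_threshold minimum combined score (default 200).
#' @return an [igraph::graph] with edge attribute \code{weight} (the score).
#' @export
loadPPIEdges <- function(path, score_threshold = 200) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("protein1", "protein2", "combined_score")
    if (!all(need %in% colnames(df)))
        stop("edge table needs columns: ", paste(need, collapse = ", "))
    score <- suppressWarnings(as.numeric(df$combined_score))
    if (anyNA(score))
        stop("malformed combined_score at line ",
             which(is.na(score))[1L] + 1L)
    df$combined_score <- score
    ppiGraph(df, score_threshold)
}

#' Build a PPI graph from an edge data.frame
#'
#' @param edges data.frame with columns \code{protein1}, \code{protein2},
#'   \code{combined_score}.
#' @param score_threshold minimum retained score (default 200).
#' @return an undirected, simplified [igraph::graph] with \code{weight}
#'   edge attribute.
#' @export
ppiGraph <- function(edges, score_threshold = 200) {
    edges <- edges[edges$combined_score >= score_threshold &
                   edges$protein1 != edges$protein2, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(edges$protein1),
                   to = as.character(edges$protein2),
                   weight = edges$combined_score), directed = FALSE)
    igraph::simplify(g, edge.attr.comb = list(weight = "max"))
}

#' Hub genes by degree or eigenvector centrality
#'
#' Degree hubs: nodes with degree >= threshold (default 20). Eigenvector
#' hubs: centrality is max-normalized to 1 over the whole graph before
#' applying the threshold (default 0.7), so the cutoff is scale-free.
#' Centralities are computed on the full graph, components included.
#'
#' @param graph an [igraph::graph].
#' @param mode \code{"degree"} or \code{"eigenvector"}.
#' @param threshold numeric cutoff; defaults 20 (degree) / 0.7 (eigenvector).
#' @return character vector of hub gene names (empty, with a warning, for an
#'   empty graph).
#' @export
hubGenes <- function(graph, mode = c("degree", "eigenvector"),
                     threshold = NULL) {
    mode <- match.arg(mode)
    if (igraph::vcount(graph) == 0L) {
        warning("empty graph: no hubs")
        return(character())
    }
    if (mode == "degree") {
        if (is.null(threshold)) threshold <- 20
        cen <- igraph::degree(graph)
    } else {
        if (is.null(threshold)) threshold <- 0.7
        if (igraph::ecount(graph) == 0L) return(character())
        ## eigen_centrality is max-normalized (scale behaviour fixed in
        ## igraph >= 2.1); weights = NA ignores edge weights
        cen <- igraph::eigen_centrality(graph, weights = NA)$vector
    }
    names(cen)[cen >= threshold]
}

#' Detect PPI communities
#'
#' Runs one of the three stacking algorithms: Girvan-Newman edge betweenness
#' or fast greedy modularity (both cut at the modularity-maximizing level of
#' their dendrogram), or Walktrap with 4-step random walks. Edge weights are
#' ignored for edge betweenness (scores are similarities, not distances) and
#' used by Walktrap/fast greedy as similarity weights.
#'
#' @param graph an [igraph::graph].
#' @param algorithm \code{"edge-betweenness"}, \code{"walktrap"} or
#'   \code{"fastgreedy"}.
#' @return A \linkS4class{SubnetworkPartition} with subnetworks named
#'   \code{"SN1"}, \code{"SN2"}, ... in decreasing size order.
#' @export
detectCommunities <- function(graph,
        algorithm = c("edge-betweenness", "walktrap", "fastgreedy")) {
    algorithm <- match.arg(algorithm)
    if (igraph::vcount(graph) == 0L)
        return(methods::new("SubnetworkPartition", algorithm = algorithm,
                            subnetworks = list()))
    comm <- switch(algorithm,
        "edge-betweenness" = igraph::cluster_edge_betweenness(
            graph, weights = NULL, directed = FALSE),
        "walktrap" = igraph::cluster_walktrap(graph, steps = 4),
        "fastgreedy" = igraph::cluster_fast_greedy(graph))
    memb <- if (algorithm == "walktrap") igraph::membership(comm) else
        bestModularityCut(graph, comm)
    sets <- split(names(memb), as.integer(memb))
    ## deterministic naming: decreasing size, ties by first node name
    ord <- order(-lengths(sets),
                 vapply(sets, function(s) sort(s)[1L], ""))
    sets <- sets[ord]
    names(sets) <- paste0("SN", seq_along(sets))
    methods::new("SubnetworkPartition", algorithm = algorithm,
                 subnetworks = sets)
}

## cut a hierarchical community dendrogram at the modularity maximum;
## near-ties (1e-10) resolve towards fewer communities
bestModularityCut <- function(graph, comm) {
    n <- igraph::vcount(graph)
    ks <- seq_len(n)
    best <- NULL; bestq <- -Inf
    for (k in ks) {
        memb <- tryCatch(igraph::cut_at(comm, no = k),
                         error = function(e) NULL)
        if (is.null(memb)) next
        q <- igraph::modularity(graph, memb)
        if (q > bestq + 1e-10) {
            bestq <- q
            best <- memb
        }
    }
    setNames(best, igraph::V(graph)$name)
}

#' @describeIn detectCommunities compact display
#' @param object a \code{SubnetworkPartition}
#' @export
setMethod("show", "SubnetworkPartition", function(object) {
    cat("SubnetworkPartition (", object@algorithm, "): ",
        length(object@subnetworks), " subnetworks, sizes ",
        paste(lengths(object@subnetworks), collapse = ", "), "\n", sep = "")
    invisible(NULL)
})

#' Pool small subnetworks into SN0
#'
#' Communities holding strictly less than \code{min_fraction} of all graph
#' nodes are merged into the miscellaneous subnetwork \code{"SN0"}; a
#' community at exactly the fraction is kept.
#'
#' @param partition \linkS4class{SubnetworkPartition}.
#' @param min_fraction minimum node fraction to stay a named subnetwork
#'   (default 0.05).
#' @return \linkS4class{SubnetworkPartition}; kept subnetworks are renumbered
#'   \code{"SN1"}, ... and \code{"SN0"} (when non-empty) comes last.
#' @export
mergeSmallSubnetworks <- function(partition, min_fraction = 0.05) {
    stopifnot(methods::is(partition, "SubnetworkPartition"))
    sets <- partition@subnetworks
    sn0 <- unlist(sets[names(sets) == "SN0"], use.names = FALSE)
    sets <- sets[names(sets) != "SN0"]
    total <- length(unlist(sets, use.names = FALSE)) + length(sn0)
    small <- lengths(sets) < min_fraction * total
    sn0 <- c(sn0, unlist(sets[small], use.names = FALSE))
    sets <- sets[!small]
    if (length(sets)) names(sets) <- paste0("SN", seq_along(sets))
    if (length(sn0)) sets$SN0 <- sort(sn0)
    methods::new("SubnetworkPartition", algorithm = partition@algorithm,
                 subnetworks = sets)
}

#' Select core DEGs by enrichment-qualified subnetwork stacking
#'
#' For each community partition (one per algorithm), a subnetwork qualifies
#' when its significant enrichment terms cover at least a fraction omega of
#' the DEG set's significant terms: |E(SN) n E(DEGs)| / |E(DEGs)| >= omega.
#' The miscellaneous subnetwork SN0 never qualifies. Within an algorithm the
#' qualifying subnetworks' DEG members are unioned; the core set is the
#' intersection of these unions across algorithms.
#'
#' @param partitions list of \linkS4class{SubnetworkPartition} objects (one
#'   per algorithm).
#' @param degs character vector: the DEG set (the universe from which core
#'   genes are drawn).
#' @param db gene-set database (see [oraEnrich()]).
#' @param background gene universe for enrichment.
#' @param omega coverage threshold in [0, 1] (default 0.25).
#' @param q_cutoff FDR cutoff defining significant terms (default 0.05).
#' @return A list: \code{core} (character, the core DEGs), \code{omega},
#'   \code{deg_terms} (E(DEGs)), and \code{coverage}, a data.frame of the
#'   per-(algorithm, subnetwork) coverage ratios and qualification calls.
#' @export
selectCoreDEGs <- function(partitions, degs, db, background, omega = 0.25,
                           q_cutoff = 0.05) {
    if (methods::is(partitions, "SubnetworkPartition"))
        partitions <- list(partitions)
    deg_enr <- oraEnrich(intersect(degs, background), db, background,
                         q_cutoff)
    deg_terms <- deg_enr$term[deg_enr$significant]
    if (!length(deg_terms))
        stop("the DEG set has no significant enrichment terms")
    subnetTerms <- function(members) {
        q <- intersect(members, background)
        if (!length(q)) return(character())
        enr <- oraEnrich(q, db, background, q_cutoff)
        enr$term[enr$significant]
    }
    cov_rows <- list(); unions <- list()
    for (part in partitions) {
        stopifnot(methods::is(part, "SubnetworkPartition"))
        keep <- character()
        for (nm in names(part@subnetworks)) {
            members <- intersect(part@subnetworks[[nm]], degs)
            ratio <- if (nm == "SN0") NA_real_ else
                length(intersect(subnetTerms(members), deg_terms)) /
                    length(deg_terms)
            qual <- !is.na(ratio) && ratio >= omega
            cov_rows[[length(cov_rows) + 1L]] <- data.frame(
                algorithm = part@algorithm, subnetwork = nm,
                n_deg_members = length(members), coverage = ratio,
                qualifies = qual)
            if (qual) keep <- union(keep, members)
        }
        unions[[part@algorithm]] <- keep
    }
    core <- Reduce(intersect, unions)
    if (!length(core))
        warning("no subnetwork qualifies for at least one algorithm; ",
                "empty core set")
    list(core = sort(core), omega = omega, deg_terms = deg_terms,
         coverage = do.call(rbind, cov_rows))
}

#' Core selection from precomputed enrichment term sets
#'
#' The combinatorial heart of [selectCoreDEGs()], exposed for small worked
#' examples: qualification and stacking given already-computed significant
#' term sets per subnetwork.
#'
#' @param partitions list of \linkS4class{SubnetworkPartition}.
#' @param subnet_terms nested list: \code{subnet_terms[[algorithm]][[SN]]} is
#'   the character vector of significant terms of that subnetwork.
#' @param deg_terms character vector E(DEGs).
#' @param degs the DEG universe (members are intersected with it).
#' @param omega coverage threshold.
#' @return character vector of core genes.
#' @export
coreFromEnrichment <- function(partitions, subnet_terms, deg_terms, degs,
                               omega = 0.25) {
    if (!length(deg_terms)) stop("deg_terms must be non-empty")
    unions <- lapply(partitions, function(part) {
        keep <- character()
        for (nm in names(part@subnetworks)) {
            if (nm == "SN0") next
            terms <- subnet_terms[[part@algorithm]][[nm]]
            ratio <- length(intersect(terms, deg_terms)) / length(deg_terms)
            if (ratio >= omega)
                keep <- union(keep, intersect(part@subnetworks[[nm]], degs))
        }
        keep
    })
    sort(Reduce(intersect, unions))
}
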