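#' Mine one-gene => one-disease association rules
#'
#' Evaluates every (gene, disease) pair over the compound transactions with
#' the standard market-basket metrics: support = P(gene & disease),
#' confidence = P(disease | gene), lift = confidence / P(disease), and the
#' odds ratio of the 2x2 co-occurrence table (Haldane-Anscombe 0.5 correction
#' when any cell is zero, flagged in \code{or_corrected}). Rules are kept
#' when support >= \code{min_support} and lift > \code{min_lift} (strict).
#'
#' @param tm \linkS4class{TransactionMatrix} (typically QC-filtered).
#' @param min_support minimum support fraction (default 0.3: the rule must
#'   hold in at least 30 percent of compounds).
#' @param min_lift rules require lift strictly above this (default 1:
#'   co-occurrence above independence).
#' @return data.frame, one row per retained rule: \code{gene},
#'   \code{disease}, \code{support}, \code{confidence}, \code{lift},
#'   \code{odds_ratio}, counts \code{n_both}, \code{n_gene_only},
#'   \code{n_disease_only}, \code{n_neither}, and \code{or_corrected}.
#' @examples
#' m <- matrix(rbinom(60, 1, 0.5), 10,
#'             dimnames = list(paste0("c", 1:10),
#'                             c(paste0("g", 1:3), paste0("d", 1:3))))
#' tm <- methods::new("TransactionMatrix", mat = m,
#'                    geneItems = paste0("g", 1:3),
#'                    diseaseItems = paste0("d", 1:3))
#' mineRules(tm, min_support = 0.2)
#' @export
mineRules <- function(tm, min_support = 0.3, min_lift = 1) {
    stopifnot(methods::is(tm, "TransactionMatrix"))
    m <- tm@mat
    r <- nrow(m)
    if (r == 0L) stop("no transactions")
    if (!length(tm@geneItems) || !length(tm@diseaseItems))
        stop("need at least one gene and one disease item")
    G <- m[, tm@geneItems, drop = FALSE]
    D <- m[, tm@diseaseItems, drop = FALSE]
    both <- crossprod(G, D)                       # genes x diseases co-counts
    ng <- colSums(G); nd <- colSums(D)
    support <- both / r
    confidence <- sweep(both, 1L, pmax(ng, 1L), "/")
    lift <- sweep(confidence, 2L, nd / r, "/")
    keep <- which(support >= min_support & lift > min_lift, arr.ind = TRUE)
    if (nrow(keep) == 0L)
        return(data.frame(gene = character(), disease = character(),
                          support = numeric(), confidence = numeric(),
                          lift = numeric(), odds_ratio = numeric(),
                          n_both = integer(), n_gene_only = integer(),
                          n_disease_only = integer(), n_neither = integer(),
                          or_corrected = logical()))
    gi <- keep[, 1L]; di <- keep[, 2L]
    n11 <- both[keep]
    n10 <- ng[gi] - n11
    n01 <- nd[di] - n11
    n00 <- r - n11 - n10 - n01
    zero <- n11 == 0 | n10 == 0 | n01 == 0 | n00 == 0
    cc <- ifelse(zero, 0.5, 0)
    oddsr <- ((n11 + cc) * (n00 + cc)) / ((n10 + cc) * (n01 + cc))
    out <- data.frame(gene = tm@geneItems[gi], disease = tm@diseaseItems[di],
                      support = support[keep], confidence = confidence[keep],
                      lift = lift[keep], odds_ratio = oddsr,
                      n_both = as.integer(n11), n_gene_only = as.integer(n10),
                      n_disease_only = as.integer(n01),
                      n_neither = as.integer(n00), or_corrected = zero,
                      row.names = NULL)
    out[order(-out$lift, -out$support, out$gene, out$disease), , drop = FALSE]
}

#' Pairwise item similarity from retained rules
#'
#' Overlap score between two diseases (or genes): the size of the
#' intersection of their associated gene (disease) sets from the retained
#' rules, divided by the product of the two set sizes --
#' sim = |S1 n S2| / (|S1| * |S2|). The product denominator is not
#' self-normalizing; \code{denominator = "sqrt-product"} switches to
#' |S1 n S2| / sqrt(|S1| * |S2|), the usual geometric-mean overlap score.
#' Items with empty association sets are excluded.
#'
#' @param rules rule table from [mineRules()].
#' @param mode \code{"disease"} (similarity between diseases via shared
#'   genes) or \code{"gene"} (via shared diseases).
#' @param denominator \code{"product"} (default, as defined above) or
#'   \code{"sqrt-product"}.
#' @return symmetric numeric matrix; the diagonal is computed by the same
#'   formula (1/|S| under the product denominator, not forced to 1).
#' @export
itemSimilarity <- function(rules, mode = c("disease", "gene"),
                           denominator = c("product", "sqrt-product")) {
    mode <- match.arg(mode)
    denominator <- match.arg(denominator)
    if (nrow(rules) == 0L) stop("no rules to compute similarity from")
    if (mode == "disease") {
        assoc <- split(rules$gene, rules$disease)
    } else {
        assoc <- split(rules$disease, rules$gene)
    }
    assoc <- lapply(assoc, unique)
    assoc <- assoc[lengths(assoc) > 0L]
    items <- names(assoc)
    k <- length(items)
    universe <- sort(unique(unlist(assoc)))
    inc <- vapply(assoc, function(s) universe %in% s,
                  logical(length(universe)))
    inc <- matrix(inc, nrow = length(universe))    # universe x items
    inter <- crossprod(inc)                        # items x items overlap
    sizes <- lengths(assoc)
    den <- outer(sizes, sizes)
    if (denominator == "sqrt-product") den <- sqrt(den)
    sim <- inter / den
    dimnames(sim) <- list(items, items)
    sim
}

#' Hierarchically cluster items on a similarity matrix
#'
#' Agglomerative clustering (average linkage by default) on the distance
#' 1 - sim, floored at zero, cut at the requested height. Labels are
#' deterministic: \code{hclust} ties break by merge order over the item
#' order of the input matrix, and cluster labels are assigned in input
#' order ([stats::cutree()]).
#'
#' @param sim symmetric similarity matrix (from [itemSimilarity()]).
#' @param cut height at which the tree is cut (distance scale).
#' @param linkage linkage method for [stats::hclust()] (default
#'   \code{"average"}).
#' @return named integer vector of cluster labels; a single item returns one
#'   cluster with a warning.
#' @export
clusterItems <- function(sim, cut, linkage = "average") {
    sim <- as.matrix(sim)
    if (nrow(sim) != ncol(sim) || any(abs(sim - t(sim)) > 1e-12))
        stop("similarity matrix must be symmetric")
    if (nrow(sim) < 2L) {
        warning("fewer than 2 items; returning a single cluster")
        return(setNames(rep(1L, nrow(sim)), rownames(sim)))
    }
    d <- pmax(1 - sim, 0)
    diag(d) <- 0
    hc <- hclust(as.dist(d), method = linkage)
    cutree(hc, h = cut)
}
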