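#' Build a compound-by-item transaction matrix
#'
#' Turns chemical-gene and chemical-disease interaction tables (CTD-style
#' pair lists) into a binary incidence matrix: one row per compound, columns
#' are the gene items followed by the disease items, entry 1 when the item is
#' recorded for the compound. Compounds with no items at all are dropped with
#' a warning.
#'
#' @param chem_gene data.frame, first two columns (compound, gene symbol).
#' @param chem_disease data.frame, first two columns (compound, disease id).
#' @return A \linkS4class{TransactionMatrix}.
#' @examples
#' cg <- data.frame(compound = c("c1", "c2"), gene = "g1")
#' cd <- data.frame(compound = "c1", disease = "d1")
#' transactionMatrix(cg, cd)
#' @export
transactionMatrix <- function(chem_gene, chem_disease) {
    cg <- pairTable(chem_gene, "chem_gene")
    cd <- pairTable(chem_disease, "chem_disease")
    genes <- sort(unique(cg$item))
    diseases <- sort(unique(cd$item))
    clash <- intersect(genes, diseases)
    if (length(clash))
        stop("item appears as both gene and disease: ",
             paste(head(clash, 5L), collapse = ", "))
    compounds <- sort(unique(c(cg$compound, cd$compound)))
    items <- c(genes, diseases)
    m <- matrix(0L, length(compounds), length(items),
                dimnames = list(compounds, items))
    all_pairs <- rbind(cg, cd)
    m[cbind(match(all_pairs$compound, compounds),
            match(all_pairs$item, items))] <- 1L
    empty <- rowSums(m) == 0L
    if (any(empty)) {
        warning("dropping ", sum(empty), " compound(s) with no items")
        m <- m[!empty, , drop = FALSE]
    }
    methods::new("TransactionMatrix", mat = m, geneItems = genes,
                 diseaseItems = diseases)
}

pairTable <- function(x, what) {
    x <- as.data.frame(x)
    if (ncol(x) < 2L || nrow(x) == 0L)
        stop(what, " must be a non-empty table of (compound, item) pairs")
    out <- data.frame(compound = as.character(x[[1L]]),
                      item = as.character(x[[2L]]))
    unique(out[complete.cases(out), ])
}

#' Accessors for TransactionMatrix
#'
#' @param x a \linkS4class{TransactionMatrix}.
#' @return \code{transactionItems}: the binary matrix; \code{geneItems} /
#'   \code{diseaseItems}: the item label vectors.
#' @export
transactionItems <- function(x) x@mat

#' @rdname transactionItems
#' @export
geneItems <- function(x) x@geneItems

#' @rdname transactionItems
#' @export
diseaseItems <- function(x) x@diseaseItems

#' @describeIn transactionMatrix compact display
#' @param object a \code{TransactionMatrix}
#' @export
setMethod("show", "TransactionMatrix", function(object) {
    cat("TransactionMatrix:", nrow(object@mat), "compounds x",
        length(object@geneItems), "genes +",
        length(object@diseaseItems), "diseases\n")
    invisible(NULL)
})

#' Quality-control filter on transaction columns
#'
#' Removes items whose activity score (column sum) is <= \code{min_count - 1},
#' i.e. items recorded for at most one compound under the default. Rows are
#' untouched.
#'
#' @param tm \linkS4class{TransactionMatrix}.
#' @param min_count minimum column sum an item must reach to survive
#'   (default 2, i.e. drop column sums <= 1).
#' @return filtered \linkS4class{TransactionMatrix}.
#' @export
qcFilterTransactions <- function(tm, min_count = 2L) {
    stopifnot(methods::is(tm, "TransactionMatrix"))
    keep <- colSums(tm@mat) >= min_count
    if (!any(keep)) stop("no items survive QC")
    m <- tm@mat[, keep, drop = FALSE]
    methods::new("TransactionMatrix", mat = m,
                 geneItems = intersect(tm@geneItems, colnames(m)),
                 diseaseItems = intersect(tm@diseaseItems, colnames(m)))
}
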