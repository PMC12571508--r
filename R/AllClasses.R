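#' @import methods
#' @importFrom stats pf pt p.adjust rnorm runif phyper var sd cor quantile
#'   hclust cutree as.dist dist glm predict binomial aggregate setNames
#'   complete.cases rbinom
#' @importFrom utils read.delim write.table head modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
NULL

DESIGN_COLS <- c("sample_id", "group", "compound", "dose", "time", "replicate")

#' ToxExperiment: expression values on a nested toxicogenomics design
#'
#' A \linkS4class{SummarizedExperiment} whose columns (samples) carry the
#' nested design annotation \code{group}, \code{compound}, \code{dose},
#' \code{time} and \code{replicate}, and whose single assay \code{"log2fc"}
#' holds log2 fold-change expression versus matched controls (genes in rows).
#' Validity enforces the nesting rules: every compound belongs to exactly one
#' group and every sample to exactly one (compound, dose, time) cell replicate.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no extra slots are added.
#' @seealso [ToxExperiment()], [clusterIndex()], [hlmTest()]
#' @export
setClass("ToxExperiment", contains = "SummarizedExperiment")

setValidity("ToxExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    miss <- setdiff(DESIGN_COLS, colnames(cd))
    if (length(miss))
        return(paste("missing design columns:", paste(miss, collapse = ", ")))
    if (ncol(object) == 0L)
        return("empty design: no samples")
    if (anyDuplicated(cd$sample_id))
        return("duplicate sample_id in design")
    ## a compound may not appear in two groups
    tab <- unique(data.frame(compound = as.character(cd$compound),
                             group = as.character(cd$group)))
    if (anyDuplicated(tab$compound))
        return("compound assigned to more than one group")
    if (length(SummarizedExperiment::assayNames(object)) < 1L)
        return("an assay is required")
    y <- SummarizedExperiment::assay(object)
    if (!is.numeric(y))
        return("assay must be numeric")
    if (anyNA(y))
        return("assay contains missing values")
    if (anyDuplicated(rownames(object)))
        return("gene ids (rownames) must be unique")
    TRUE
})

#' Quadratic-form projectors of the hierarchical F-statistic
#'
#' Holds the dense n-by-n projector matrices used to express the between-group
#' and within-cell sums of squares as quadratic forms pi = y'Ay and
#' psi = y'By, together with the scale factor eta = (n-p)/(a-1) and the two
#' F degrees of freedom. Both matrices are symmetric idempotent; trace(A) =
#' a-1 and trace(B) = n-p.
#'
#' @slot A numeric matrix, between-group projector.
#' @slot B numeric matrix, within-cell residual projector.
#' @slot eta numeric(1), (n-p)/(a-1).
#' @slot df1 integer(1), a-1.
#' @slot df2 integer(1), n-p.
#' @seealso [quadraticForms()]
#' @export
setClass("QuadraticForms",
    representation(A = "matrix", B = "matrix", eta = "numeric",
                   df1 = "integer", df2 = "integer"))

setValidity("QuadraticForms", function(object) {
    n <- nrow(object@A)
    if (ncol(object@A) != n || any(dim(object@B) != n))
        return("A and B must be square matrices of equal order")
    if (object@df1 < 0L) return("df1 must be >= 0")
    if (object@df2 < 1L) return("df2 must be >= 1")
    TRUE
})

#' Compound-by-item transaction matrix for association-rule mining
#'
#' Binary incidence of items (genes then diseases) across compound
#' transactions. Gene and disease item labels are disjoint; each row is the
#' item set of one compound.
#'
#' @slot mat binary (0/1) integer matrix, compounds in rows, items in columns.
#' @slot geneItems character, column names that are genes.
#' @slot diseaseItems character, column names that are diseases.
#' @seealso [transactionMatrix()], [mineRules()]
#' @export
setClass("TransactionMatrix",
    representation(mat = "matrix", geneItems = "character",
                   diseaseItems = "character"))

setValidity("TransactionMatrix", function(object) {
    m <- object@mat
    if (!all(m %in% c(0L, 1L))) return("entries must be 0/1")
    if (anyDuplicated(colnames(m))) return("item labels must be unique")
    if (length(intersect(object@geneItems, object@diseaseItems)))
        return("an item cannot be both gene and disease")
    if (!setequal(colnames(m), c(object@geneItems, object@diseaseItems)))
        return("columns must be exactly the gene and disease items")
    TRUE
})

#' Community partition of a PPI network
#'
#' Disjoint subnetworks (node sets) covering all graph nodes, produced by one
#' community-detection algorithm. After [mergeSmallSubnetworks()], communities
#' below the minimum size fraction are pooled into the miscellaneous
#' subnetwork \code{"SN0"}.
#'
#' @slot algorithm character(1), one of \code{"edge-betweenness"},
#'   \code{"walktrap"}, \code{"fastgreedy"}.
#' @slot subnetworks named list of character vectors (node sets); the pooled
#'   miscellaneous set, when present, is named \code{"SN0"}.
#' @seealso [detectCommunities()], [selectCoreDEGs()]
#' @export
setClass("SubnetworkPartition",
    representation(algorithm = "character", subnetworks = "list"))

setValidity("SubnetworkPartition", function(object) {
    nodes <- unlist(object@subnetworks, use.names = FALSE)
    if (anyDuplicated(nodes)) return("subnetworks must be disjoint")
    if (length(object@subnetworks) && is.null(names(object@subnetworks)))
        return("subnetworks must be named")
    TRUE
})
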