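#' Construct a ToxExperiment
#'
#' Bundles a log2 fold-change expression matrix with its nested design
#' annotation. Expression is supplied samples-by-genes (the orientation of the
#' flat TSV interchange format) or genes-by-samples; rows of the design table
#' must match the samples one-to-one via \code{sample_id}.
#'
#' @param expr numeric matrix of log2 fold-changes, either samples x genes
#'   (rownames = sample ids) or genes x samples (colnames = sample ids).
#' @param design data.frame with columns \code{sample_id}, \code{group},
#'   \code{compound}, \code{dose}, \code{time}, \code{replicate}.
#' @return A \linkS4class{ToxExperiment} (genes in rows, samples in columns).
#' @examples
#' des <- data.frame(sample_id = paste0("s", 1:4),
#'                   group = rep(c("pos", "neg"), each = 2),
#'                   compound = rep(c("c1", "c2"), each = 2),
#'                   dose = 1, time = 1, replicate = rep(1:2, 2))
#' y <- matrix(rnorm(8), 4, 2, dimnames = list(des$sample_id, c("g1", "g2")))
#' te <- ToxExperiment(y, des)
#' @export
ToxExperiment <- function(expr, design) {
    design <- validateDesign(design)
    expr <- as.matrix(expr)
    if (!is.numeric(expr)) stop("expression matrix must be numeric")
    sid <- as.character(design$sample_id)
    if (!is.null(rownames(expr)) && all(sid %in% rownames(expr))) {
        expr <- t(expr[sid, , drop = FALSE])
    } else if (!is.null(colnames(expr)) && all(sid %in% colnames(expr))) {
        expr <- expr[, sid, drop = FALSE]
    } else if (nrow(expr) == nrow(design) && ncol(expr) != nrow(design)) {
        rownames(expr) <- sid
        expr <- t(expr)
    } else if (ncol(expr) == nrow(design)) {
        colnames(expr) <- sid
    } else {
        stop("cannot align expression matrix to design samples")
    }
    if (is.null(rownames(expr)))
        rownames(expr) <- paste0("gene", seq_len(nrow(expr)))
    cd <- S4Vectors::DataFrame(design, row.names = sid)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2fc = expr), colData = cd)
    methods::new("ToxExperiment", se)
}

## normalize/validate a design table; shared by ToxExperiment() and the
## functions that accept a raw data.frame design
validateDesign <- function(design) {
    design <- as.data.frame(design)
    miss <- setdiff(DESIGN_COLS, colnames(design))
    if (length(miss))
        stop("design is missing columns: ", paste(miss, collapse = ", "))
    if (nrow(design) == 0L) stop("empty design: no samples")
    if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
    tab <- unique(design[, c("compound", "group")])
    if (anyDuplicated(tab$compound))
        stop("compound assigned to more than one group")
    design
}

#' Design annotation of a ToxExperiment
#'
#' @param x a \linkS4class{ToxExperiment}.
#' @return data.frame with the design columns, one row per sample.
#' @export
hierDesign <- function(x) {
    stopifnot(methods::is(x, "ToxExperiment"))
    as.data.frame(SummarizedExperiment::colData(x))[, DESIGN_COLS]
}

#' Expression values as a samples-by-genes matrix
#'
#' The orientation used by all the model mathematics (Y of dimension n x h).
#'
#' @param x a \linkS4class{ToxExperiment}.
#' @return numeric matrix, samples in rows, genes in columns.
#' @export
exprMatrix <- function(x) {
    stopifnot(methods::is(x, "ToxExperiment"))
    t(SummarizedExperiment::assay(x, "log2fc"))
}

#' @describeIn ToxExperiment compact display
#' @param object a \code{ToxExperiment}
#' @export
setMethod("show", "ToxExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("ToxExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  groups:   ", paste(unique(as.character(cd$group)), collapse = ", "), "\n")
    cat("  compounds:", length(unique(cd$compound)),
        " doses:", length(unique(cd$dose)),
        " times:", length(unique(cd$time)), "\n")
    if ("is_deg" %in% colnames(SummarizedExperiment::rowData(object)))
        cat("  simulated truth: ",
            sum(SummarizedExperiment::rowData(object)$is_deg),
            " true DEGs\n", sep = "")
    invisible(NULL)
})
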