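#' Read an experiment from flat TSV files
#'
#' The interchange format: the expression TSV has \code{sample_id} as its
#' first column and one column per gene; the design TSV has the columns
#' \code{sample_id}, \code{group}, \code{compound}, \code{dose}, \code{time},
#' \code{replicate}.
#'
#' @param expr_path path to the expression TSV.
#' @param design_path path to the design TSV.
#' @return A \linkS4class{ToxExperiment}.
#' @export
readToxExperiment <- function(expr_path, design_path) {
    expr <- read.delim(expr_path, check.names = FALSE,
                       stringsAsFactors = FALSE)
    if (colnames(expr)[1L] != "sample_id")
        stop("expression TSV must start with a sample_id column")
    design <- read.delim(design_path, stringsAsFactors = FALSE)
    y <- as.matrix(expr[, -1L, drop = FALSE])
    rownames(y) <- as.character(expr$sample_id)
    ToxExperiment(y, design)
}

#' Write an experiment to flat TSV files
#'
#' @param te \linkS4class{ToxExperiment}.
#' @param expr_path,design_path output paths; either may be NULL to skip.
#' @param truth_path optional path for the simulation truth (written only
#'   when \code{rowData} carries \code{is_deg}).
#' @return invisibly, the paths written.
#' @export
writeToxExperiment <- function(te, expr_path = NULL, design_path = NULL,
                               truth_path = NULL) {
    stopifnot(methods::is(te, "ToxExperiment"))
    written <- character()
    if (!is.null(expr_path)) {
        y <- exprMatrix(te)
        df <- data.frame(sample_id = rownames(y), y, check.names = FALSE)
        write.table(df, expr_path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        written <- c(written, expr_path)
    }
    if (!is.null(design_path)) {
        write.table(hierDesign(te), design_path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        written <- c(written, design_path)
    }
    rd <- SummarizedExperiment::rowData(te)
    if (!is.null(truth_path) && "is_deg" %in% colnames(rd)) {
        write.table(data.frame(gene = rownames(te), as.data.frame(rd)),
                    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
        written <- c(written, truth_path)
    }
    invisible(written)
}

writeResultTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
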