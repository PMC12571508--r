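#' Leave-(b_i - 1)-out reduced designs
#'
#' Builds the r = sum(b_i) reduced designs of the outlier-refinement scheme.
#' The subset tagged by compound c_ij keeps only c_ij in its own (focal) group
#' i and every compound of every other group, so a gene driven by a single
#' chemical loses its signal in all subsets that retain a different compound
#' of that group.
#'
#' @param design design data.frame or \linkS4class{ToxExperiment}.
#' @return list of length r; each element has \code{compound} (the retained
#'   focal compound), \code{group} (its group) and \code{rows} (logical vector
#'   selecting the subset's samples in design row order).
#' @export
reducedDesigns <- function(design) {
    if (methods::is(design, "ToxExperiment")) design <- hierDesign(design)
    design <- validateDesign(design)
    index <- clusterIndex(design)
    if (index$a < 2L) stop("at least two compound groups are required")
    comp <- as.character(index$compound)
    lapply(names(index$group_of_compound), function(cj) {
        gi <- index$group_of_compound[[cj]]
        drop <- names(index$group_of_compound)[
            index$group_of_compound == gi & names(index$group_of_compound) != cj]
        list(compound = cj, group = gi, rows = !(comp %in% drop))
    })
}

#' Refine a DEG set by leave-(b_i - 1)-out intersection
#'
#' Computes the initial DEG set on the full design, re-tests on every reduced
#' design from [reducedDesigns()] with the same alpha and correction (the
#' adjustment always uses the full gene universe so thresholds are
#' comparable), and intersects: genes must be significant in the full design
#' and in every subset. Genes whose significance rides on a single chemical's
#' outlying expression drop out.
#'
#' @param x \linkS4class{ToxExperiment}, or samples-by-genes matrix.
#' @param design design data.frame when \code{x} is a matrix.
#' @param alpha significance level (default 0.05).
#' @param correction \code{"bonferroni"} (default) or \code{"BH"}.
#' @return list with \code{initial} (character, DEGs on the full design),
#'   \code{refined} (character, the intersection), \code{n_subsets} (r) and
#'   \code{table}: per initial DEG, the number of subsets in which it stays
#'   significant and whether it was kept.
#' @export
refineDEGs <- function(x, design = NULL, alpha = 0.05,
                       correction = c("bonferroni", "BH")) {
    correction <- match.arg(correction)
    if (methods::is(x, "ToxExperiment")) {
        Y <- exprMatrix(x)
        design <- hierDesign(x)
    } else {
        if (is.null(design)) stop("design required when x is a matrix")
        Y <- as.matrix(x)
        design <- validateDesign(design)
    }
    if (is.null(colnames(Y))) colnames(Y) <- paste0("gene", seq_len(ncol(Y)))
    h <- ncol(Y)
    full <- hlmTest(Y, design, alpha = alpha, correction = correction,
                    icc = FALSE)
    initial <- full$gene[full$significant]
    plan <- reducedDesigns(design)
    ## per-subset significance; adjustment over the full universe of h genes
    sig <- matrix(FALSE, h, length(plan), dimnames = list(colnames(Y), NULL))
    for (j in seq_along(plan)) {
        rows <- plan[[j]]$rows
        sub <- design[rows, , drop = FALSE]
        subidx <- clusterIndex(sub)
        if (subidx$n <= subidx$p)
            stop("subset retaining compound '", plan[[j]]$compound,
                 "' has no within-cell replication (n = p); cannot test")
        res <- hlmTest(Y[rows, , drop = FALSE], sub, alpha = alpha,
                       correction = correction, icc = FALSE)
        sig[, j] <- res$p_adj < alpha
    }
    nsig <- rowSums(sig)
    refined <- intersect(initial, colnames(Y)[nsig == length(plan)])
    tab <- data.frame(gene = initial,
                      n_subsets_significant = nsig[initial],
                      kept = initial %in% refined, row.names = NULL)
    list(initial = initial, refined = refined, n_subsets = length(plan),
         table = tab)
}
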