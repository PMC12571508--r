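#' Index the nested design into groups and cells
#'
#' Precomputes the bookkeeping used by every model computation: the sample
#' membership of each (compound, dose, time) cell, group sizes, and the counts
#' a (groups), b_i (compounds per group), p (realized cells) and n (samples).
#' Only realized cells are counted; empty combinations of the factors do not
#' contribute to p.
#'
#' @param design a design data.frame (see [ToxExperiment()]) or a
#'   \linkS4class{ToxExperiment}.
#' @return list with components \code{group}, \code{cell}, \code{compound}
#'   (factors over samples, in design row order), \code{a}, \code{b_i},
#'   \code{p}, \code{n}, \code{n_i}, \code{n_cell},
#'   \code{group_of_compound}, and \code{cell_group} (group of each cell).
#' @examples
#' des <- expand.grid(replicate = 1:3, time = 1:4, dose = 1:3,
#'                    compound = 1:14)
#' des$group <- ifelse(des$compound <= 7, "pos", "neg")
#' des$sample_id <- paste0("s", seq_len(nrow(des)))
#' idx <- clusterIndex(des)
#' c(idx$n, idx$p, idx$a)  # 504 168 2
#' @export
clusterIndex <- function(design) {
    if (methods::is(design, "ToxExperiment")) design <- hierDesign(design)
    design <- validateDesign(design)
    ## groups keep their order of first appearance (the positive/reference
    ## group is conventionally listed first), not alphabetical order
    group <- factor(design$group, levels = unique(as.character(design$group)))
    compound <- factor(design$compound)
    cell <- interaction(design$compound, design$dose, design$time,
                        drop = TRUE, lex.order = TRUE)
    n <- nrow(design)
    n_i <- as.vector(table(group))
    names(n_i) <- levels(group)
    n_cell <- as.vector(table(cell))
    names(n_cell) <- levels(cell)
    gc <- unique(data.frame(compound = as.character(compound),
                            group = as.character(group)))
    group_of_compound <- setNames(gc$group, gc$compound)
    b_i <- as.vector(table(factor(gc$group, levels = levels(group))))
    names(b_i) <- levels(group)
    ## group of each cell, via its compound
    cell_comp <- vapply(split(as.character(compound), cell), `[`, "", 1L)
    cell_group <- group_of_compound[cell_comp]
    list(group = group, cell = cell, compound = compound,
         a = nlevels(group), b_i = b_i, p = nlevels(cell), n = n,
         n_i = n_i, n_cell = n_cell,
         group_of_compound = group_of_compound, cell_group = cell_group)
}
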