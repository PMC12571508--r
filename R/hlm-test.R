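#' Hierarchical linear model F-test over all genes
#'
#' Tests, for every gene, the null hypothesis that all compound-group effects
#' are zero, using the F-statistic F = eta * pi / psi where pi is the
#' group-size-weighted between-group sum of squares, psi the within-cell
#' residual sum of squares, and eta = (n-p)/(a-1). Under the null (and no
#' residual clustering) F follows the central F distribution with (a-1, n-p)
#' degrees of freedom. pi and psi are the diagonals of Y'AY and Y'BY; they are
#' accumulated through group and cell means, never through the dense n x n
#' projectors.
#'
#' Genes with psi = 0 are flagged: \code{"degenerate"} (pi > 0, F = Inf,
#' p = 0) or \code{"constant"} (pi = 0, p = 1). All other genes carry flag
#' \code{"ok"}.
#'
#' @param x a \linkS4class{ToxExperiment}, or a samples-by-genes numeric
#'   matrix (then \code{design} is required).
#' @param design design data.frame; ignored when \code{x} is a
#'   \code{ToxExperiment}.
#' @param alpha significance level used for the \code{significant} column
#'   (default 0.05).
#' @param correction multiple-testing correction for \code{p_adj}:
#'   \code{"bonferroni"} (default, the DEG-calling rule) or \code{"BH"}.
#' @param icc if \code{TRUE} (default) add the per-gene intracluster
#'   correlation estimate (see [estimateICC()]).
#' @return data.frame with one row per gene: \code{gene}, \code{F},
#'   \code{df1}, \code{df2}, \code{pi}, \code{psi}, \code{p}, \code{p_adj},
#'   \code{avg_log2fc} (two-group designs; NA otherwise), \code{icc},
#'   \code{flag}, \code{significant}.
#' @examples
#' te <- simulateTox(h = 50, kappa = 0.2, delta = 1, rho = 0.3, seed = 1)
#' head(hlmTest(te))
#' @export
hlmTest <- function(x, design = NULL, alpha = 0.05,
                    correction = c("bonferroni", "BH"), icc = TRUE) {
    correction <- match.arg(correction)
    if (methods::is(x, "ToxExperiment")) {
        Y <- exprMatrix(x)
        index <- clusterIndex(hierDesign(x))
    } else {
        if (is.null(design)) stop("design required when x is a matrix")
        Y <- as.matrix(x)
        index <- asClusterIndex(design)
    }
    if (nrow(Y) != index$n) stop("expression matrix not aligned to design")
    if (index$a < 2L) stop("at least two compound groups are required")
    if (index$n <= index$p) stop("df2 = 0: no within-cell replication")
    if (is.null(colnames(Y))) colnames(Y) <- paste0("gene", seq_len(ncol(Y)))

    qt <- quadTerms(Y, index)
    df1 <- index$a - 1L
    df2 <- index$n - index$p
    eta <- df2 / df1
    tol <- 1e-12 * pmax(qt$totss, 1)
    psi0 <- qt$psi <= tol
    Fg <- ifelse(psi0, ifelse(qt$pi <= tol, 0, Inf), eta * qt$pi / qt$psi)
    pg <- ifelse(psi0, ifelse(qt$pi <= tol, 1, 0),
                 pf(eta * qt$pi / pmax(qt$psi, .Machine$double.xmin),
                    df1, df2, lower.tail = FALSE))
    flag <- ifelse(psi0, ifelse(qt$pi <= tol, "constant", "degenerate"), "ok")
    p_adj <- adjustPvalues(pg, correction)
    avg <- if (index$a == 2L) summarizeLog2FC(Y, index, "overall") else
        rep(NA_real_, ncol(Y))
    res <- data.frame(gene = colnames(Y), F = Fg, df1 = df1, df2 = df2,
                      pi = qt$pi, psi = qt$psi, p = pg, p_adj = p_adj,
                      avg_log2fc = avg,
                      icc = if (icc) estimateICC(Y, index) else NA_real_,
                      flag = flag, significant = p_adj < alpha,
                      row.names = NULL)
    res
}

## between-group and within-cell quadratic terms per gene (diag of Y'AY, Y'BY)
quadTerms <- function(Y, index) {
    gm <- rowsum(Y, index$group, reorder = TRUE) / index$n_i    # a x h
    cm <- rowsum(Y, index$cell, reorder = TRUE) / index$n_cell  # p x h
    ybar <- colSums(Y) / index$n
    pi_ <- colSums(gm^2 * index$n_i) - index$n * ybar^2
    psi <- colSums(Y^2) - colSums(cm^2 * index$n_cell)
    totss <- colSums(Y^2) - index$n * ybar^2
    list(pi = pmax(pi_, 0), psi = pmax(psi, 0), totss = pmax(totss, 0))
}

#' Per-gene intracluster correlation estimate
#'
#' Moment estimator of rho = sigma_o^2 / (sigma_o^2 + sigma_eps^2): group
#' means are removed, then a one-way random-effects ANOVA treats each
#' (compound, dose, time) cell as a cluster. sigma_eps^2 is the within-cell
#' mean square; sigma_o^2 = max(0, (MS_between - MS_within)/n_tilde) with
#' n_tilde the unbalanced-ANOVA coefficient (n - sum(n_cell^2)/n) / (p - 1).
#' Negative moment estimates truncate to zero, so the estimate lies in [0, 1].
#'
#' @param Y samples-by-genes matrix or \linkS4class{ToxExperiment}.
#' @param index cluster index (or design); ignored when \code{Y} is a
#'   \code{ToxExperiment}.
#' @return numeric vector of ICC estimates in [0, 1]; NA when only one cell
#'   exists or there is no within-cell replication.
#' @export
estimateICC <- function(Y, index = NULL) {
    if (methods::is(Y, "ToxExperiment")) {
        index <- clusterIndex(hierDesign(Y))
        Y <- exprMatrix(Y)
    } else {
        Y <- as.matrix(Y)
        index <- asClusterIndex(index)
    }
    h <- ncol(Y)
    if (index$p < 2L || index$n <= index$p)
        return(rep(NA_real_, h))
    ## remove group means so the group effect does not masquerade as clustering
    gm <- rowsum(Y, index$group, reorder = TRUE) / index$n_i
    Yc <- Y - gm[as.integer(index$group), , drop = FALSE]
    cm <- rowsum(Yc, index$cell, reorder = TRUE) / index$n_cell
    ybar <- colSums(Yc) / index$n
    ssb <- colSums(cm^2 * index$n_cell) - index$n * ybar^2
    ssw <- colSums(Yc^2) - colSums(cm^2 * index$n_cell)
    msb <- ssb / (index$p - 1L)
    msw <- ssw / (index$n - index$p)
    ntilde <- (index$n - sum(index$n_cell^2) / index$n) / (index$p - 1L)
    s2o <- pmax(0, (msb - msw) / ntilde)
    denom <- s2o + msw
    ifelse(denom > 0, s2o / denom, 0)
}

#' Average log2 fold-change summaries
#'
#' For two-group designs, \code{"overall"} returns mean(positive samples) -
#' mean(negative samples) per gene, the x-axis of the classic volcano display.
#' The first group level is taken as positive unless \code{positive} names
#' another. Levels \code{"compound"}, \code{"dose"} and \code{"time"} return
#' per-gene means within each level of that factor, separately by group, as a
#' matrix (rows = group:level).
#'
#' @param Y samples-by-genes matrix or \linkS4class{ToxExperiment}.
#' @param index cluster index or design (ignored for \code{ToxExperiment}).
#' @param level \code{"overall"} (default), \code{"compound"}, \code{"dose"}
#'   or \code{"time"}.
#' @param positive group label treated as positive; default first level.
#' @return numeric vector (overall) or matrix (other levels).
#' @export
summarizeLog2FC <- function(Y, index = NULL,
                            level = c("overall", "compound", "dose", "time"),
                            positive = NULL) {
    level <- match.arg(level)
    design <- NULL
    if (methods::is(Y, "ToxExperiment")) {
        design <- hierDesign(Y)
        index <- clusterIndex(design)
        Y <- exprMatrix(Y)
    } else {
        Y <- as.matrix(Y)
        if (is.data.frame(index)) design <- index
        index <- asClusterIndex(index)
    }
    if (level == "overall") {
        if (index$a != 2L)
            stop("overall log2FC difference needs exactly two groups")
        lev <- levels(index$group)
        if (is.null(positive)) positive <- lev[1L]
        if (!positive %in% lev) stop("unknown positive group: ", positive)
        gm <- rowsum(Y, index$group, reorder = TRUE) / index$n_i
        return(gm[positive, ] - gm[setdiff(lev, positive), ])
    }
    if (is.null(design))
        stop("a design data.frame is required for level summaries")
    fac <- switch(level, compound = index$compound,
                  dose = factor(design$dose), time = factor(design$time))
    key <- interaction(index$group, fac, drop = TRUE, lex.order = TRUE)
    rowsum(Y, key, reorder = TRUE) / as.vector(table(key))
}

#' Multiple-testing adjustment
#'
#' Bonferroni (min(1, h*p)) or Benjamini-Hochberg step-up adjustment, with
#' input validation. Thin wrapper over [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method \code{"bonferroni"} or \code{"BH"}.
#' @return adjusted p-values, same length and order as \code{p}.
#' @export
adjustPvalues <- function(p, method = c("bonferroni", "BH")) {
    method <- match.arg(method)
    if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must be numeric in [0, 1]")
    p.adjust(p, method = method)
}
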