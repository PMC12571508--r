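#' Pooled two-group Welch t-test per gene
#'
#' The group-pooling comparator: all samples of each compound group are
#' treated as independent observations and compared with an unequal-variance
#' two-sample t-test (Satterthwaite degrees of freedom), vectorized over
#' genes. Ignores the nested structure by construction.
#'
#' @param x \linkS4class{ToxExperiment} or samples-by-genes matrix.
#' @param design design data.frame when \code{x} is a matrix.
#' @return data.frame per gene: \code{gene}, \code{t}, \code{df}, \code{p}.
#' @examples
#' y <- cbind(g1 = c(1, 2, 3, 4, 5, 6))
#' des <- data.frame(sample_id = paste0("s", 1:6),
#'                   group = rep(c("a", "b"), each = 3),
#'                   compound = rep(c("c1", "c2"), each = 3),
#'                   dose = 1, time = 1, replicate = rep(1:3, 2))
#' welchPooledTest(y, des)  # t = 3.674..., df = 4
#' @export
welchPooledTest <- function(x, design = NULL) {
    d <- twoGroupData(x, design, min_per_group = 2L)
    n1 <- d$n1; n2 <- d$n2
    m1 <- colMeans(d$Y1); m2 <- colMeans(d$Y2)
    v1 <- (colSums(d$Y1^2) - n1 * m1^2) / (n1 - 1)
    v2 <- (colSums(d$Y2^2) - n2 * m2^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
                    ifelse(m1 == m2, 0, Inf * sign(m1 - m2)))
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 n1 + n2 - 2)
    p <- ifelse(is.finite(tstat), 2 * pt(abs(tstat), df, lower.tail = FALSE),
                0)
    p[tstat == 0 & se2 == 0] <- 1
    data.frame(gene = d$genes, t = tstat, df = df, p = p, row.names = NULL)
}

#' Moderated t-test per gene (empirical-Bayes variance shrinkage)
#'
#' Pooled two-group comparison with gene-wise variances shrunk towards a
#' common prior: the posterior variance is (d0*s0^2 + dg*sg^2)/(d0 + dg) and
#' the moderated t is referred to a t distribution on d0 + dg degrees of
#' freedom. The prior (d0, s0^2) is obtained by moment matching on the log
#' residual variances: under the scaled inverse-chi-square model, log(sg^2)
#' has variance trigamma(dg/2) + trigamma(d0/2), so d0 solves
#' trigamma(d0/2) = var(log sg^2) - trigamma(dg/2) (d0 = Inf when the
#' observed spread does not exceed the sampling floor).
#'
#' @inheritParams welchPooledTest
#' @return data.frame per gene: \code{gene}, \code{t}, \code{df}, \code{p},
#'   plus attributes \code{d0} and \code{s0} (prior df and variance).
#' @export
moderatedTTest <- function(x, design = NULL) {
    d <- twoGroupData(x, design, min_per_group = 3L)
    n1 <- d$n1; n2 <- d$n2
    m1 <- colMeans(d$Y1); m2 <- colMeans(d$Y2)
    dg <- n1 + n2 - 2
    s2 <- ((colSums(d$Y1^2) - n1 * m1^2) + (colSums(d$Y2^2) - n2 * m2^2)) / dg
    pos <- s2 > 0
    if (sum(pos) < 2L) stop("too few genes with positive variance")
    z <- log(s2[pos])
    ## moment matching on log variances
    evar <- var(z) - trigamma(dg / 2)
    if (is.na(evar) || evar <= 0) {
        d0 <- Inf
        s0 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2))
    } else {
        d0 <- 2 * trigammaInverse(evar)
        s0 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
    }
    stilde2 <- if (is.finite(d0)) (d0 * s0 + dg * s2) / (d0 + dg) else
        rep(s0, length(s2))
    se <- sqrt(stilde2 * (1 / n1 + 1 / n2))
    tstat <- ifelse(se > 0, (m1 - m2) / se, 0)
    dft <- if (is.finite(d0)) d0 + dg else Inf
    p <- 2 * pt(abs(tstat), dft, lower.tail = FALSE)
    out <- data.frame(gene = d$genes, t = tstat, df = dft, p = p,
                      row.names = NULL)
    attr(out, "d0") <- d0
    attr(out, "s0") <- s0
    out
}

## Newton solve of trigamma(y) = x, as used for the variance-prior df
trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, 2L)
        y <- y + dif
        if (abs(dif / y) < 1e-8) break
    }
    y
}

## split a two-group experiment into per-group sample-by-gene matrices
twoGroupData <- function(x, design, min_per_group) {
    if (methods::is(x, "ToxExperiment")) {
        Y <- exprMatrix(x)
        design <- hierDesign(x)
    } else {
        if (is.null(design)) stop("design required when x is a matrix")
        Y <- as.matrix(x)
        design <- validateDesign(design)
    }
    if (is.null(colnames(Y))) colnames(Y) <- paste0("gene", seq_len(ncol(Y)))
    g <- factor(design$group)
    if (nlevels(g) != 2L) stop("exactly two groups are required")
    i1 <- g == levels(g)[1L]
    n1 <- sum(i1); n2 <- sum(!i1)
    if (min(n1, n2) < min_per_group)
        stop("each group needs at least ", min_per_group, " samples")
    list(Y1 = Y[i1, , drop = FALSE], Y2 = Y[!i1, , drop = FALSE],
         n1 = n1, n2 = n2, genes = colnames(Y))
}
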