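#' Dense quadratic-form projectors for the hierarchical F-statistic
#'
#' Builds the n x n matrices A and B with pi = y'Ay (between-group sum of
#' squares, weighted by group size) and psi = y'By (within-cell residual sum
#' of squares), so that F = eta * pi / psi with eta = (n-p)/(a-1). A is the
#' difference between the group-mean projector and the grand-mean projector;
#' B is the complement of the cell-mean projector. The dense matrices exist
#' for verification and pedagogy; [hlmTest()] computes the same diagonals of
#' Y'AY and Y'BY through grouped means without materializing them.
#'
#' @param index cluster index from [clusterIndex()], or a design/
#'   \linkS4class{ToxExperiment} (indexed on the fly).
#' @return A \linkS4class{QuadraticForms} object.
#' @examples
#' des <- data.frame(sample_id = paste0("s", 1:4),
#'                   group = rep(c("pos", "neg"), each = 2),
#'                   compound = rep(c("c1", "c2"), each = 2),
#'                   dose = 1, time = 1, replicate = rep(1:2, 2))
#' qf <- quadraticForms(clusterIndex(des))
#' c(sum(diag(qf@A)), sum(diag(qf@B)), qf@eta)  # 1 2 2
#' @export
quadraticForms <- function(index) {
    index <- asClusterIndex(index)
    n <- index$n; p <- index$p; a <- index$a
    if (n <= p)
        stop("df2 = 0: no within-cell replication (n = p)")
    Zg <- indicatorMatrix(index$group)                # n x a indicator
    Zc <- indicatorMatrix(index$cell)                 # n x p indicator
    A <- sweep(Zg, 2L, index$n_i, "/") %*% t(Zg) - 1 / n
    B <- diag(n) - sweep(Zc, 2L, index$n_cell, "/") %*% t(Zc)
    dimnames(A) <- dimnames(B) <- NULL
    methods::new("QuadraticForms", A = A, B = B,
                 eta = if (a > 1L) (n - p) / (a - 1) else Inf,
                 df1 = as.integer(a - 1L), df2 = as.integer(n - p))
}

## 0/1 membership matrix of a factor (robust to single-level factors)
indicatorMatrix <- function(fac) {
    z <- matrix(0, length(fac), nlevels(fac),
                dimnames = list(NULL, levels(fac)))
    z[cbind(seq_along(fac), as.integer(fac))] <- 1
    z
}

asClusterIndex <- function(x) {
    if (is.list(x) && all(c("group", "cell", "n", "p", "a") %in% names(x)))
        return(x)
    clusterIndex(x)
}

#' @describeIn quadraticForms compact display
#' @param object a \code{QuadraticForms}
#' @export
setMethod("show", "QuadraticForms", function(object) {
    cat("QuadraticForms: n =", nrow(object@A),
        " df = (", object@df1, ",", object@df2, ")  eta =", object@eta, "\n")
    invisible(NULL)
})
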