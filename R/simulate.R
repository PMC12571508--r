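#' Map effect size to explained variance
#'
#' r2 = (delta / sqrt(delta^2 + 4))^2, the classical conversion between a
#' standardized two-group mean difference (Cohen's d) and the squared
#' point-biserial correlation under balanced groups.
#'
#' @param delta nonnegative effect size.
#' @return explained variance fraction in [0, 1), monotone in \code{delta}.
#' @examples
#' effectToR2(c(0, 1, 2))  # 0 0.2 0.5
#' @export
effectToR2 <- function(delta) {
    if (!is.numeric(delta) || anyNA(delta) || any(delta < 0))
        stop("delta must be nonnegative")
    (delta / sqrt(delta^2 + 4))^2
}

#' Partition the intercept variance across the three nesting levels
#'
#' Draws (sigma_beta^2, sigma_gamma^2, sigma_lambda^2) from U(0, rho) and
#' rescales so they sum to rho exactly, one triple per gene.
#'
#' @param rho total intercept variance (>= 0).
#' @param n number of triples to draw (default 1).
#' @return 3 x n matrix with rows \code{beta}, \code{gamma}, \code{lambda};
#'   columns sum to \code{rho}.
#' @export
partitionVariances <- function(rho, n = 1L) {
    if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0)
        stop("rho must be a nonnegative scalar")
    out <- matrix(0, 3L, n, dimnames = list(c("beta", "gamma", "lambda"), NULL))
    if (rho > 0) {
        u <- matrix(runif(3L * n, 0, rho), 3L, n)
        out[] <- sweep(u, 2L, colSums(u), "/") * rho
    }
    out
}

#' Simulate a nested toxicogenomics experiment
#'
#' Generates standardized log2 fold-change expression on a two-group nested
#' design (compound -> dose -> time -> replicate). Each gene is built from
#' independent Gaussian layers: a per-gene overall intercept mu ~ U(-theta,
#' theta), a group effect, compound / dose / time random intercepts with
#' variances summing to the target intracluster variance, and residual noise.
#' For true DEGs the two group means sit at mu + r and mu - r with
#' r = delta / sqrt(delta^2 + 4), so the explained variance is r^2 =
#' [effectToR2()] and sigma_eps^2 + rho + r^2 = 1: every gene has total
#' variance ~1. Non-DEG genes have delta = 0; their intercept variance is
#' controlled by \code{nullIntercepts}: \code{"zero"} (default; no clustering,
#' the "perfectly non-DEG" null), \code{"match"} (intercept variance rho, the
#' configuration used for ICC parameter-recovery studies), or \code{"small"}
#' (U(0, 0.02), minor biological noise).
#'
#' @param h number of genes.
#' @param kappa fraction of true DEGs (round(kappa*h) genes).
#' @param delta effect size for true DEGs (>= 0).
#' @param rho total intercept variance of true-DEG genes, in [0, 1).
#' @param compounds integer vector of compounds per group (length = number of
#'   groups, default \code{c(7, 7)}).
#' @param doses,times,replicates integers (defaults 3, 4, 3).
#' @param theta bound of the uniform overall intercept (default 1).
#' @param nullIntercepts one of \code{"zero"}, \code{"match"}, \code{"small"}.
#' @param seed optional integer seed (local RNG; the global seed is restored).
#' @return \linkS4class{ToxExperiment} with the simulation truth in
#'   \code{rowData}: \code{is_deg}, \code{delta}, plus per-gene variance
#'   components \code{s2_beta}, \code{s2_gamma}, \code{s2_lambda},
#'   \code{s2_eps}.
#' @examples
#' te <- simulateTox(h = 100, kappa = 0.1, delta = 0.5, rho = 0.5, seed = 1)
#' te
#' @export
simulateTox <- function(h, kappa = 0.1, delta = 0.5, rho = 0,
                        compounds = c(7L, 7L), doses = 3L, times = 4L,
                        replicates = 3L, theta = 1,
                        nullIntercepts = c("zero", "match", "small"),
                        seed = NULL) {
    nullIntercepts <- match.arg(nullIntercepts)
    stopifnot(h >= 1, kappa >= 0, kappa <= 1, rho >= 0, rho < 1, delta >= 0,
              theta >= 0, length(compounds) >= 2, all(compounds >= 1))
    r2 <- effectToR2(delta)
    if (rho + r2 >= 1)
        stop("rho + r2(delta) must be < 1 so the residual variance is positive")
    if (!is.null(seed)) {
        old <- globalSeed()
        on.exit(restoreSeed(old), add = TRUE)
        set.seed(seed)
    }
    design <- makeNestedDesign(compounds, doses, times, replicates)
    index <- clusterIndex(design)
    n <- index$n
    h1 <- round(kappa * h)
    ## delta = 0 means no effect: nothing is truly differential
    is_deg <- c(rep(delta > 0, h1), rep(FALSE, h - h1))

    ## per-gene variance partitions
    s <- matrix(0, 3L, h, dimnames = list(c("beta", "gamma", "lambda"), NULL))
    if (h1 > 0) s[, seq_len(h1)] <- partitionVariances(rho, h1)
    if (h1 < h) {
        s[, seq.int(h1 + 1L, h)] <- switch(nullIntercepts,
            zero  = 0,
            match = partitionVariances(rho, h - h1),
            small = {
                u <- matrix(runif(3L * (h - h1)), 3L)
                tot <- runif(h - h1, 0, 0.02)
                sweep(u, 2L, colSums(u), "/") * rep(tot, each = 3L)
            })
    }
    s2o <- colSums(s)
    reff <- ifelse(is_deg, sqrt(r2), 0)
    s2eps <- 1 - s2o - reff^2

    mu <- runif(h, -theta, theta)
    ## effect +r for the first-listed group ("pos"), -r otherwise
    tau <- ifelse(design$group == design$group[1L], 1, -1)
    nb <- length(index$group_of_compound)
    dosecell <- interaction(design$compound, design$dose, drop = TRUE)
    ndc <- nlevels(dosecell)
    beta <- matrix(rnorm(nb * h), nb, h) * rep(sqrt(s["beta", ]), each = nb)
    gam <- matrix(rnorm(ndc * h), ndc, h) * rep(sqrt(s["gamma", ]), each = ndc)
    lam <- matrix(rnorm(index$p * h), index$p, h) *
        rep(sqrt(s["lambda", ]), each = index$p)
    eps <- matrix(rnorm(n * h), n, h) * rep(sqrt(s2eps), each = n)
    Y <- rep(mu, each = n) + outer(tau, reff) +
        beta[as.integer(index$compound), , drop = FALSE] +
        gam[as.integer(dosecell), , drop = FALSE] +
        lam[as.integer(index$cell), , drop = FALSE] + eps
    dimnames(Y) <- list(design$sample_id, sprintf("gene%04d", seq_len(h)))

    te <- ToxExperiment(Y, design)
    SummarizedExperiment::rowData(te) <- S4Vectors::DataFrame(
        is_deg = is_deg, delta = ifelse(is_deg, delta, 0),
        s2_beta = s["beta", ], s2_gamma = s["gamma", ],
        s2_lambda = s["lambda", ], s2_eps = s2eps)
    te
}

#' Fully crossed nested design table
#'
#' @param compounds integer vector: compounds per group; groups are labelled
#'   \code{"pos"}, \code{"neg"} when length 2, else \code{"g1"}, ...
#' @param doses,times,replicates integers.
#' @return design data.frame suitable for [ToxExperiment()].
#' @export
makeNestedDesign <- function(compounds = c(7L, 7L), doses = 3L, times = 4L,
                             replicates = 3L) {
    a <- length(compounds)
    glab <- if (a == 2L) c("pos", "neg") else paste0("g", seq_len(a))
    comp <- sprintf("c%02d", seq_len(sum(compounds)))
    grp <- rep(glab, compounds)
    des <- expand.grid(replicate = seq_len(replicates), time = seq_len(times),
                       dose = seq_len(doses), compound = comp,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    des$group <- grp[match(des$compound, comp)]
    des$sample_id <- sprintf("s%05d", seq_len(nrow(des)))
    des[, DESIGN_COLS]
}

#' Plant a compound-restricted shift in simulated data
#'
#' Adds \code{shift} to the chosen genes in samples of the chosen compounds
#' only. Used to create chemical-specific outlier genes for refinement
#' studies.
#'
#' @param te \linkS4class{ToxExperiment}.
#' @param genes gene ids (rownames) to modify.
#' @param compounds compound labels whose samples receive the shift.
#' @param shift numeric scalar added to the selected entries.
#' @return modified \code{ToxExperiment}.
#' @export
plantEffect <- function(te, genes, compounds, shift) {
    stopifnot(methods::is(te, "ToxExperiment"))
    des <- hierDesign(te)
    gi <- match(genes, rownames(te))
    if (anyNA(gi)) stop("unknown gene id")
    cols <- des$compound %in% compounds
    if (!any(cols)) stop("unknown compound")
    a <- SummarizedExperiment::assay(te, "log2fc")
    a[gi, cols] <- a[gi, cols] + shift
    SummarizedExperiment::assay(te, "log2fc") <- a
    te
}

globalSeed <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
}

restoreSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}
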