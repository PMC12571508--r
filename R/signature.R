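#' Block-averaging operator over design levels
#'
#' Builds the n x c matrix Omega whose columns average samples within each
#' cell of the chosen level: \code{"time"} gives the (compound, dose, time)
#' cells, \code{"dose"} the (compound, dose) cells, \code{"compound"} the
#' compounds. Y' Omega (genes x cells) equals the per-cell means. Each column
#' sums to 1 and each row has exactly one nonzero entry 1/n_cell.
#'
#' @param index cluster index, design data.frame, or
#'   \linkS4class{ToxExperiment}.
#' @param level \code{"time"}, \code{"dose"} or \code{"compound"}.
#' @return numeric matrix (samples x cells) with cell labels as colnames.
#' @export
averagingOperator <- function(index, level = c("time", "dose", "compound")) {
    level <- match.arg(level)
    design <- if (methods::is(index, "ToxExperiment")) hierDesign(index)
              else if (is.data.frame(index)) validateDesign(index)
              else NULL
    if (is.null(design)) {
        if (!is.list(index) || is.null(index$cell))
            stop("need a design, ToxExperiment, or cluster index")
        if (level != "time")
            stop("dose/compound levels need the design table")
        fac <- index$cell
    } else {
        fac <- switch(level,
            time = interaction(design$compound, design$dose, design$time,
                               drop = TRUE, lex.order = TRUE),
            dose = interaction(design$compound, design$dose,
                               drop = TRUE, lex.order = TRUE),
            compound = factor(design$compound))
    }
    omega <- indicatorMatrix(fac)
    sweep(omega, 2L, colSums(omega), "/")
}

#' Mean AUC of logistic regression under repeated stratified k-fold CV
#'
#' Fits a logistic regression of the two-class label on the signature
#' features within each training fold and scores the held-out fold; the AUC
#' of each fold's scores is the Mann-Whitney statistic. Folds are stratified
#' by class and re-drawn each repeat; fold assignment is reproducible from
#' \code{seed}.
#'
#' @param X numeric matrix, samples x features (the signature columns).
#' @param labels two-level factor (or coercible) of length nrow(X).
#' @param folds number of CV folds (default 10).
#' @param repeats number of CV repetitions (default 100).
#' @param seed integer seed for fold assignment (default 1).
#' @return list with \code{mean_auc}, \code{auc_per_repeat} (numeric vector,
#'   mean over folds within each repeat), \code{folds}, \code{repeats}.
#' @export
logisticCvAuc <- function(X, labels, folds = 10L, repeats = 100L, seed = 1L) {
    X <- as.matrix(X)
    y <- factor(labels)
    if (nlevels(y) != 2L) stop("labels must have exactly two classes")
    if (nrow(X) != length(y)) stop("labels must match rows of X")
    if (min(table(y)) < folds)
        stop("each class needs at least ", folds,
             " samples for stratified ", folds, "-fold CV")
    old <- globalSeed(); on.exit(restoreSeed(old), add = TRUE)
    set.seed(seed)
    pos <- levels(y)[2L]
    dat <- data.frame(X)
    per_repeat <- numeric(repeats)
    for (rep in seq_len(repeats)) {
        fold <- integer(length(y))
        for (cl in levels(y)) {        # stratified assignment
            idx <- which(y == cl)
            fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
        }
        aucs <- numeric(folds)
        for (f in seq_len(folds)) {
            test <- fold == f
            fit <- suppressWarnings(glm(y ~ ., family = binomial(),
                data = cbind(y = y[!test], dat[!test, , drop = FALSE])))
            sc <- suppressWarnings(
                predict(fit, dat[test, , drop = FALSE], type = "link"))
            aucs[f] <- aucFromScores(sc, y[test] == pos)
        }
        per_repeat[rep] <- mean(aucs)
    }
    list(mean_auc = mean(per_repeat), auc_per_repeat = per_repeat,
         folds = folds, repeats = repeats)
}

## rank-based (Mann-Whitney) AUC; ties get 0.5 credit
aucFromScores <- function(scores, is_pos) {
    n1 <- sum(is_pos); n0 <- sum(!is_pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(scores)
    (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Ward hierarchical clustering of a signature
#'
#' Euclidean distances, \code{"ward.D2"} linkage (the squared-distance Ward
#' update), optional cut into k clusters and average silhouette width per
#' requested k. Constant data produce a warning and a tree with all merge
#' heights zero (deterministic merge order follows row order).
#'
#' @param X numeric matrix, rows are the objects to cluster.
#' @param linkage linkage for [stats::hclust()] (default \code{"ward.D2"}).
#' @param k optional integer vector of cluster counts to cut at.
#' @return list with \code{hclust} (the tree), and when \code{k} is given,
#'   \code{labels} (matrix, one column per k) and \code{silhouette} (mean
#'   silhouette width per k; NA for k = 1).
#' @export
hclustSignature <- function(X, linkage = "ward.D2", k = NULL) {
    X <- as.matrix(X)
    if (nrow(X) < 2L) {
        warning("single row: trivial tree")
        return(list(hclust = NULL,
                    labels = matrix(1L, 1L, length(k)), silhouette = NA))
    }
    d <- dist(X)
    if (all(d < .Machine$double.eps))
        warning("constant data: all merge heights are zero")
    hc <- hclust(d, method = linkage)
    out <- list(hclust = hc)
    if (!is.null(k)) {
        lab <- vapply(k, function(kk) cutree(hc, k = kk),
                      integer(nrow(X)))
        colnames(lab) <- paste0("k", k)
        sil <- vapply(seq_along(k), function(i) {
            if (k[i] < 2L || k[i] >= nrow(X)) return(NA_real_)
            mean(cluster::silhouette(lab[, i], d)[, "sil_width"])
        }, 0)
        out$labels <- lab
        out$silhouette <- setNames(sil, colnames(lab))
    }
    out
}

#' Cross-platform signature validation with a random-signature null
#'
#' Pearson correlation of two per-gene summary profiles (one matched
#' condition per platform) over the signature genes, compared against the
#' correlations of \code{n_random} size-matched gene sets drawn without
#' replacement from the shared universe. The empirical p uses the add-one
#' rule, so it is never zero.
#'
#' @param profile_a,profile_b named numeric vectors of per-gene summaries
#'   (e.g. average log2 fold-changes) from the two platforms.
#' @param signature character vector of signature genes; at least 3 must be
#'   shared by both profiles.
#' @param n_random number of random signatures (default 10000; must be >= 1).
#' @param seed integer seed (default 1).
#' @return list with \code{observed_r}, \code{null_r} (numeric vector),
#'   \code{p} = (1 + #\{null >= observed\}) / (1 + n_random),
#'   \code{n_shared} and \code{universe_size}.
#' @export
crossPlatformValidation <- function(profile_a, profile_b, signature,
                                    n_random = 10000L, seed = 1L) {
    if (n_random < 1L) stop("n_random must be >= 1")
    shared <- intersect(names(profile_a), names(profile_b))
    if (length(shared) < 3L) stop("fewer than 3 genes shared by platforms")
    sig <- intersect(signature, shared)
    if (length(sig) < 3L)
        stop("signature has fewer than 3 genes shared by both platforms")
    a <- profile_a[shared]; b <- profile_b[shared]
    observed <- cor(a[sig], b[sig])
    old <- globalSeed(); on.exit(restoreSeed(old), add = TRUE)
    set.seed(seed)
    null_r <- vapply(seq_len(n_random), function(i) {
        g <- sample(shared, length(sig))
        cor(a[g], b[g])
    }, 0)
    list(observed_r = observed, null_r = null_r,
         p = (1 + sum(null_r >= observed)) / (1 + n_random),
         n_shared = length(sig), universe_size = length(shared))
}
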