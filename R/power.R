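#' Power and type-I error experiment over simulated datasets
#'
#' Repeatedly simulates nested two-group datasets with [simulateTox()], tests
#' every gene with the chosen methods, and reports power (rejection fraction
#' among true DEGs) and type-I error (rejection fraction among null genes).
#' Rejection is at adjusted p < alpha; \code{adjust = "bonferroni"} with
#' \code{nTests} equal to the nominal screen size reproduces the genome-wide
#' DEG-calling rule at reduced simulation cost (per-gene power does not
#' depend on how many genes are co-simulated, only on the threshold), while
#' \code{adjust = "none"} gives the raw per-gene level.
#'
#' @param grid data.frame of scenarios; recognized columns \code{delta},
#'   \code{rho}, \code{r} (total compounds, split as evenly as possible over
#'   two groups), \code{kappa}, \code{h}, \code{doses}, \code{times},
#'   \code{replicates}, \code{nullIntercepts}. Missing columns take the
#'   [simulateTox()] defaults (with \code{h = 100}, \code{kappa = 0.5}).
#' @param methods subset of \code{"hlm"}, \code{"welch"}, \code{"modt"}.
#' @param nreps replicate datasets per scenario (default 100).
#' @param alpha significance level (default 0.05).
#' @param adjust \code{"bonferroni"}, \code{"BH"}, or \code{"none"}.
#' @param nTests multiplicity used by the adjustment; default the number of
#'   genes simulated per dataset. Set to the nominal screen size (e.g. 10000)
#'   when simulating fewer genes than the screen being emulated.
#' @param seed integer; per-replicate seeds are drawn reproducibly from it.
#' @return data.frame with one row per (scenario, method): scenario columns,
#'   \code{method}, \code{power}, \code{type1}, \code{nreps}.
#' @examples
#' grid <- data.frame(delta = 0.5, rho = c(0, 0.5), r = 4, h = 40)
#' powerExperiment(grid, methods = "hlm", nreps = 3, seed = 1)
#' @export
powerExperiment <- function(grid, methods = c("hlm", "welch"), nreps = 100L,
                            alpha = 0.05,
                            adjust = c("bonferroni", "BH", "none"),
                            nTests = NULL, seed = 1L) {
    adjust <- match.arg(adjust)
    known <- c("hlm", "welch", "modt")
    if (!all(methods %in% known))
        stop("unknown method label: ",
             paste(setdiff(methods, known), collapse = ", "))
    grid <- as.data.frame(grid)
    if (nreps < 1L) stop("nreps must be >= 1")
    defaults <- list(delta = 0.5, rho = 0, r = 14L, kappa = 0.5, h = 100L,
                     doses = 3L, times = 4L, replicates = 3L,
                     nullIntercepts = "zero")
    out <- vector("list", nrow(grid) * length(methods))
    k <- 0L
    set.seed(seed)
    repseeds <- matrix(sample.int(.Machine$integer.max, nrow(grid) * nreps),
                       nrow(grid), nreps)
    for (i in seq_len(nrow(grid))) {
        cfg <- defaults
        for (nm in intersect(names(defaults), colnames(grid))) {
            v <- grid[[nm]][i]
            if (!is.na(v)) cfg[[nm]] <- v
        }
        b1 <- ceiling(cfg$r / 2); b2 <- cfg$r - b1
        thr_mult <- if (adjust == "bonferroni")
            max(if (is.null(nTests)) cfg$h else nTests, 1L) else 1
        rej <- array(0, c(length(methods), 2L),
                     dimnames = list(methods, c("power", "type1")))
        cnt <- rej
        for (rep in seq_len(nreps)) {
            te <- simulateTox(h = cfg$h, kappa = cfg$kappa, delta = cfg$delta,
                              rho = cfg$rho, compounds = c(b1, b2),
                              doses = cfg$doses, times = cfg$times,
                              replicates = cfg$replicates,
                              nullIntercepts = cfg$nullIntercepts,
                              seed = repseeds[i, rep] %% .Machine$integer.max)
            truth <- SummarizedExperiment::rowData(te)$is_deg
            Y <- exprMatrix(te); des <- hierDesign(te)
            idx <- clusterIndex(des)
            for (mth in methods) {
                p <- switch(mth,
                    hlm = {
                        qt <- quadTerms(Y, idx)
                        Fg <- (idx$n - idx$p) / (idx$a - 1) * qt$pi /
                            pmax(qt$psi, .Machine$double.xmin)
                        pf(Fg, idx$a - 1, idx$n - idx$p, lower.tail = FALSE)
                    },
                    welch = welchPooledTest(Y, des)$p,
                    modt = moderatedTTest(Y, des)$p)
                hit <- if (adjust == "BH")
                    p.adjust(p, "BH") < alpha
                else pmin(1, p * thr_mult) < alpha
                rej[mth, "power"] <- rej[mth, "power"] + sum(hit[truth])
                rej[mth, "type1"] <- rej[mth, "type1"] + sum(hit[!truth])
                cnt[mth, "power"] <- cnt[mth, "power"] + sum(truth)
                cnt[mth, "type1"] <- cnt[mth, "type1"] + sum(!truth)
            }
        }
        for (mth in methods) {
            k <- k + 1L
            out[[k]] <- data.frame(delta = cfg$delta, rho = cfg$rho,
                r = cfg$r, kappa = cfg$kappa, h = cfg$h, method = mth,
                power = if (cnt[mth, "power"] > 0)
                    rej[mth, "power"] / cnt[mth, "power"] else NA_real_,
                type1 = if (cnt[mth, "type1"] > 0)
                    rej[mth, "type1"] / cnt[mth, "type1"] else NA_real_,
                nreps = nreps)
        }
    }
    do.call(rbind, out[seq_len(k)])
}
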