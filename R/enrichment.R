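#' Read a GMT gene-set database
#'
#' GMT dialect: one tab-separated line per set -- term id, description, then
#' the member symbols. Members are whitespace-trimmed, case-preserved and
#' deduplicated.
#'
#' @param path file path.
#' @return list with \code{sets} (named list of character vectors) and
#'   \code{descriptions} (named character).
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty GMT file: ", path)
    sets <- list(); desc <- character()
    for (i in seq_along(lines)) {
        f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
        if (length(f) < 3L)
            stop("GMT line ", i, " has fewer than 3 fields")
        members <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
        if (!length(members))
            stop("GMT line ", i, " has no members")
        if (f[1L] %in% names(sets))
            stop("duplicate term id in GMT: ", f[1L])
        sets[[f[1L]]] <- members
        desc[[f[1L]]] <- f[2L]
    }
    list(sets = sets, descriptions = desc)
}

#' Write a GMT gene-set database
#'
#' @param db list as returned by [readGMT()] (or a bare named list of sets).
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeGMT <- function(db, path) {
    sets <- if (is.list(db) && !is.null(db$sets)) db$sets else db
    desc <- if (is.list(db) && !is.null(db$descriptions)) db$descriptions
            else setNames(rep("na", length(sets)), names(sets))
    lines <- vapply(names(sets), function(id)
        paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Over-representation analysis against a gene-set database
#'
#' Upper-tail hypergeometric test per term: with a background of N genes, a
#' term of K genes, a query of k genes and an overlap of x, p = P(X >= x)
#' (the observed count included). q-values are Benjamini-Hochberg across the
#' tested terms; terms with zero background intersection are skipped.
#'
#' @param query character vector of gene symbols (must lie in background).
#' @param db gene-set database from [readGMT()] or a named list of sets.
#' @param background character vector, the tested gene universe.
#' @param q_cutoff FDR threshold for the \code{significant} column
#'   (default 0.05).
#' @return data.frame ordered by p: \code{term}, \code{description},
#'   \code{overlap}, \code{set_size}, \code{query_size}, \code{bg_size},
#'   \code{p}, \code{q}, \code{significant}, plus a \code{genes} column with
#'   the overlapping symbols (comma-separated).
#' @examples
#' db <- list(sets = list(T1 = paste0("g", 1:5)),
#'            descriptions = c(T1 = "toy"))
#' oraEnrich(paste0("g", 1:5), db, paste0("g", 1:20))$p  # 76/15504
#' @export
oraEnrich <- function(query, db, background, q_cutoff = 0.05) {
    sets <- if (is.list(db) && !is.null(db$sets)) db$sets else db
    desc <- if (is.list(db) && !is.null(db$descriptions)) db$descriptions
            else setNames(rep(NA_character_, length(sets)), names(sets))
    background <- unique(as.character(background))
    if (!length(background)) stop("empty background")
    query <- unique(as.character(query))
    if (!all(query %in% background))
        stop("query genes outside the background: ",
             paste(head(setdiff(query, background), 5L), collapse = ", "))
    N <- length(background); k <- length(query)
    rows <- lapply(names(sets), function(id) {
        set <- intersect(sets[[id]], background)
        K <- length(set)
        if (K == 0L) return(NULL)   # no background intersection: skip
        ov <- intersect(query, set)
        x <- length(ov)
        p <- phyper(x - 1L, K, N - K, k, lower.tail = FALSE)
        data.frame(term = id, description = unname(desc[id]), overlap = x,
                   set_size = K, query_size = k, bg_size = N, p = p,
                   genes = paste(sort(ov), collapse = ","),
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows)) stop("no term intersects the background")
    out <- do.call(rbind, rows)
    out$q <- p.adjust(out$p, "BH")
    out$significant <- out$q < q_cutoff
    out <- out[order(out$p, out$term),
               c("term", "description", "overlap", "set_size", "query_size",
                 "bg_size", "p", "q", "significant", "genes")]
    rownames(out) <- NULL
    out
}
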