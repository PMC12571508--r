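test_that("edge ingest applies the score threshold and deduplicates", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("protein1\tprotein2\tcombined_score",
                 "a\tb\t150", "b\tc\t200", "c\td\t900", "d\tc\t400",
                 "e\te\t999"), f)
    g <- loadPPIEdges(f, score_threshold = 200)
    expect_equal(igraph::ecount(g), 2)          # a-b dropped, c-d deduped
    expect_false("a" %in% igraph::V(g)$name)         # its only edge was subthreshold
    ed <- igraph::as_data_frame(g)
    cd_edge <- ed[(ed$from == "c" & ed$to == "d") |
                  (ed$from == "d" & ed$to == "c"), ]
    expect_identical(nrow(cd_edge), 1L)
    expect_equal(cd_edge$weight, 900)                # duplicate keeps the max
    # self loop never enters
    expect_false("e" %in% igraph::V(g)$name)

    bad <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("protein1\tprotein2\tcombined_score", "a\tb\toops"), bad)
    expect_error(loadPPIEdges(bad), "line 2")
})

test_that("edge round trip preserves the edge set", {
    set.seed(71)
    ed <- data.frame(protein1 = sample(letters[1:8], 12, TRUE),
                     protein2 = sample(letters[1:8], 12, TRUE),
                     combined_score = sample(200:999, 12))
    g1 <- ppiGraph(ed)
    f <- withr::local_tempfile(fileext = ".tsv")
    df <- igraph::as_data_frame(g1)
    write.table(data.frame(protein1 = df$from, protein2 = df$to,
                           combined_score = df$weight),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    g2 <- loadPPIEdges(f)
    cano <- function(g) {
        d <- igraph::as_data_frame(g)
        ep <- t(apply(d[, 1:2], 1, sort))
        paste(ep[, 1], ep[, 2])
    }
    expect_setequal(cano(g2), cano(g1))
})

test_that("hub calls by degree and max-normalized eigenvector centrality", {
    g <- igraph::make_full_graph(22)
    igraph::V(g)$name <- paste0("n", 1:22)
    expect_setequal(hubGenes(g, "degree"), paste0("n", 1:22))  # degree 21
    star <- igraph::make_star(4, mode = "undirected", center = 1)
    igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
    # leaves sit at 1/sqrt(3) ~ 0.577 < 0.7 after max normalization
    expect_identical(hubGenes(star, "eigenvector"), "hub")
    edgeless <- igraph::make_empty_graph(3, directed = FALSE)
    igraph::V(edgeless)$name <- letters[1:3]
    expect_length(hubGenes(edgeless, "degree"), 0L)
    expect_warning(hubGenes(igraph::make_empty_graph(0, directed = FALSE)),
                   "empty graph")
})

test_that("all three community algorithms split two bridged cliques", {
    g <- igraph::disjoint_union(igraph::make_full_graph(10),
                                igraph::make_full_graph(10))
    g <- igraph::add_edges(g, c(1, 11))
    igraph::V(g)$name <- paste0("n", 1:20)
    for (alg in c("edge-betweenness", "walktrap", "fastgreedy")) {
        part <- detectCommunities(g, alg)
        expect_length(part@subnetworks, 2L)
        expect_setequal(part@subnetworks[["SN1"]],
                        paste0("n", if ("n1" %in% part@subnetworks[["SN1"]])
                               1:10 else 11:20))
    }
    clique <- igraph::make_full_graph(6)
    igraph::V(clique)$name <- paste0("c", 1:6)
    expect_length(detectCommunities(clique, "fastgreedy")@subnetworks, 1L)
    expect_error(detectCommunities(clique, "louvain"), "arg")
})

test_that("small subnetworks pool into SN0 with a strict-below rule", {
    mk <- function(sizes) {
        sets <- lapply(seq_along(sizes), function(i)
            paste0("s", i, "_", seq_len(sizes[i])))
        names(sets) <- paste0("SN", seq_along(sizes))
        methods::new("SubnetworkPartition", algorithm = "walktrap",
                     subnetworks = sets)
    }
    m <- mergeSmallSubnetworks(mk(c(90, 6, 4)))    # 4 < 5% of 100 -> SN0
    expect_setequal(names(m@subnetworks), c("SN1", "SN2", "SN0"))
    expect_length(m@subnetworks$SN0, 4L)
    m2 <- mergeSmallSubnetworks(mk(c(90, 5, 5)))   # exactly 5%: kept
    expect_false("SN0" %in% names(m2@subnetworks))
    m3 <- mergeSmallSubnetworks(mk(rep(2, 10)), min_fraction = 0.3)
    expect_identical(names(m3@subnetworks), "SN0")
    expect_length(m3@subnetworks$SN0, 20L)
    # disjoint cover preserved
    expect_setequal(unname(unlist(m@subnetworks)),
                    unname(unlist(mk(c(90, 6, 4))@subnetworks)))
})

test_that("edgeless graphs collapse entirely into SN0", {
    g <- igraph::make_empty_graph(30, directed = FALSE)
    igraph::V(g)$name <- paste0("n", 1:30)
    part <- detectCommunities(g, "walktrap")
    expect_length(part@subnetworks, 30L)
    merged <- mergeSmallSubnetworks(part)
    expect_identical(names(merged@subnetworks), "SN0")
})

mkPart <- function(alg, sets) {
    names(sets) <- ifelse(names(sets) == "", paste0("SN", seq_along(sets)),
                          names(sets))
    methods::new("SubnetworkPartition", algorithm = alg, subnetworks = sets)
}

test_that("core selection: coverage ratio, SN0 exclusion, stacking", {
    degs <- paste0("g", 1:8)
    p1 <- mkPart("edge-betweenness",
                 list(SN1 = c("g1", "g2", "g3"), SN2 = c("g4", "g5"),
                      SN0 = c("g6")))
    p2 <- mkPart("walktrap",
                 list(SN1 = c("g2", "g3", "g4"), SN2 = c("g7", "g8")))
    terms <- list(
        "edge-betweenness" = list(SN1 = c("t1", "t2", "t3"), SN2 = "t9",
                                  SN0 = c("t1", "t2", "t3", "t4")),
        "walktrap" = list(SN1 = c("t1", "t4"), SN2 = character()))
    deg_terms <- c("t1", "t2", "t3", "t4")
    # EBC: SN1 covers 3/4 >= 0.25 -> {g1,g2,g3}; SN2 0/4; SN0 ignored
    # walktrap: SN1 covers 2/4 -> {g2,g3,g4}
    core <- coreFromEnrichment(list(p1, p2), terms, deg_terms, degs,
                               omega = 0.25)
    expect_identical(core, c("g2", "g3"))
    # brute force over all (algorithm, subnetwork) pairs
    brute <- Reduce(intersect, lapply(list(p1, p2), function(p) {
        u <- character()
        for (nm in setdiff(names(p@subnetworks), "SN0")) {
            cov <- length(intersect(terms[[p@algorithm]][[nm]], deg_terms)) /
                length(deg_terms)
            if (cov >= 0.25)
                u <- union(u, intersect(p@subnetworks[[nm]], degs))
        }
        u
    }))
    expect_setequal(core, brute)
})

test_that("raising omega never enlarges the core set", {
    degs <- paste0("g", 1:8)
    p1 <- mkPart("edge-betweenness",
                 list(SN1 = c("g1", "g2", "g3"), SN2 = c("g4", "g5")))
    p2 <- mkPart("walktrap",
                 list(SN1 = c("g2", "g3", "g4"), SN2 = c("g1", "g5")))
    terms <- list(
        "edge-betweenness" = list(SN1 = c("t1", "t2", "t3"), SN2 = c("t1")),
        "walktrap" = list(SN1 = c("t1", "t2"), SN2 = c("t3")))
    deg_terms <- c("t1", "t2", "t3", "t4")
    cores <- lapply(c(0, 0.25, 0.5, 0.75, 1), function(w)
        coreFromEnrichment(list(p1, p2), terms, deg_terms, degs, omega = w))
    for (i in seq_len(length(cores) - 1))
        expect_true(all(cores[[i + 1]] %in% cores[[i]]))
    # omega = 0: every non-SN0 subnetwork qualifies
    expect_setequal(cores[[1]],
                    intersect(unlist(p1@subnetworks), unlist(p2@subnetworks)))
})

test_that("end-to-end core selection over a synthetic PPI instance", {
    # two modules; module 1 carries the DEG-enriched terms
    g <- igraph::disjoint_union(igraph::make_full_graph(8),
                                igraph::make_full_graph(8))
    g <- igraph::add_edges(g, c(1, 9))
    igraph::V(g)$name <- paste0("g", 1:16)
    parts <- lapply(c("edge-betweenness", "walktrap", "fastgreedy"),
                    function(a) mergeSmallSubnetworks(detectCommunities(g, a)))
    db <- list(sets = list(T1 = paste0("g", 1:8), T2 = paste0("g", 5:12),
                           T3 = paste0("g", 9:16)))
    bg <- paste0("g", 1:40)
    degs <- paste0("g", 1:16)
    sel <- selectCoreDEGs(parts, degs, db, bg, omega = 0.25)
    expect_true(all(sel$core %in% degs))
    expect_true(length(sel$deg_terms) >= 1)
    expect_identical(
        nrow(sel$coverage),
        sum(vapply(parts, function(p) length(p@subnetworks), 0L)))
})
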