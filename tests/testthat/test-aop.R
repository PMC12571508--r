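test_that("transaction matrix from pair tables", {
    cg <- data.frame(compound = c("c1", "c2"), gene = c("g1", "g1"))
    cd <- data.frame(compound = "c1", disease = "d1")
    tm <- transactionMatrix(cg, cd)
    m <- transactionItems(tm)
    expect_identical(dim(m), c(2L, 2L))
    expect_identical(unname(m["c1", ]), c(1L, 1L))
    expect_identical(unname(m["c2", ]), c(1L, 0L))
    expect_identical(geneItems(tm), "g1")
    expect_identical(diseaseItems(tm), "d1")
})

test_that("degenerate transaction inputs are rejected", {
    empty <- data.frame(compound = character(), item = character())
    expect_error(transactionMatrix(empty, empty), "non-empty")
    cg <- data.frame(compound = "c1", gene = "x1")
    cd <- data.frame(compound = "c1", disease = "x1")
    expect_error(transactionMatrix(cg, cd), "both gene and disease")
})

test_that("matrix -> pairs -> matrix round trip is the identity", {
    tm <- toyTransactions()
    m <- transactionItems(tm)
    idx <- which(m == 1L, arr.ind = TRUE)
    is_gene <- colnames(m)[idx[, 2]] %in% geneItems(tm)
    cg <- data.frame(compound = rownames(m)[idx[is_gene, 1]],
                     gene = colnames(m)[idx[is_gene, 2]])
    cd <- data.frame(compound = rownames(m)[idx[!is_gene, 1]],
                     disease = colnames(m)[idx[!is_gene, 2]])
    tm2 <- transactionMatrix(cg, cd)
    m2 <- transactionItems(tm2)
    keep <- rownames(m)[rowSums(m) > 0]   # itemless compounds cannot return
    expect_identical(m2[keep, colnames(m)], m[keep, ])
})

test_that("QC drops items supported by at most one compound", {
    m <- matrix(0L, 4, 4, dimnames = list(paste0("c", 1:4),
                                          c("g1", "g2", "g3", "d1")))
    m[1, "g1"] <- 1L                     # column sum 1 -> dropped
    m[1:2, "g2"] <- 1L                   # 2 -> kept
    m[1:3, "d1"] <- 1L                   # 3 -> kept; g3 sum 0 -> dropped
    tm <- methods::new("TransactionMatrix", mat = m,
                       geneItems = c("g1", "g2", "g3"), diseaseItems = "d1")
    f <- qcFilterTransactions(tm)
    expect_setequal(colnames(transactionItems(f)), c("g2", "d1"))
    expect_identical(nrow(transactionItems(f)), 4L)  # rows untouched
    # survivors equal a brute-force column scan
    expect_setequal(colnames(transactionItems(f)),
                    colnames(m)[colSums(m) >= 2])
    expect_error(qcFilterTransactions(
        methods::new("TransactionMatrix",
                     mat = m[, "g1", drop = FALSE] * 0L,
                     geneItems = "g1", diseaseItems = character())),
        "no items survive")
})

test_that("rule metrics on the worked 10-compound example", {
    tm <- toyTransactions()
    rules <- mineRules(tm, min_support = 0.3, min_lift = 1)
    r <- rules[rules$gene == "g1" & rules$disease == "d1", ]
    expect_equal(r$support, 0.4)
    expect_equal(r$confidence, 2 / 3, tolerance = 1e-12)
    expect_equal(r$lift, 4 / 3, tolerance = 1e-12)
    expect_equal(r$odds_ratio, 6)   # (4*3)/(2*1)
    o <- bruteRule(transactionItems(tm), "g1", "d1")
    expect_equal(r$support, o$support)
    expect_equal(r$confidence, o$confidence)
    expect_equal(r$lift, o$lift)
    expect_equal(r$odds_ratio, o$odds_ratio)
})

test_that("support and lift thresholds prune as specified", {
    tm <- toyTransactions()
    # g2/d2 co-occur in 2 of 10 compounds: support 0.2 < 0.3 -> dropped
    rules <- mineRules(tm, min_support = 0.3, min_lift = 1)
    expect_false(any(rules$gene == "g2" & rules$disease == "d2"))
    # an independent pair has lift exactly 1 and is dropped by the strict cut
    m <- matrix(0L, 4, 2, dimnames = list(paste0("c", 1:4), c("g1", "d1")))
    m[1:2, "g1"] <- 1L
    m[c(1, 3), "d1"] <- 1L   # P(both) = 1/4 = P(g)P(d): independent
    tmi <- methods::new("TransactionMatrix", mat = m, geneItems = "g1",
                        diseaseItems = "d1")
    expect_identical(nrow(mineRules(tmi, min_support = 0.1, min_lift = 1)), 0L)
})

test_that("rule metrics agree with brute-force 2x2 enumeration on random data", {
    set.seed(61)
    m <- matrix(rbinom(15 * 8, 1, 0.5), 15, 8,
                dimnames = list(paste0("c", 1:15),
                                c(paste0("g", 1:4), paste0("d", 1:4))))
    storage.mode(m) <- "integer"
    tm <- methods::new("TransactionMatrix", mat = m,
                       geneItems = paste0("g", 1:4),
                       diseaseItems = paste0("d", 1:4))
    rules <- mineRules(tm, min_support = 0, min_lift = 0)
    for (i in seq_len(nrow(rules))) {
        o <- bruteRule(m, rules$gene[i], rules$disease[i])
        expect_equal(rules$support[i], o$support)
        expect_equal(rules$confidence[i], o$confidence)
        expect_equal(rules$lift[i], o$lift)
        expect_equal(rules$odds_ratio[i], o$odds_ratio)
    }
    # metric identities
    pD <- colSums(m)[rules$disease] / nrow(m)
    pG <- colSums(m)[rules$gene] / nrow(m)
    expect_true(all(rules$support <= pmin(pG, pD) + 1e-12))
    expect_equal(rules$lift * pD, rules$confidence, tolerance = 1e-12,
                 ignore_attr = TRUE)
    # permuting compounds leaves metrics unchanged
    perm <- sample(nrow(m))
    tmp <- methods::new("TransactionMatrix", mat = m[perm, ],
                        geneItems = paste0("g", 1:4),
                        diseaseItems = paste0("d", 1:4))
    rp <- mineRules(tmp, min_support = 0, min_lift = 0)
    key <- function(r) r[order(r$gene, r$disease),
                         c("support", "confidence", "lift", "odds_ratio")]
    expect_equal(key(rp), key(rules), ignore_attr = TRUE)
})

test_that("QC-then-mine equals mine-then-discard on QC-failed items", {
    set.seed(62)
    m <- matrix(rbinom(12 * 6, 1, 0.35), 12, 6,
                dimnames = list(paste0("c", 1:12),
                                c(paste0("g", 1:3), paste0("d", 1:3))))
    storage.mode(m) <- "integer"
    tm <- methods::new("TransactionMatrix", mat = m,
                       geneItems = paste0("g", 1:3),
                       diseaseItems = paste0("d", 1:3))
    surviving <- colnames(m)[colSums(m) >= 2]
    a <- mineRules(qcFilterTransactions(tm), min_support = 0.1, min_lift = 0)
    b <- mineRules(tm, min_support = 0.1, min_lift = 0)
    b <- b[b$gene %in% surviving & b$disease %in% surviving, ]
    key <- function(r) r[order(r$gene, r$disease),
                         c("gene", "disease", "support", "lift")]
    expect_equal(key(a), key(b), ignore_attr = TRUE)
})

test_that("item similarity follows the printed overlap formula", {
    rules <- data.frame(gene = c("g1", "g2", "g2", "g3"),
                        disease = c("D1", "D1", "D2", "D2"))
    sim <- itemSimilarity(rules, mode = "disease")
    expect_equal(sim["D1", "D2"], 1 / (2 * 2))    # {g1,g2} n {g2,g3}
    expect_equal(sim["D2", "D1"], 0.25)           # symmetric
    sim2 <- itemSimilarity(rules, mode = "disease",
                           denominator = "sqrt-product")
    expect_equal(sim2["D1", "D2"], 1 / 2)
    # disjoint sets give zero; identical singleton sets give one
    r2 <- data.frame(gene = c("g1", "g2"), disease = c("D1", "D2"))
    expect_equal(itemSimilarity(r2, "disease")["D1", "D2"], 0)
    r3 <- data.frame(gene = c("g1", "g1"), disease = c("D1", "D2"))
    expect_equal(itemSimilarity(r3, "disease")["D1", "D2"], 1)
})

test_that("item clustering cuts the average-linkage tree as expected", {
    # two tight blocks, zero across: the cut at 0.5 recovers the blocks
    items <- c("a1", "a2", "a3", "b1", "b2", "b3")
    sim <- matrix(0, 6, 6, dimnames = list(items, items))
    sim[1:3, 1:3] <- 0.9; sim[4:6, 4:6] <- 0.8; diag(sim) <- 1
    lab <- clusterItems(sim, cut = 0.5)
    expect_identical(length(unique(lab[1:3])), 1L)
    expect_identical(length(unique(lab[4:6])), 1L)
    expect_false(lab["a1"] == lab["b1"])
    # sim = 1 pair merges at any cut above zero
    s2 <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
    expect_identical(unname(clusterItems(s2, 0.1)), c(1L, 1L))
    # all-zero similarity: everything is its own cluster below height 1
    s3 <- diag(3); dimnames(s3) <- list(letters[1:3], letters[1:3])
    s3[s3 == 0] <- 0
    expect_identical(length(unique(clusterItems(s3, 0.5))), 3L)
    expect_warning(clusterItems(matrix(1, 1, 1, dimnames = list("a", "a")),
                                0.5), "fewer than 2")
})
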