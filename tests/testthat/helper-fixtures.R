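# Shared fixtures and independent oracles, all built in code.

# minimal 2-group design: 1 compound per group, 1 dose, 1 time, 2 replicates
toyDesign4 <- function() {
    data.frame(sample_id = paste0("s", 1:4),
               group = rep(c("g1", "g2"), each = 2),
               compound = rep(c("c1", "c2"), each = 2),
               dose = 1, time = 1, replicate = rep(1:2, 2))
}

# random valid nested design; some cells lose a replicate so sizes are unbalanced
randomDesign <- function(seed) {
    set.seed(seed)
    b <- sample(2:4, 2, replace = TRUE)
    des <- makeNestedDesign(compounds = b, doses = sample(2:3, 1),
                            times = sample(2:3, 1), replicates = 3)
    drop <- sample(nrow(des), floor(nrow(des) * 0.1))
    des[-drop, , drop = FALSE]
}

# brute-force per-gene F via explicit sums (independent of the package path)
loopF <- function(y, design) {
    g <- split(seq_along(y), design$group)
    cells <- split(seq_along(y), interaction(design$compound, design$dose,
                                             design$time, drop = TRUE))
    n <- length(y); p <- length(cells); a <- length(g)
    ybar <- mean(y)
    pi_ <- 0
    for (idx in g) pi_ <- pi_ + length(idx) * (mean(y[idx]) - ybar)^2
    psi <- 0
    for (idx in cells) psi <- psi + sum((y[idx] - mean(y[idx]))^2)
    list(pi = pi_, psi = psi, F = (n - p) / (a - 1) * pi_ / psi,
         df1 = a - 1, df2 = n - p)
}

# brute-force rule metrics for one (gene, disease) pair from a binary matrix
bruteRule <- function(m, gcol, dcol) {
    r <- nrow(m)
    n11 <- sum(m[, gcol] == 1 & m[, dcol] == 1)
    n10 <- sum(m[, gcol] == 1 & m[, dcol] == 0)
    n01 <- sum(m[, gcol] == 0 & m[, dcol] == 1)
    n00 <- r - n11 - n10 - n01
    cc <- if (any(c(n11, n10, n01, n00) == 0)) 0.5 else 0
    list(support = n11 / r,
         confidence = n11 / (n11 + n10),
         lift = (n11 / (n11 + n10)) / ((n11 + n01) / r),
         odds_ratio = ((n11 + cc) * (n00 + cc)) / ((n10 + cc) * (n01 + cc)))
}

# toy transaction matrix used across rule-mining tests
toyTransactions <- function() {
    m <- matrix(0L, 10, 4,
                dimnames = list(paste0("c", 1:10),
                                c("g1", "g2", "d1", "d2")))
    m[1:6, "g1"] <- 1L          # gene in 6 compounds
    m[c(1:4, 7), "d1"] <- 1L    # disease in 5; both in 4
    m[c(1, 2), "g2"] <- 1L
    m[c(1, 2), "d2"] <- 1L
    methods::new("TransactionMatrix", mat = m,
                 geneItems = c("g1", "g2"), diseaseItems = c("d1", "d2"))
}
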